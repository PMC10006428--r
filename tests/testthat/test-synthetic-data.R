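test_that("generators are deterministic under a fixed seed", {
  expect_identical(simulate_ltr_pairs(n_elements = 5, ltr_length = 100,
                                      seed = 11),
                   simulate_ltr_pairs(n_elements = 5, ltr_length = 100,
                                      seed = 11))
  expect_identical(simulate_methylome(n_sites = c(CG = 50, CHG = 50,
                                                  CHH = 50),
                                      chrom_length = 5000, seed = 3),
                   simulate_methylome(n_sites = c(CG = 50, CHG = 50,
                                                  CHH = 50),
                                      chrom_length = 5000, seed = 3))
  expect_identical(simulate_hgt_tables(n_queries = 5, n_transferred = 1,
                                       seed = 5),
                   simulate_hgt_tables(n_queries = 5, n_transferred = 1,
                                       seed = 5))
  expect_identical(simulate_ks(n_pairs = 100, seed = 2),
                   simulate_ks(n_pairs = 100, seed = 2))
  expect_identical(simulate_feature_genome(n_chroms = 1,
                                           chrom_length = 3e4, seed = 9),
                   simulate_feature_genome(n_chroms = 1,
                                           chrom_length = 3e4, seed = 9))
})

test_that("LTR pairs at age zero are identical; transition bias is honoured", {
  sim0 <- simulate_ltr_pairs(n_elements = 10, ltr_length = 300,
                             true_age = 0, seed = 1)
  expect_identical(sim0$pairs$seq5, sim0$pairs$seq3)
  k <- ltr_insertion_ages(sim0$pairs)
  expect_true(all(k$K == 0))
  expect_true(all(k$T == 0))

  sim_ts <- simulate_ltr_pairs(n_elements = 20, ltr_length = 500,
                               true_age = 2e7, transition_fraction = 1,
                               seed = 4)
  tv <- vapply(seq_len(20), function(i) {
    count_substitutions(sim_ts$pairs$seq5[i],
                        sim_ts$pairs$seq3[i])$n_transversions
  }, integer(1))
  expect_true(all(tv == 0L))
})

test_that("mean LTR divergence converges to the exponential expectation", {
  r <- 2.2e-9
  T0 <- 1e7
  sim <- simulate_ltr_pairs(n_elements = 100, ltr_length = 2000,
                            true_age = T0, seed = 21)
  div <- vapply(seq_len(100), function(i) {
    cs <- count_substitutions(sim$pairs$seq5[i], sim$pairs$seq3[i])
    (cs$n_transitions + cs$n_transversions) / cs$n_sites
  }, numeric(1))
  # expected per-site divergence is ~1 - exp(-2 r T); multiple hits make the
  # realised value slightly smaller, Monte-Carlo error ~5e-4 at 2e5 sites
  expect_lt(abs(mean(div) - (1 - exp(-2 * r * T0))), 0.003)
})

test_that("methylome simulation respects degenerate parameter settings", {
  null_sim <- simulate_methylome(n_sites = c(CG = 200, CHG = 200, CHH = 200),
                                 levels = c(CG = 0, CHG = 0, CHH = 0),
                                 chrom_length = 2e4, non_conversion = 0,
                                 lambda_sites = 0, seed = 6)
  expect_true(all(null_sim$records$count_m == 0L))

  sat_sim <- simulate_methylome(n_sites = c(CG = 200, CHG = 200, CHH = 200),
                                levels = c(CG = 1, CHG = 1, CHH = 1),
                                chrom_length = 2e4, lambda_sites = 0,
                                seed = 6)
  expect_identical(sat_sim$records$count_m, sat_sim$records$count_total)
})

test_that("empirical context levels converge to truth within 3 binomial SE", {
  lv <- c(CG = 0.83, CHG = 0.69, CHH = 0.04)
  nc <- 0.005
  sim <- simulate_methylome(n_sites = c(CG = 5000, CHG = 5000, CHH = 5000),
                            levels = lv, chrom_length = 1e5,
                            non_conversion = nc, lambda_sites = 0, seed = 8)
  for (ctx in c("CG", "CHG", "CHH")) {
    rec <- sim$records[sim$records$context == ctx, ]
    expected <- lv[[ctx]] + (1 - lv[[ctx]]) * nc
    n_reads <- sum(rec$count_total)
    se <- sqrt(expected * (1 - expected) / n_reads)
    expect_lt(abs(methylation_level(rec) - expected), 3 * se + 1e-12)
  }
})

test_that("planted DMVs force near-zero levels and out-of-span DMVs error", {
  dmv <- data.frame(start = 5000, end = 9000)
  sim <- simulate_methylome(n_sites = c(CG = 500, CHG = 500, CHH = 500),
                            chrom_length = 2e4, dmvs = dmv,
                            lambda_sites = 0, seed = 2)
  inside <- sim$truth$sites$pos >= 5000 & sim$truth$sites$pos <= 9000
  expect_true(all(sim$truth$sites$true_level[inside] < 0.01))
  expect_error(
    simulate_methylome(chrom_length = 2e4,
                       dmvs = data.frame(start = 1, end = 3e4)),
    "outside the simulated chromosome")
})

test_that("HGT tables plant the ABV contrast and cover every species", {
  sim <- simulate_hgt_tables(n_queries = 20, n_transferred = 3, seed = 13)
  expect_equal(sum(sim$truth$transferred), 3L)
  out_tab <- sim$tables$out
  expect_equal(length(unique(out_tab$species)), 120L)
  # every query hits every out-group species once
  expect_equal(nrow(out_tab), 20L * 120L)
  expect_true(all(out_tab$subject_id %in% sim$species_map$subject_id))
  # more species than the cap: downstream keeps exactly 100
  scr <- screen_candidates(rbind(sim$tables$out, sim$tables$mid,
                                 sim$tables$`in`))
  expect_true(all(scr$n_out == 100L))
})

test_that("Ks draws follow the requested mixture", {
  pt <- simulate_ks(n_pairs = 200, weights = 1, means = 1.4, sds = 1e-6,
                    seed = 3)
  expect_true(all(abs(pt$ks - 1.4) < 1e-4))

  one <- simulate_ks(n_pairs = 2000, weights = 1, means = 1.4, sds = 0.2,
                     seed = 4)
  expect_lt(abs(mean(one$ks) - 1.4), 3 * 0.2 / sqrt(2000))
  expect_true(all(one$ks > 0))
  expect_error(simulate_ks(means = c(-1, 1), weights = c(0.5, 0.5),
                           sds = c(1, 1)), "positive")
})

test_that("feature genomes carry telomere arrays and a 101-bp monomer", {
  sim <- simulate_feature_genome(n_chroms = 3, chrom_length = 5e4,
                                 telomere_copies = 100,
                                 telomere_ends = c("3prime", "none", "both"),
                                 centromere_copies = 200, seed = 5)
  scan <- telomere_scan(sim$sequences, min_copies = 10)
  expect_equal(scan$has_3prime, c(TRUE, FALSE, TRUE))
  expect_equal(scan$has_5prime, c(FALSE, FALSE, TRUE))

  none <- simulate_feature_genome(n_chroms = 2, chrom_length = 5e4,
                                  telomere_copies = 0,
                                  centromere_copies = 200, seed = 5)
  scan0 <- telomere_scan(none$sequences, min_copies = 10)
  expect_false(any(scan0$has_5prime) || any(scan0$has_3prime))

  cen <- centromere_monomer_summary(sim$tandem_annotations)
  expect_equal(cen$modal_period, 101)
  expect_equal(cen$presence, c("chr01", "chr02", "chr03"))

  expect_error(simulate_feature_genome(chrom_length = 1000,
                                       telomere_copies = 100,
                                       centromere_copies = 200),
               "exceed")
})
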