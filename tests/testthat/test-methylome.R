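test_that("conversion rate pools lambda reads", {
  rec <- make_cx(pos = c(10, 20), count_m = c(3, 2),
                 count_total = c(500, 500), chrom = "lambda")
  est <- estimate_conversion_rate(rec)
  expect_equal(est$rate, 0.995)
  expect_equal(est$total, 1000)
  expect_s3_class(est, "conversion_estimate")

  all_conv <- make_cx(pos = 1:3, count_m = 0L, count_total = 100L,
                      chrom = "lambda")
  expect_equal(estimate_conversion_rate(all_conv)$rate, 1.0)
  expect_error(estimate_conversion_rate(make_cx(1, 0L, 0L)), "zero total")
})

test_that("conversion estimate from a large simulated spike-in is tight", {
  sim <- simulate_methylome(n_sites = c(CG = 10, CHG = 10, CHH = 10),
                            chrom_length = 1000, lambda_sites = 5000,
                            mean_depth = 20, non_conversion = 0.005,
                            seed = 12)
  est <- estimate_conversion_rate(sim$lambda_records)
  expect_gt(est$total, 9e4)  # ~1e5 read observations
  expect_lt(abs(est$rate - 0.995), 0.001)
})

test_that("binomial p-values match closed forms", {
  rec <- make_cx(pos = c(1, 2, 3), count_m = c(0L, 5L, 1L),
                 count_total = c(10L, 5L, 10L))
  calls <- call_methylated_sites(rec, conversion = 0.99)
  expect_equal(calls$p_value[1], 1)                      # 0 of 10
  expect_equal(calls$p_value[2], 0.01^5, tolerance = 1e-12)  # all reads mC
  expect_equal(calls$p_value[3], 1 - 0.99^10, tolerance = 1e-12)

  # perfect conversion: null probability 0, any mC read is exact evidence
  calls1 <- call_methylated_sites(rec, conversion = 1)
  expect_equal(calls1$p_value, c(1, 0, 0))
  expect_error(call_methylated_sites(rec, conversion = 0.99, alpha = 1.5),
               "alpha")
})

test_that("FDR adjustment is BH within context, equal to a brute-force oracle", {
  set.seed(33)
  for (n in c(1, 17, 400, 1000)) {
    p <- runif(n)^2
    expect_equal(p.adjust(p, method = "BH"), brute_bh(p))
  }
  # per-context adjustment: q-values within one context are unaffected by
  # the other context's p-values
  rec <- rbind(make_cx(pos = 1:50, count_m = 5L, count_total = 10L,
                       context = "CG"),
               make_cx(pos = 101:150, count_m = 1L, count_total = 10L,
                       context = "CHH"))
  calls <- call_methylated_sites(rec, conversion = 0.995)
  cg_only <- call_methylated_sites(rec[rec$context == "CG", ],
                                   conversion = 0.995)
  expect_equal(calls$q_value[calls$context == "CG"], cg_only$q_value)
})

test_that("methylation level pools counts, not per-site means", {
  expect_equal(methylation_level(make_cx(1, 83L, 100L)), 0.83)
  expect_equal(methylation_level(make_cx(1:3, 0L, 10L)), 0)
  two <- make_cx(pos = c(1, 2), count_m = c(10L, 0L),
                 count_total = c(10L, 90L))
  expect_equal(methylation_level(two), 0.10)  # weighted, not 0.50
  expect_true(is.na(methylation_level(make_cx(1, 0L, 0L))))
})

test_that("binned levels aggregate consistently and leave empty bins NA", {
  rec <- make_cx(pos = c(100, 5000, 15000), count_m = c(8L, 2L, 5L),
                 count_total = c(10L, 10L, 10L))
  b <- binned_levels(rec, chrom_sizes = c(chr1 = 40000), bin = 10000,
                     contexts = "CG")
  expect_equal(nrow(b), 4L)
  expect_equal(b$level[1], 0.5)   # (8 + 2) / 20
  expect_equal(b$level[2], 0.5)
  expect_true(all(is.na(b$level[3:4])))
  expect_equal(b$n_sites, c(2, 1, 0, 0))

  # single bin spanning the chromosome equals the global level
  b1 <- binned_levels(rec, chrom_sizes = c(chr1 = 40000), bin = 40000,
                      contexts = "CG")
  expect_equal(b1$level, methylation_level(rec))

  # exact pooling identity: global level is the coverage-weighted bin mean
  sim <- simulate_methylome(n_sites = c(CG = 800, CHG = 800, CHH = 800),
                            chrom_length = 5e4, seed = 19)
  bb <- binned_levels(sim$records, chrom_sizes = c(chr1 = 5e4), bin = 1e4)
  for (ctx in c("CG", "CHG", "CHH")) {
    sub <- sim$records[sim$records$context == ctx, ]
    bsub <- bb[bb$context == ctx & !is.na(bb$level), ]
    w <- vapply(seq_len(nrow(bsub)), function(i) {
      r <- sub[sub$pos >= bsub$start[i] & sub$pos <= bsub$end[i], ]
      sum(r$count_total)
    }, numeric(1))
    expect_equal(sum(bsub$level * w) / sum(w), methylation_level(sub))
  }
})

test_that("gene metaprofile shows the exon/flank step and stays flat when uniform", {
  gm <- make_gene_models(
    data.frame(gene_id = "g1", chrom = "chr1", start = 2001, end = 4000,
               strand = "+"),
    list(data.frame(start = 2001, end = 4000)))
  pos <- seq(10, 6000, by = 20)
  in_gene <- pos >= 2001 & pos <= 4000
  rec <- make_cx(pos = pos, count_m = ifelse(in_gene, 8L, 2L),
                 count_total = 10L)
  prof <- gene_metaprofile(rec, gm, flank = 2000, n_bins = 5)
  exon_lv <- prof$level[prof$segment == "exon" & prof$context == "CG"]
  up_lv <- prof$level[prof$segment == "upstream" & prof$context == "CG"]
  expect_true(all(exon_lv == 0.8))
  expect_true(all(up_lv == 0.2))

  uniform <- make_cx(pos = pos, count_m = 5L, count_total = 10L)
  pu <- gene_metaprofile(uniform, gm, flank = 2000, n_bins = 5)
  lv <- pu$level[!is.na(pu$level)]
  expect_true(all(lv == 0.5))
})

test_that("minus-strand metaprofiles mirror their plus-strand equivalents", {
  L <- 4000
  pos <- seq(10, 3990, by = 10)
  counts <- as.integer((pos %/% 10) %% 6)
  rec_plus <- make_cx(pos = pos, count_m = counts, count_total = 10L)
  gm_plus <- make_gene_models(
    data.frame(gene_id = "g", chrom = "chr1", start = 1001, end = 3000,
               strand = "+"),
    list(data.frame(start = c(1001, 2001), end = c(1600, 3000))))

  # reflect every position through the chromosome midpoint
  rec_minus <- rec_plus
  rec_minus$pos <- (L + 1L) - rec_plus$pos
  gm_minus <- make_gene_models(
    data.frame(gene_id = "g", chrom = "chr1", start = 1001, end = 3000,
               strand = "-"),
    list(data.frame(start = c(L + 1 - 3000, L + 1 - 1600),
                    end = c(L + 1 - 2001, L + 1 - 1001))))

  p1 <- gene_metaprofile(rec_plus, gm_plus, flank = 500, n_bins = 4)
  p2 <- gene_metaprofile(rec_minus, gm_minus, flank = 500, n_bins = 4)
  expect_equal(p1, p2)
})

test_that("expression ventiles partition genes and track a planted trend", {
  n <- 40
  gdf <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
                    start = (0:(n - 1)) * 1000 + 1,
                    end = (0:(n - 1)) * 1000 + 500, strand = "+")
  gm <- make_gene_models(gdf, lapply(seq_len(n), function(i) {
    data.frame(start = gdf$start[i], end = gdf$end[i])
  }))
  rec <- make_cx(pos = gdf$start + 100, count_m = as.integer(1:n),
                 count_total = 100L)
  expr <- data.frame(gene_id = gdf$gene_id, tpm = as.numeric(1:n))
  gv <- expression_ventile_gbm(rec, gm, expr, n_groups = 20,
                               contexts = "CG")
  expect_equal(unique(gv$n_genes), 2L)
  expect_equal(nrow(gv), 20L)
  lv <- gv$level[order(gv$group)]
  expect_true(all(diff(lv) > 0))  # planted monotone trend recovered
  expect_equal(gv$median_tpm[gv$group == 1], 1.5)

  # all-equal TPM: stable tie order by gene id, equal medians
  tie <- expression_ventile_gbm(rec, gm,
                                transform(expr, tpm = 7), n_groups = 20,
                                contexts = "CG")
  expect_true(all(tie$median_tpm == 7))
  expect_error(expression_ventile_gbm(rec, gm, expr, n_groups = 50),
               "n_groups")
})

test_that("planted demethylation valleys are recovered with high overlap", {
  dmv <- data.frame(start = 80001, end = 90000)
  sim <- simulate_methylome(n_sites = c(CG = 2000, CHG = 2000, CHH = 4000),
                            chrom_length = 2e5, dmvs = dmv,
                            mean_depth = 20, lambda_sites = 0, seed = 14)
  found <- detect_dmv(sim$records)
  expect_equal(length(found), 1L)
  j <- interval_jaccard(GenomicRanges::start(found),
                        GenomicRanges::end(found), dmv$start, dmv$end)
  expect_gte(j, 0.9)
  expect_true(all(S4Vectors::mcols(found)$level_cg < 0.05))
})

test_that("DMV detection is silent on high methylation and short valleys", {
  high <- simulate_methylome(n_sites = c(CG = 1000, CHG = 1000, CHH = 0),
                             levels = c(CG = 0.8, CHG = 0.8, CHH = 0),
                             chrom_length = 1e5, lambda_sites = 0, seed = 15)
  expect_equal(length(detect_dmv(high$records)), 0L)

  short <- simulate_methylome(n_sites = c(CG = 2000, CHG = 2000,
                                          CHH = 2000),
                              chrom_length = 2e5,
                              dmvs = data.frame(start = 50001, end = 50600),
                              lambda_sites = 0, seed = 16)
  found <- detect_dmv(short$records, min_length = 1000)
  expect_equal(length(found), 0L)
  expect_error(detect_dmv(high$records, threshold = 1.2), "threshold")
})

test_that("common DMVs are exact base-pair intersections", {
  g <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
  a <- g(1, 10000)
  b <- g(5001, 15000)
  c3 <- g(5001, 8000)
  common <- common_dmvs(list(a, b, c3), min_length = 1000)
  expect_equal(GenomicRanges::start(common), 5001)
  expect_equal(GenomicRanges::end(common), 8000)

  expect_equal(common_dmvs(list(a, a), min_length = 1000), GenomicRanges::reduce(a))
  expect_equal(length(common_dmvs(list(g(1, 2000), g(9001, 12000)),
                                  min_length = 1)), 0L)
  expect_error(common_dmvs(list(a)), "two")
})

test_that("genes are flagged by >= 1 bp DMV overlap only", {
  dmv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000))
  gdf <- data.frame(gene_id = c("inside", "past_end", "touching"),
                    chrom = "chr1",
                    start = c(1200, 2001, 1951),
                    end = c(1400, 2500, 2200), strand = "+")
  gm <- make_gene_models(gdf, lapply(seq_len(3), function(i) {
    data.frame(start = gdf$start[i], end = gdf$end[i])
  }))
  fl <- annotate_dmv_genes(dmv, gm)
  expect_equal(fl$in_dmv, c(TRUE, FALSE, TRUE))

  # planted DMV over 3 of 10 regularly spaced genes
  gdf10 <- data.frame(gene_id = sprintf("g%02d", 1:10), chrom = "chr1",
                      start = (0:9) * 1000 + 1, end = (0:9) * 1000 + 800,
                      strand = "+")
  gm10 <- make_gene_models(gdf10, lapply(1:10, function(i) {
    data.frame(start = gdf10$start[i], end = gdf10$end[i])
  }))
  dmv3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 5000))
  expect_equal(sum(annotate_dmv_genes(dmv3, gm10)$in_dmv), 3L)
})

test_that("chi-squared enrichment matches hand computation", {
  res <- enrichment_chi2(50, 50, 10, 90)
  # expected counts 30/70/30/70 -> 2 * (400/30 + 400/70) = 38.095
  expect_equal(res$chi2, 2 * (400 / 30 + 400 / 70), tolerance = 1e-10)
  expect_equal(round(res$chi2, 3), 38.095)
  expect_equal(res$df, 1L)
  expect_lt(res$p, 1e-4)

  indep <- enrichment_chi2(20, 80, 10, 40)
  expect_equal(indep$chi2, 0, tolerance = 1e-12)
  expect_error(enrichment_chi2(0, 0, 5, 5), "marginal")
})
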