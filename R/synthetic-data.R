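# Seeded generators for every input the pipeline consumes, each returning a
# ground-truth table so downstream stages have truth-known tests. All
# randomness flows through set.seed(seed) at entry: the same seed gives
# byte-identical output.

.BASES <- c("A", "C", "G", "T")
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

#' Simulate diverged 5'/3' LTR pairs of known age
#'
#' Each intact LTR retrotransposon starts with two identical LTR copies; from
#' insertion onward each copy accumulates substitutions independently. Here a
#' random ancestral LTR is copied twice and each copy receives a Poisson
#' number of substitution events per site (rate `subst_rate * true_age`), so
#' multiple hits occur and the Kimura two-parameter multiple-hit correction is
#' genuinely exercised. Each event is a transition with probability
#' `transition_fraction`, otherwise one of the two transversions.
#'
#' @param n_elements number of intact elements to simulate.
#' @param ltr_length LTR length in bp.
#' @param true_age insertion age in years.
#' @param subst_rate substitution rate per site per year (default `2.2e-9`,
#'   the gymnosperm rate used for dating).
#' @param transition_fraction fraction of substitution events that are
#'   transitions (default 2/3).
#' @param seed integer RNG seed.
#' @return a list with `pairs` (data.frame `element_id`, `seq5`, `seq3`) and
#'   `truth` (data.frame `element_id`, `true_age`).
#' @export
simulate_ltr_pairs <- function(n_elements = 200, ltr_length = 2000,
                               true_age = 1e7, subst_rate = 2.2e-9,
                               transition_fraction = 2 / 3, seed = 1) {
  .check_scalar(n_elements, "n_elements", lower = 1)
  .check_scalar(ltr_length, "ltr_length", lower = 1)
  .check_scalar(true_age, "true_age", lower = 0)
  .check_scalar(subst_rate, "subst_rate", lower = 0, strict_lower = TRUE)
  if (transition_fraction <= 0 || transition_fraction >= 1) {
    # allow the degenerate documented cases 0/1 for testing
    if (!(transition_fraction %in% c(0, 1))) {
      stop("'transition_fraction' must be in [0, 1]", call. = FALSE)
    }
  }
  set.seed(seed)
  lambda <- subst_rate * true_age  # expected events per site per copy

  mutate_copy <- function(anc) {
    n_ev <- rpois(length(anc), lambda)
    idx <- which(n_ev > 0L)
    for (i in idx) {
      b <- anc[i]
      for (k in seq_len(n_ev[i])) {
        b <- if (runif(1) < transition_fraction) .TRANSITION[[b]]
             else sample(.TRANSVERSIONS[[b]], 1L)
      }
      anc[i] <- b
    }
    anc
  }

  ids <- sprintf("ltr%04d", seq_len(n_elements))
  seq5 <- character(n_elements)
  seq3 <- character(n_elements)
  for (e in seq_len(n_elements)) {
    anc <- sample(.BASES, ltr_length, replace = TRUE)
    seq5[e] <- paste(mutate_copy(anc), collapse = "")
    seq3[e] <- paste(mutate_copy(anc), collapse = "")
  }
  list(pairs = data.frame(element_id = ids, seq5 = seq5, seq3 = seq3,
                          stringsAsFactors = FALSE),
       truth = data.frame(element_id = ids, true_age = true_age,
                          stringsAsFactors = FALSE))
}

#' Simulate a per-cytosine bisulfite methylome with planted valleys
#'
#' Sites are scattered on one chromosome; each has a context-specific true
#' methylation level, coverage drawn from a Poisson around `mean_depth`, and a
#' methylated read count drawn binomially with success probability
#' `level + (1 - level) * non_conversion` (bisulfite non-conversion makes
#' unmethylated cytosines look methylated). Inside planted demethylation
#' valleys the true level is forced below 0.005. Lambda spike-in cytosines are
#' fully unmethylated, so their apparent level estimates the non-conversion
#' rate.
#'
#' @param n_sites named integer vector: sites per context (`CG`,`CHG`,`CHH`).
#' @param levels named numeric vector of per-context true methylation levels;
#'   default `c(CG = 0.83, CHG = 0.69, CHH = 0.04)`, the global seed-genome
#'   averages the pipeline is designed around.
#' @param chrom,chrom_length chromosome name and length (bp).
#' @param mean_depth expected coverage per site.
#' @param non_conversion probability an unmethylated cytosine escapes
#'   conversion (default 0.005, i.e. a 99.5% conversion rate).
#' @param dmvs optional data.frame (`start`, `end`, 1-based inclusive) of
#'   planted low-methylation valleys; must lie within the chromosome.
#' @param lambda_sites number of lambda spike-in cytosines.
#' @param seed integer RNG seed.
#' @return list with `records` and `lambda_records` (CX-style data.frames as
#'   from [read_cx_report()]) and `truth` (list: per-site `sites` table with
#'   true levels, and the planted `dmvs`).
#' @export
simulate_methylome <- function(n_sites = c(CG = 2000, CHG = 2000, CHH = 4000),
                               levels = c(CG = 0.83, CHG = 0.69, CHH = 0.04),
                               chrom = "chr1", chrom_length = 2e5,
                               mean_depth = 20, non_conversion = 0.005,
                               dmvs = NULL, lambda_sites = 2000, seed = 1) {
  stopifnot(all(.methylation_contexts %in% names(n_sites)),
            all(.methylation_contexts %in% names(levels)))
  if (any(levels < 0 | levels > 1)) {
    stop("'levels' must be in [0, 1]", call. = FALSE)
  }
  .check_scalar(non_conversion, "non_conversion", lower = 0, upper = 1)
  .check_scalar(mean_depth, "mean_depth", lower = 0)
  total <- sum(n_sites[.methylation_contexts])
  if (total > chrom_length) {
    stop("more sites requested than positions available", call. = FALSE)
  }
  if (!is.null(dmvs)) {
    if (any(dmvs$start < 1 | dmvs$end > chrom_length | dmvs$start > dmvs$end)) {
      stop("planted DMV outside the simulated chromosome span", call. = FALSE)
    }
  }
  set.seed(seed)
  pos <- sort(sample.int(chrom_length, total))
  context <- sample(rep(.methylation_contexts, n_sites[.methylation_contexts]))
  strand <- sample(c("+", "-"), total, replace = TRUE)
  level <- unname(levels[context])
  if (!is.null(dmvs) && nrow(dmvs)) {
    in_dmv <- rep(FALSE, total)
    for (i in seq_len(nrow(dmvs))) {
      in_dmv <- in_dmv | (pos >= dmvs$start[i] & pos <= dmvs$end[i])
    }
    level[in_dmv] <- runif(sum(in_dmv), 0, 0.005)
  }
  depth <- rpois(total, mean_depth)
  p_obs <- level + (1 - level) * non_conversion
  count_m <- rbinom(total, depth, p_obs)
  records <- data.frame(chrom = chrom, pos = pos, strand = strand,
                        context = context, count_m = count_m,
                        count_total = depth, coverage_zero = depth == 0L,
                        stringsAsFactors = FALSE)

  lam <- NULL
  if (lambda_sites > 0) {
    ldepth <- rpois(lambda_sites, mean_depth)
    lam <- data.frame(chrom = "lambda", pos = seq_len(lambda_sites) * 10L,
                      strand = sample(c("+", "-"), lambda_sites,
                                      replace = TRUE),
                      context = sample(.methylation_contexts, lambda_sites,
                                       replace = TRUE),
                      count_m = rbinom(lambda_sites, ldepth, non_conversion),
                      count_total = ldepth,
                      coverage_zero = ldepth == 0L,
                      stringsAsFactors = FALSE)
  }
  list(records = records, lambda_records = lam,
       truth = list(sites = data.frame(chrom = chrom, pos = pos,
                                       context = context, true_level = level,
                                       stringsAsFactors = FALSE),
                    dmvs = dmvs, non_conversion = non_conversion))
}

#' Simulate three-database BLAST bitscore tables with planted transfers
#'
#' Emulates the screen's input: each query hits species in an out-group
#' (prokaryote/fungal), mid-group (non-gymnosperm plant) and in-group
#' (gymnosperm) database. Native queries score higher against the mid-group;
#' horizontally transferred queries score higher against the out-group.
#'
#' @param n_queries number of query proteins.
#' @param n_transferred number of planted transfers (first queries).
#' @param species_per_db named integer vector (`out`, `mid`, `in`): species
#'   per database; every species yields one hit per query.
#' @param bitscore_means list with `native` and `transferred`, each a named
#'   numeric vector of per-database mean bitscores.
#' @param bitscore_sd bitscore standard deviation.
#' @param seed integer RNG seed.
#' @return list with `tables` (named list of outfmt-6-shaped data.frames, one
#'   per database), `species_map` (data.frame `subject_id`, `species`) and
#'   `truth` (data.frame `query_id`, `transferred`).
#' @export
simulate_hgt_tables <- function(n_queries = 100, n_transferred = 10,
                                species_per_db = c(out = 120, mid = 80,
                                                   `in` = 20),
                                bitscore_means = list(
                                  native = c(out = 100, mid = 200,
                                             `in` = 300),
                                  transferred = c(out = 250, mid = 100,
                                                  `in` = 300)),
                                bitscore_sd = 15, seed = 1) {
  if (n_transferred > n_queries) {
    stop("'n_transferred' must be <= 'n_queries'", call. = FALSE)
  }
  .check_scalar(bitscore_sd, "bitscore_sd", lower = 0, strict_lower = TRUE)
  dbs <- c("out", "mid", "in")
  stopifnot(all(dbs %in% names(species_per_db)),
            all(dbs %in% names(bitscore_means$native)),
            all(dbs %in% names(bitscore_means$transferred)))
  set.seed(seed)
  qids <- sprintf("query%04d", seq_len(n_queries))
  transferred <- seq_len(n_queries) <= n_transferred
  species <- lapply(setNames(dbs, dbs), function(d) {
    sprintf("%s_species%03d", d, seq_len(species_per_db[[d]]))
  })
  map <- do.call(rbind, lapply(dbs, function(d) {
    data.frame(subject_id = paste0(species[[d]], "_prot1"),
               species = species[[d]], stringsAsFactors = FALSE)
  }))
  tables <- lapply(setNames(dbs, dbs), function(d) {
    n_sp <- species_per_db[[d]]
    mu <- ifelse(transferred, bitscore_means$transferred[[d]],
                 bitscore_means$native[[d]])
    qcol <- rep(qids, each = n_sp)
    bits <- pmax(25, rnorm(n_queries * n_sp, rep(mu, each = n_sp),
                           bitscore_sd))
    data.frame(query_id = qcol,
               subject_id = rep(paste0(species[[d]], "_prot1"), n_queries),
               pident = round(runif(n_queries * n_sp, 30, 95), 2),
               length = 300L, mismatch = 50L, gapopen = 2L,
               qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
               evalue = 2^(-bits), bitscore = round(bits, 1),
               species = rep(species[[d]], n_queries),
               db_class = d, stringsAsFactors = FALSE)
  })
  list(tables = tables, species_map = map,
       truth = data.frame(query_id = qids, transferred = transferred,
                          stringsAsFactors = FALSE))
}

#' Simulate a Ks table from a Gaussian mixture
#'
#' Draws synonymous-distance values for paralog pairs from a specified
#' mixture, truncated at zero by redrawing, emulating a paralog Ks
#' distribution carrying an ancient whole-genome duplication component. The
#' defaults plant a WGD component at Ks = 1.4 over a broader recent-duplicate
#' background.
#'
#' @param n_pairs number of gene pairs.
#' @param weights,means,sds mixture component weights (sum to 1), means (> 0)
#'   and standard deviations (> 0).
#' @param seed integer RNG seed.
#' @return data.frame with `pair_id` and `ks`.
#' @export
simulate_ks <- function(n_pairs = 2000, weights = c(0.5, 0.5),
                        means = c(0.3, 1.4), sds = c(0.1, 0.25), seed = 1) {
  if (abs(sum(weights) - 1) > 1e-8) stop("'weights' must sum to 1",
                                         call. = FALSE)
  if (any(means <= 0)) stop("component means must be positive", call. = FALSE)
  if (any(sds <= 0)) stop("component sds must be positive", call. = FALSE)
  if (length(means) != length(weights) || length(sds) != length(weights)) {
    stop("'weights', 'means', 'sds' must have equal length", call. = FALSE)
  }
  set.seed(seed)
  comp <- sample.int(length(weights), n_pairs, replace = TRUE, prob = weights)
  ks <- rnorm(n_pairs, means[comp], sds[comp])
  while (any(ks <= 0)) {
    bad <- which(ks <= 0)
    ks[bad] <- rnorm(length(bad), means[comp[bad]], sds[comp[bad]])
  }
  data.frame(pair_id = sprintf("pair%05d", seq_len(n_pairs)), ks = ks,
             stringsAsFactors = FALSE)
}

#' Simulate chromosomes with planted telomere and centromere features
#'
#' Random background sequence with tandem TTTAGGG telomere arrays planted at
#' chromosome ends (reverse-complemented at 5' ends, as the motif reads on
#' the forward strand) and a tandem centromeric monomer array (default
#' 101 bp) planted mid-chromosome.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length (bp).
#' @param telomere_copies tandem copies of the telomere motif per planted end.
#' @param telomere_ends character vector recycled over chromosomes, each one
#'   of `"both"`, `"5prime"`, `"3prime"`, `"none"`.
#' @param centromere_monomer_length centromeric monomer period (default 101).
#' @param centromere_copies tandem copies of the monomer per chromosome.
#' @param seed integer RNG seed.
#' @return list with `sequences` (a [Biostrings::DNAStringSet]), `truth`
#'   (data.frame of planted features) and `tandem_annotations` (data.frame
#'   `chrom`, `start`, `end`, `period`, `copies` for
#'   [centromere_monomer_summary()]).
#' @export
simulate_feature_genome <- function(n_chroms = 3, chrom_length = 1e5,
                                    telomere_copies = 100,
                                    telomere_ends = "both",
                                    centromere_monomer_length = 101,
                                    centromere_copies = 200, seed = 1) {
  motif <- "TTTAGGG"
  telo_len <- telomere_copies * nchar(motif)
  cen_len <- centromere_monomer_length * centromere_copies
  if (2 * telo_len + cen_len + 100 > chrom_length) {
    stop("planted features exceed chromosome length", call. = FALSE)
  }
  set.seed(seed)
  ends <- rep_len(telomere_ends, n_chroms)
  seqs <- character(n_chroms)
  truth <- list()
  tandem <- list()
  rc_motif <- as.character(reverseComplement(DNAString(motif)))
  for (i in seq_len(n_chroms)) {
    chrom <- sprintf("chr%02d", i)
    s <- sample(.BASES, chrom_length, replace = TRUE)
    if (telomere_copies > 0 && ends[i] %in% c("both", "5prime")) {
      arr <- strsplit(strrep(rc_motif, telomere_copies), "")[[1]]
      s[seq_along(arr)] <- arr
      truth[[length(truth) + 1]] <- data.frame(
        chrom = chrom, feature = "telomere_5prime", start = 1L,
        end = telo_len, period = nchar(motif), copies = telomere_copies)
    }
    if (telomere_copies > 0 && ends[i] %in% c("both", "3prime")) {
      arr <- strsplit(strrep(motif, telomere_copies), "")[[1]]
      s[(chrom_length - telo_len + 1):chrom_length] <- arr
      truth[[length(truth) + 1]] <- data.frame(
        chrom = chrom, feature = "telomere_3prime",
        start = chrom_length - telo_len + 1L, end = chrom_length,
        period = nchar(motif), copies = telomere_copies)
    }
    if (centromere_copies > 0) {
      monomer <- sample(.BASES, centromere_monomer_length, replace = TRUE)
      arr <- rep(monomer, centromere_copies)
      cen_start <- (chrom_length - cen_len) %/% 2L
      s[cen_start + seq_along(arr)] <- arr
      truth[[length(truth) + 1]] <- data.frame(
        chrom = chrom, feature = "centromere", start = cen_start + 1L,
        end = cen_start + cen_len, period = centromere_monomer_length,
        copies = centromere_copies)
    }
    seqs[i] <- paste(s, collapse = "")
    names(seqs)[i] <- chrom
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), feature = character(), start = integer(),
               end = integer(), period = integer(), copies = integer())
  tandem <- truth[, c("chrom", "start", "end", "period", "copies")]
  list(sequences = DNAStringSet(seqs), truth = truth,
       tandem_annotations = tandem)
}
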