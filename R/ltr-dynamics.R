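# LTR retrotransposon dating: at insertion the two LTRs of an element are
# identical; their divergence K (Kimura two-parameter corrected) clocks the
# insertion time T = K / (2 r), with r the per-site per-year substitution
# rate (2.2e-9 for gymnosperms). Gap/ambiguity columns are excluded from the
# compared sites (pairwise deletion); saturated distances raise a typed
# condition rather than returning NaN.

.GYMNOSPERM_RATE <- 2.2e-9

#' Globally align the two LTRs of an element and count substitutions
#'
#' Needleman-Wunsch global alignment under linear gap scoring (via
#' [Biostrings::pairwiseAlignment]), then transition/transversion counting
#' over columns where both rows carry a base.
#'
#' @param seq5,seq3 the 5' and 3' LTR sequences (A/C/G/T only).
#' @param match,mismatch,gap alignment scores (gap is the per-base penalty,
#'   given as a negative score).
#' @param element_id optional element label.
#' @return an object of class `ltr_pair_alignment`: list with `element_id`,
#'   `aligned_5prime`, `aligned_3prime`, `n_sites` (columns with a base in
#'   both rows), `n_transitions`, `n_transversions`, `score`.
#' @export
align_ltr_pair <- function(seq5, seq3, match = 1, mismatch = -1, gap = -2,
                           element_id = NA_character_) {
  seq5 <- toupper(seq5); seq3 <- toupper(seq3)
  if (!grepl("^[ACGT]+$", seq5) || !grepl("^[ACGT]+$", seq3)) {
    stop("sequences must be non-empty and contain only A/C/G/T",
         call. = FALSE)
  }
  if (gap >= 0) stop("'gap' must be a negative score", call. = FALSE)
  mat <- nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                      baseOnly = TRUE)
  aln <- pairwiseAlignment(seq5, seq3, substitutionMatrix = mat,
                           gapOpening = 0, gapExtension = abs(gap),
                           type = "global")
  a5 <- as.character(alignedPattern(aln))
  a3 <- as.character(alignedSubject(aln))
  counts <- count_substitutions(a5, a3)
  structure(c(list(element_id = element_id, aligned_5prime = unname(a5),
                   aligned_3prime = unname(a3),
                   score = unname(BiocGenerics::score(aln))),
              counts),
            class = "ltr_pair_alignment")
}

#' Count transitions and transversions over an aligned pair
#'
#' Columns with a gap or ambiguity in either row are excluded from `n_sites`
#' (pairwise deletion).
#'
#' @param a5,a3 equal-length gapped sequences.
#' @return list with `n_sites`, `n_transitions`, `n_transversions`.
#' @export
count_substitutions <- function(a5, a3) {
  x <- strsplit(a5, "")[[1]]
  y <- strsplit(a3, "")[[1]]
  if (length(x) != length(y)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  ok <- x %in% .BASES & y %in% .BASES
  x <- x[ok]; y <- y[ok]
  diff <- x != y
  purine <- c("A", "G")
  ts <- diff & ((x %in% purine) == (y %in% purine))
  list(n_sites = sum(ok), n_transitions = sum(ts),
       n_transversions = sum(diff & !ts))
}

#' @export
print.ltr_pair_alignment <- function(x, ...) {
  cat("ltr_pair_alignment", if (!is.na(x$element_id)) x$element_id else "",
      "\n  sites:", x$n_sites, " transitions:", x$n_transitions,
      " transversions:", x$n_transversions, " score:", x$score, "\n")
  invisible(x)
}

#' Kimura two-parameter distance
#'
#' K = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)] where P and Q are the observed
#' transition and transversion proportions. The multiple-hit correction
#' guarantees K >= P + Q on the defined domain. Saturated inputs (where the
#' log argument is non-positive) raise a condition of class
#' `"k2p_saturation_error"`.
#'
#' @param P transition proportion.
#' @param Q transversion proportion.
#' @return corrected substitutions per site (vectorized).
#' @export
kimura2p <- function(P, Q) {
  if (any(P < 0 | Q < 0 | P + Q > 1)) {
    stop("'P' and 'Q' must be proportions with P + Q <= 1", call. = FALSE)
  }
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (any(a <= 0 | b <= 0)) {
    stop(structure(class = c("k2p_saturation_error", "error", "condition"),
                   list(message = "saturated distance: K2P correction undefined (1 - 2P - Q or 1 - 2Q <= 0)",
                        call = sys.call())))
  }
  -0.5 * log(a * sqrt(b))
}

#' LTR insertion time from a corrected distance
#'
#' T = K / (2 r): the two LTRs diverge along two branches, so their distance
#' accumulates at twice the per-site substitution rate.
#'
#' @param K corrected distance (substitutions/site), >= 0.
#' @param r substitution rate per site per year (default `2.2e-9`, the
#'   gymnosperm rate).
#' @return insertion time in years (vectorized).
#' @export
insertion_time <- function(K, r = .GYMNOSPERM_RATE) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0) {
    stop("'r' must be a positive rate", call. = FALSE)
  }
  if (any(K < 0)) stop("'K' must be >= 0", call. = FALSE)
  K / (2 * r)
}

#' Date a table of LTR pairs
#'
#' Runs [align_ltr_pair()], [kimura2p()] and [insertion_time()] over a table
#' of 5'/3' LTR sequence pairs. Saturated elements get `K = NA`, `T = NA` and
#' `saturated = TRUE`; their count is reported in a message.
#'
#' @param pairs data.frame with `element_id`, `seq5`, `seq3` (as produced by
#'   [simulate_ltr_pairs()]).
#' @param r substitution rate per site per year.
#' @param match,mismatch,gap alignment scores passed to [align_ltr_pair()].
#' @return data.frame with `element_id`, `n_sites`, `P`, `Q`, `K`, `T`,
#'   `saturated`.
#' @export
ltr_insertion_ages <- function(pairs, r = .GYMNOSPERM_RATE, match = 1,
                               mismatch = -1, gap = -2) {
  stopifnot(all(c("element_id", "seq5", "seq3") %in% names(pairs)))
  n <- nrow(pairs)
  out <- data.frame(element_id = pairs$element_id, n_sites = NA_integer_,
                    P = NA_real_, Q = NA_real_, K = NA_real_, T = NA_real_,
                    saturated = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    aln <- align_ltr_pair(pairs$seq5[i], pairs$seq3[i], match = match,
                          mismatch = mismatch, gap = gap,
                          element_id = pairs$element_id[i])
    P <- aln$n_transitions / aln$n_sites
    Q <- aln$n_transversions / aln$n_sites
    out$n_sites[i] <- aln$n_sites
    out$P[i] <- P
    out$Q[i] <- Q
    K <- tryCatch(kimura2p(P, Q), k2p_saturation_error = function(e) NA_real_)
    out$K[i] <- K
    out$saturated[i] <- is.na(K)
    if (!is.na(K)) out$T[i] <- insertion_time(K, r)
  }
  n_sat <- sum(out$saturated)
  if (n_sat > 0) message(n_sat, " element(s) saturated; T undefined")
  out
}

#' Histogram of LTR insertion ages
#'
#' Counts per fixed-width age bin, overall (`family = "all"`) and stratified
#' by an optional family/subfamily label.
#'
#' @param ages numeric vector of ages in years (NAs dropped).
#' @param bin_width bin width in years, > 0.
#' @param family optional label vector parallel to `ages`.
#' @return data.frame with `family`, `bin_start`, `bin_end`, `count`
#'   (occupied bins only).
#' @export
age_distribution <- function(ages, bin_width = 1e6, family = NULL) {
  .check_scalar(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  if (!is.null(family) && length(family) != length(ages)) {
    stop("'family' must be parallel to 'ages'", call. = FALSE)
  }
  keep <- !is.na(ages)
  ages <- ages[keep]
  if (any(ages < 0)) stop("ages must be non-negative", call. = FALSE)
  if (length(ages) == 0L) {
    return(data.frame(family = character(), bin_start = numeric(),
                      bin_end = numeric(), count = integer()))
  }
  fam <- if (is.null(family)) rep("all", length(ages)) else
    as.character(family[keep])
  one <- function(a, label) {
    b <- floor(a / bin_width)
    t <- table(b)
    data.frame(family = label, bin_start = as.numeric(names(t)) * bin_width,
               bin_end = (as.numeric(names(t)) + 1) * bin_width,
               count = as.integer(t), stringsAsFactors = FALSE)
  }
  res <- one(ages, "all")
  if (!is.null(family)) {
    for (f in sort(unique(fam))) {
      res <- rbind(res, one(ages[fam == f], f))
    }
  }
  rownames(res) <- NULL
  res
}

#' Solo:intact LTR ratio
#'
#' Solo LTRs arise when unequal recombination excises the element body; a
#' high ratio indexes element removal. Reported to two decimals (half-up),
#' the convention of genome reports.
#'
#' @param n_solo number of solo LTRs, >= 0.
#' @param n_intact number of intact elements, > 0.
#' @return the ratio, two decimals.
#' @export
solo_intact_ratio <- function(n_solo, n_intact) {
  .check_scalar(n_solo, "n_solo", lower = 0)
  if (!is.numeric(n_intact) || length(n_intact) != 1L || n_intact <= 0) {
    stop("undefined ratio: 'n_intact' must be > 0", call. = FALSE)
  }
  round_half_up(n_solo / n_intact, 2)
}
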