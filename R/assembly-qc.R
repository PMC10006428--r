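# Assembly-descriptive arithmetic: N50, coverage folds, Phred-QV accuracy,
# anchoring/repeat fractions, k-mer genome-size estimation, telomere motif
# scanning and centromeric monomer summaries.

#' Contig N50
#'
#' The largest length L such that contigs of length >= L sum to at least half
#' the assembly. When several lengths satisfy the condition the largest
#' qualifying contig length is returned.
#'
#' @param lengths positive contig lengths (bp).
#' @return the N50 in bp.
#' @examples
#' contig_n50(c(5, 4, 3, 2, 1))  # 4
#' @export
contig_n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list", call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("contig lengths must be positive", call. = FALSE)
  }
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Sequencing coverage fold
#'
#' Total sequenced bases over genome size, rounded half-up to one decimal
#' (the convention of assembly reports, e.g. 1.93 Tb over a 20-Gb genome
#' is 96.5x).
#'
#' @param total_bases sequenced bases (bp).
#' @param genome_size genome size (bp), > 0.
#' @return fold coverage, one decimal.
#' @export
coverage_fold <- function(total_bases, genome_size) {
  .check_scalar(genome_size, "genome_size", lower = 0, strict_lower = TRUE)
  .check_scalar(total_bases, "total_bases", lower = 0)
  round_half_up(total_bases / genome_size, 1)
}

#' Convert a Phred-scaled consensus quality (QV) to percent base accuracy
#'
#' accuracy = (1 - 10^(-QV/10)) * 100; QV 46.9 corresponds to 99.998%.
#'
#' @param qv Phred-scaled consensus quality, >= 0.
#' @return percent accuracy (not rounded; round to the report's precision for
#'   display).
#' @export
qv_to_accuracy <- function(qv) {
  if (any(qv < 0)) stop("'qv' must be >= 0", call. = FALSE)
  (1 - 10^(-qv / 10)) * 100
}

#' Fraction of an assembly, as a percentage
#'
#' E.g. anchored bases over total assembly size (anchoring rate) or repeat
#' bases over assembly size (repeat fraction), one decimal, half-up.
#'
#' @param part_bases bp in the part, `0 <= part_bases <= total_bases`.
#' @param total_bases total bp, > 0.
#' @return percentage, one decimal.
#' @export
fraction_of_assembly <- function(part_bases, total_bases) {
  .check_scalar(total_bases, "total_bases", lower = 0, strict_lower = TRUE)
  if (part_bases < 0 || part_bases > total_bases) {
    stop("'part_bases' must be in [0, total_bases]", call. = FALSE)
  }
  round_half_up(part_bases / total_bases * 100, 1)
}

#' Estimate genome size from a k-mer depth histogram
#'
#' Total k-mer observations above a low-depth error cutoff divided by the
#' homozygous-peak depth. The cutoff defaults to the histogram's first local
#' minimum (the valley between the sequencing-error spike and the coverage
#' mode).
#'
#' @param histogram data.frame with columns `depth` and `count` (number of
#'   distinct k-mers observed at that depth), sorted or not.
#' @param error_cutoff depth at/below which k-mers are treated as errors;
#'   `NULL` (default) uses the first local minimum.
#' @return estimated genome size in bp.
#' @export
genome_size_from_kmer_histogram <- function(histogram, error_cutoff = NULL) {
  stopifnot(all(c("depth", "count") %in% names(histogram)))
  h <- histogram[order(histogram$depth), ]
  if (any(h$depth <= 0)) stop("depths must be positive", call. = FALSE)
  if (is.null(error_cutoff)) {
    rising <- which(diff(h$count) >= 0)
    if (length(rising) == 0L) {
      stop("no k-mer coverage mode above the error region", call. = FALSE)
    }
    error_cutoff <- h$depth[rising[1]]
  }
  above <- h[h$depth > error_cutoff, , drop = FALSE]
  if (nrow(above) == 0L || all(above$count == 0)) {
    stop("no k-mer coverage mode above the error cutoff", call. = FALSE)
  }
  peak_depth <- above$depth[which.max(above$count)]
  sum(above$depth * above$count) / peak_depth
}

#' Scan chromosome ends for the telomere motif
#'
#' Counts non-overlapping occurrences of the plant telomere motif
#' (default TTTAGGG) in the 3' terminal window and of its reverse complement
#' in the 5' terminal window; an end is flagged when the copy count reaches
#' `min_copies`.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector) of
#'   chromosome sequences.
#' @param motif telomere repeat unit as read at the 3' end.
#' @param window terminal window size in bp (default 10 kb, capped at the
#'   sequence length).
#' @param min_copies copies required to flag an end (default 10).
#' @return data.frame with one row per chromosome: `chrom`, `copies_5prime`,
#'   `copies_3prime`, `has_5prime`, `has_3prime`.
#' @export
telomere_scan <- function(seqs, motif = "TTTAGGG", window = 10000,
                          min_copies = 10) {
  if (!nzchar(motif)) stop("empty motif", call. = FALSE)
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  rc <- reverseComplement(DNAString(motif))
  res <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    w <- min(window, length(s))
    c5 <- countPattern(rc, subseq(s, 1L, w))
    c3 <- countPattern(DNAString(motif), subseq(s, length(s) - w + 1L,
                                                length(s)))
    data.frame(chrom = names(seqs)[i] %||% paste0("seq", i),
               copies_5prime = c5, copies_3prime = c3,
               has_5prime = c5 >= min_copies, has_3prime = c3 >= min_copies,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Summarize tandem-repeat annotations into a centromeric monomer report
#'
#' Aggregates copy totals by repeat period, reports the modal period (ties
#' flagged and all tied periods returned) and the chromosomes carrying arrays
#' of the modal period above a copy threshold.
#'
#' @param tandem data.frame with columns `chrom`, `start`, `end`, `period`,
#'   `copies`.
#' @param min_copies copies an array needs to establish chromosome presence
#'   (default 50).
#' @return list with `period_totals` (data.frame `period`, `total_copies`),
#'   `modal_period` (integer vector; length > 1 on ties), `tie` (logical) and
#'   `presence` (character vector of chromosomes with qualifying modal-period
#'   arrays).
#' @export
centromere_monomer_summary <- function(tandem, min_copies = 50) {
  if (nrow(tandem) == 0L) {
    return(list(period_totals = data.frame(period = integer(),
                                           total_copies = numeric()),
                modal_period = integer(), tie = FALSE,
                presence = character()))
  }
  if (any(tandem$period <= 0)) stop("periods must be positive", call. = FALSE)
  tot <- aggregate(copies ~ period, data = tandem, FUN = sum)
  names(tot) <- c("period", "total_copies")
  top <- tot$period[tot$total_copies == max(tot$total_copies)]
  pres <- unique(tandem$chrom[tandem$period %in% top &
                              tandem$copies >= min_copies])
  list(period_totals = tot[order(-tot$total_copies), ],
       modal_period = sort(top), tie = length(top) > 1,
       presence = sort(pres))
}
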