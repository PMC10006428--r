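# Small expression-side computations: relative expression by the
# delta-delta-Ct method, descriptive fold changes, and small-RNA length
# spectra.

#' Relative expression by the 2^(-ddCt) method
#'
#' Each measurement carries target and reference (normalizer, e.g. actin)
#' cycle thresholds; technical replicates are averaged on the Ct scale
#' before differencing. Relative expression of the test sample against the
#' calibrator is `2^-(dCt_test - dCt_calibrator)` with `dCt = Ct_target -
#' Ct_reference`.
#'
#' @param test,calibrator lists (or one-row data.frames) with numeric
#'   `ct_target` and `ct_reference`, each possibly a replicate vector.
#' @return the fold relative expression.
#' @export
ddct_relative_expression <- function(test, calibrator) {
  dct <- function(m) {
    ct_t <- m$ct_target
    ct_r <- m$ct_reference
    if (any(!is.finite(ct_t)) || any(!is.finite(ct_r)) ||
        any(ct_t <= 0) || any(ct_r <= 0)) {
      stop("Ct values must be positive and finite", call. = FALSE)
    }
    mean(ct_t) - mean(ct_r)
  }
  2^(-(dct(test) - dct(calibrator)))
}

#' Descriptive fold change between two expression groups
#'
#' Ratio of group means with an optional pseudocount; a descriptive summary,
#' not a differential-expression test.
#'
#' @param group_a,group_b non-empty numeric TPM vectors.
#' @param pseudocount added to both means (default 0).
#' @return `(mean(group_a) + pseudocount) / (mean(group_b) + pseudocount)`.
#' @export
fold_change <- function(group_a, group_b, pseudocount = 0) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("groups must be non-empty", call. = FALSE)
  }
  (mean(group_a) + pseudocount) / (mean(group_b) + pseudocount)
}

#' Small-RNA length spectrum
#'
#' Histogram of read lengths and the modal length(s); a tie returns every
#' tied length.
#'
#' @param read_lengths positive integer read lengths (nt).
#' @return list with `spectrum` (data.frame `length`, `count`) and
#'   `modal_length` (integer vector).
#' @export
srna_length_spectrum <- function(read_lengths) {
  if (length(read_lengths) == 0L) stop("empty length list", call. = FALSE)
  if (any(read_lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  t <- table(read_lengths)
  spectrum <- data.frame(length = as.integer(names(t)),
                         count = as.integer(t))
  list(spectrum = spectrum,
       modal_length = spectrum$length[spectrum$count == max(spectrum$count)])
}
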