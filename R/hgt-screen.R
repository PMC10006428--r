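# Average-bitscore (ABV) screen for horizontal gene transfer. Each query
# protein is searched against three database partitions: an out-group
# (prokaryotes/fungi), a mid-group (non-gymnosperm plants) and an in-group
# (gymnosperms). Per database, hits are reduced to one best hit per species,
# capped at 100, and averaged; a query whose out-group ABV exceeds its
# mid-group ABV is a transfer candidate, to be confirmed by phylogeny
# externally.

# deterministic hit order: bitscore desc, then evalue asc, then subject id
.order_hits <- function(hits) {
  hits[order(-hits$bitscore, hits$evalue, hits$subject_id), , drop = FALSE]
}

#' Keep the single best hit per species
#'
#' Highest bitscore wins; ties break by lower e-value, then lexicographic
#' subject id, making the result invariant to input row order.
#'
#' @param hits data.frame of hits sharing one query and one database
#'   (`species`, `bitscore`, `evalue`, `subject_id` columns).
#' @return the filtered hits.
#' @export
best_hit_per_species <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  h <- .order_hits(hits)
  h[!duplicated(h$species), , drop = FALSE]
}

#' Cap the retained hits per database
#'
#' Keeps the top `cap` hits by bitscore (same deterministic tie order as
#' [best_hit_per_species()]). The screen's rule: no more than 100 hits, one
#' per species, per database.
#'
#' @param hits data.frame of one-hit-per-species rows.
#' @param cap maximum hits retained (default 100).
#' @return the truncated hits.
#' @export
truncate_top_hits <- function(hits, cap = 100) {
  if (nrow(hits) <= cap) return(.order_hits(hits))
  head(.order_hits(hits), cap)
}

#' Average bitscore value (ABV)
#'
#' @param hits data.frame of kept hits.
#' @return arithmetic mean bitscore, or `NA` when there are no hits (a
#'   missing ABV, never zero).
#' @export
compute_abv <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NA_real_)
  mean(hits$bitscore)
}

#' Screen queries for horizontal-transfer candidates
#'
#' Per query and database partition: [best_hit_per_species()], then
#' [truncate_top_hits()], then [compute_abv()]. A query is a candidate when
#' it has an out-group ABV supported by at least `min_out_hits` kept hits and
#' either its mid-group ABV is missing (flagged `mid_absent` — a classic HGT
#' signature but contamination-prone) or the out-group ABV exceeds it.
#' Queries with in-group hits only are labelled `no_signal`.
#'
#' @param hits data.frame of e-value-filtered hits over all three databases,
#'   with columns `query_id`, `subject_id`, `species`, `db_class`
#'   (`out`/`mid`/`in`), `bitscore`, `evalue` — e.g. rbind of three
#'   [read_blast_tab()] results or [simulate_hgt_tables()] tables.
#' @param cap hits retained per database (default 100).
#' @param min_out_hits minimum kept out-group hits for candidacy (default 5;
#'   single-hit ABVs are noise-dominated).
#' @return data.frame with one row per query: `query_id`, `abv_out`,
#'   `abv_mid`, `abv_in`, `n_out`, `n_mid`, `n_in`, `is_candidate`,
#'   `status` (`candidate`, `candidate_mid_absent`, `no_signal`, `rejected`),
#'   ordered by query id.
#' @export
screen_candidates <- function(hits, cap = 100, min_out_hits = 5) {
  need <- c("query_id", "species", "db_class", "bitscore", "evalue",
            "subject_id")
  stopifnot(all(need %in% names(hits)))
  if (!all(hits$db_class %in% c("out", "mid", "in"))) {
    stop("'db_class' must be one of out/mid/in", call. = FALSE)
  }
  qids <- sort(unique(hits$query_id))
  rows <- lapply(qids, function(q) {
    hq <- hits[hits$query_id == q, , drop = FALSE]
    kept <- lapply(c(out = "out", mid = "mid", `in` = "in"), function(d) {
      truncate_top_hits(
        best_hit_per_species(hq[hq$db_class == d, , drop = FALSE]), cap)
    })
    abv <- vapply(kept, compute_abv, numeric(1))
    n <- vapply(kept, nrow, integer(1))
    cand <- !is.na(abv[["out"]]) && n[["out"]] >= min_out_hits &&
      (is.na(abv[["mid"]]) || abv[["out"]] > abv[["mid"]])
    status <- if (cand && is.na(abv[["mid"]])) "candidate_mid_absent"
      else if (cand) "candidate"
      else if (is.na(abv[["out"]]) && is.na(abv[["mid"]])) "no_signal"
      else "rejected"
    data.frame(query_id = q, abv_out = abv[["out"]], abv_mid = abv[["mid"]],
               abv_in = abv[["in"]], n_out = n[["out"]], n_mid = n[["mid"]],
               n_in = n[["in"]], is_candidate = cand, status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a screen run
#'
#' Candidate counts and, when a truth table is supplied, confusion-matrix
#' metrics against the planted transfers.
#'
#' @param records data.frame from [screen_candidates()].
#' @param truth optional data.frame with `query_id` and logical
#'   `transferred`.
#' @return list with `n_queries`, `n_candidates`, `n_mid_absent` and, given
#'   truth, `tp`, `fp`, `fn`, `tn`, `precision`, `recall`.
#' @export
summarize_candidates <- function(records, truth = NULL) {
  out <- list(n_queries = nrow(records),
              n_candidates = sum(records$is_candidate),
              n_mid_absent = sum(records$status == "candidate_mid_absent"))
  if (!is.null(truth)) {
    idx <- match(records$query_id, truth$query_id)
    if (anyNA(idx)) stop("truth table does not cover all queries",
                         call. = FALSE)
    pos <- truth$transferred[idx]
    called <- records$is_candidate
    out$tp <- sum(called & pos)
    out$fp <- sum(called & !pos)
    out$fn <- sum(!called & pos)
    out$tn <- sum(!called & !pos)
    out$precision <- if (out$tp + out$fp > 0) out$tp / (out$tp + out$fp)
                     else NA_real_
    out$recall <- if (out$tp + out$fn > 0) out$tp / (out$tp + out$fn)
                  else NA_real_
  }
  out
}
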