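# Whole-genome bisulfite sequencing statistics: conversion-rate estimation
# from the unmethylated lambda spike-in, one-sided binomial methylation
# calling against the non-conversion null with BH FDR control per context,
# count-pooled methylation levels at every aggregation scale (10-kb bins,
# gene metaprofiles, expression ventiles), demethylation-valley discovery and
# cross-sample intersection, and 2x2 chi-squared enrichment.

#' Estimate the bisulfite conversion rate from lambda spike-in cytosines
#'
#' The lambda genome is unmethylated, so every methylated-looking read at a
#' lambda cytosine is a conversion failure: rate = converted reads / total
#' reads, pooled over all lambda cytosines.
#'
#' @param lambda_records CX-style data.frame of lambda cytosines
#'   (`count_m`, `count_total`).
#' @return object of class `conversion_estimate`: list with `converted`,
#'   `total`, `rate`.
#' @export
estimate_conversion_rate <- function(lambda_records) {
  total <- sum(lambda_records$count_total)
  if (is.na(total) || total <= 0) {
    stop("zero total coverage at lambda cytosines", call. = FALSE)
  }
  converted <- total - sum(lambda_records$count_m)
  structure(list(converted = converted, total = total,
                 rate = converted / total),
            class = "conversion_estimate")
}

#' @export
print.conversion_estimate <- function(x, ...) {
  cat(sprintf("bisulfite conversion rate: %.4f (%d / %d reads)\n",
              x$rate, x$converted, x$total))
  invisible(x)
}

#' Call methylated cytosines with a binomial test and FDR control
#'
#' Per site, the one-sided upper-tail binomial p-value of observing at least
#' `count_m` methylated reads in `count_total` reads under the null success
#' probability `1 - conversion rate` (non-conversion alone). P-values are
#' Benjamini-Hochberg adjusted within each context class; a site is called
#' methylated when q < `alpha`.
#'
#' @param records CX-style data.frame of cytosines.
#' @param conversion a `conversion_estimate` (or a numeric rate in `[0, 1]`).
#' @param alpha FDR threshold (default 0.05).
#' @param min_coverage minimum `count_total` for a site to be tested
#'   (default 4); lower-coverage sites are dropped from the output.
#' @return data.frame: the tested records plus `p_value`, `q_value`,
#'   `is_methylated`.
#' @export
call_methylated_sites <- function(records, conversion, alpha = 0.05,
                                  min_coverage = 4) {
  rate <- if (inherits(conversion, "conversion_estimate")) conversion$rate
          else conversion
  .check_scalar(rate, "conversion rate", lower = 0, upper = 1)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  }
  r <- records[records$count_total >= min_coverage, , drop = FALSE]
  p0 <- 1 - rate
  if (p0 == 0) {
    p <- ifelse(r$count_m > 0, 0, 1)
  } else {
    p <- pbinom(r$count_m - 1L, r$count_total, p0, lower.tail = FALSE)
  }
  r$p_value <- p
  r$q_value <- stats::ave(p, r$context,
                          FUN = function(x) p.adjust(x, method = "BH"))
  r$is_methylated <- r$q_value < alpha
  rownames(r) <- NULL
  r
}

#' Pooled methylation level of a set of cytosines
#'
#' Count-weighted pooling: sum of methylated counts over sum of total counts
#' (the window-level formula), not the mean of per-site levels.
#'
#' @param records CX-style data.frame.
#' @return the pooled level in `[0, 1]`, or `NA` when pooled coverage is 0.
#' @export
methylation_level <- function(records) {
  total <- sum(records$count_total)
  if (length(total) == 0L || is.na(total) || total == 0) return(NA_real_)
  sum(records$count_m) / total
}

#' Per-context methylation levels in fixed genomic bins
#'
#' Divides each chromosome into non-overlapping bins (default 10 kb, last
#' partial bin retained) and reports the count-pooled level per context per
#' bin. Bins without covered cytosines get `NA`, not zero.
#'
#' @param records CX-style data.frame.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param bin bin width in bp (default 10000).
#' @param contexts contexts to report.
#' @return data.frame with `chrom`, `start`, `end` (1-based closed),
#'   `context`, `n_sites`, `level`.
#' @export
binned_levels <- function(records, chrom_sizes, bin = 10000,
                          contexts = .methylation_contexts) {
  .check_scalar(bin, "bin", lower = 0, strict_lower = TRUE)
  if (is.null(names(chrom_sizes))) {
    stop("'chrom_sizes' must be named", call. = FALSE)
  }
  grid <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    n_bins <- max(1L, as.integer(ceiling(chrom_sizes[[ch]] / bin)))
    data.frame(chrom = ch, bin_idx = seq_len(n_bins) - 1L,
               stringsAsFactors = FALSE)
  }))
  grid <- merge(grid, data.frame(context = contexts), by = NULL)
  r <- records[records$count_total > 0 & records$context %in% contexts, ,
               drop = FALSE]
  r$bin_idx <- (r$pos - 1L) %/% bin
  if (nrow(r) == 0L) {
    agg <- data.frame(chrom = character(), bin_idx = numeric(),
                      context = character(), count_m = numeric(),
                      count_total = numeric(), n_sites = numeric())
  } else {
    agg <- aggregate(cbind(count_m, count_total, n_sites = 1) ~
                       chrom + bin_idx + context, data = r, FUN = sum)
  }
  out <- merge(grid, agg, by = c("chrom", "bin_idx", "context"), all.x = TRUE)
  out$n_sites[is.na(out$n_sites)] <- 0L
  out$level <- ifelse(is.na(out$count_total) | out$count_total == 0,
                      NA_real_, out$count_m / out$count_total)
  out$start <- out$bin_idx * bin + 1
  out$end <- pmin(out$start + bin - 1,
                  unname(chrom_sizes[out$chrom]))
  out <- out[order(out$chrom, out$bin_idx, out$context),
             c("chrom", "start", "end", "context", "n_sites", "level")]
  rownames(out) <- NULL
  out
}

# map cytosines of one chromosome onto one gene's segments; returns a
# data.frame of (segment, bin, context, count_m, count_total) contributions
.gene_segment_hits <- function(r, gene, exons, flank, n_bins) {
  ch <- as.character(seqnames(gene))
  minus <- as.character(strand(gene)) == "-"
  gs <- start(gene); ge <- end(gene)
  res <- list()
  add <- function(segment, pos_frac, sel) {
    if (!any(sel)) return()
    frac <- pos_frac[sel]
    if (minus) frac <- 1 - frac
    bin <- pmin(n_bins, floor(frac * n_bins) + 1L)
    res[[length(res) + 1L]] <<- data.frame(
      segment = segment, bin = bin, context = r$context[sel],
      count_m = r$count_m[sel], count_total = r$count_total[sel],
      stringsAsFactors = FALSE)
  }
  # flanks: 'upstream' is 5' of the gene in transcription orientation
  up <- if (minus) c(ge + 1, ge + flank) else c(gs - flank, gs - 1)
  dn <- if (minus) c(gs - flank, gs - 1) else c(ge + 1, ge + flank)
  in_up <- r$pos >= up[1] & r$pos <= up[2]
  # fraction measured outward->gene for upstream, gene->outward downstream
  frac_up <- (r$pos - up[1] + 0.5) / flank
  add("upstream", frac_up, in_up)
  in_dn <- r$pos >= dn[1] & r$pos <= dn[2]
  frac_dn <- (r$pos - dn[1] + 0.5) / flank
  add("downstream", frac_dn, in_dn)

  exs <- start(exons); exe <- end(exons)  # sorted by start
  exw <- exe - exs + 1L
  excum <- cumsum(c(0L, exw[-length(exw)]))
  exlen <- sum(exw)
  ex_idx <- rep(NA_integer_, nrow(r))
  for (j in seq_along(exs)) {
    hit <- r$pos >= exs[j] & r$pos <= exe[j]
    ex_idx[hit] <- j
  }
  in_ex <- !is.na(ex_idx)
  off <- ifelse(in_ex, excum[ex_idx] + (r$pos - exs[ex_idx]), NA_real_)
  add("exon", (off + 0.5) / exlen, in_ex)

  if (length(exs) > 1L) {
    ins <- exe[-length(exe)] + 1L
    ine <- exs[-1] - 1L
    keep <- ine >= ins
    ins <- ins[keep]; ine <- ine[keep]
    if (length(ins)) {
      inw <- ine - ins + 1L
      incum <- cumsum(c(0L, inw[-length(inw)]))
      inlen <- sum(inw)
      int_idx <- rep(NA_integer_, nrow(r))
      for (j in seq_along(ins)) {
        hit <- r$pos >= ins[j] & r$pos <= ine[j]
        int_idx[hit] <- j
      }
      in_int <- !is.na(int_idx)
      ioff <- ifelse(in_int, incum[int_idx] + (r$pos - ins[int_idx]),
                     NA_real_)
      add("intron", (ioff + 0.5) / inlen, in_int)
    }
  }
  if (length(res)) do.call(rbind, res) else NULL
}

#' Gene metaprofile of methylation levels
#'
#' Pools methylation over all genes into a strand-aware positional profile:
#' fixed-width upstream and downstream flanks plus exonic and intronic
#' coordinates each scaled into `n_bins` bins (upstream = 5' of the gene).
#' Levels are count-pooled across genes per bin per context.
#'
#' @param records CX-style data.frame.
#' @param genes a `gene_models` object from [read_gff_genes()].
#' @param flank flank width in bp (default 2000).
#' @param n_bins bins per segment (default 10).
#' @param contexts contexts to report.
#' @return data.frame with `segment` (upstream/exon/intron/downstream),
#'   `bin`, `context`, `n_obs` (pooled read count), `level`; ordered 5' to
#'   3'. Genes on chromosomes absent from `records` are skipped (their count
#'   is reported in a message).
#' @export
gene_metaprofile <- function(records, genes, flank = 2000, n_bins = 10,
                             contexts = .methylation_contexts) {
  stopifnot(inherits(genes, "gene_models"))
  if (length(genes$genes) == 0L) stop("no genes", call. = FALSE)
  r_all <- records[records$count_total > 0 &
                     records$context %in% contexts, , drop = FALSE]
  by_chrom <- split(r_all, r_all$chrom)
  skipped <- 0L
  parts <- list()
  for (i in seq_along(genes$genes)) {
    g <- genes$genes[i]
    ch <- as.character(seqnames(g))
    if (is.null(by_chrom[[ch]])) {
      skipped <- skipped + 1L
      next
    }
    parts[[length(parts) + 1L]] <-
      .gene_segment_hits(by_chrom[[ch]], g, genes$exons[[i]], flank, n_bins)
  }
  if (skipped > 0L) message(skipped, " gene(s) on chromosomes without data")
  segs <- c("upstream", "exon", "intron", "downstream")
  grid <- expand.grid(segment = segs, bin = seq_len(n_bins),
                      context = contexts, stringsAsFactors = FALSE)
  hits <- do.call(rbind, parts)
  if (is.null(hits) || nrow(hits) == 0L) {
    grid$n_obs <- 0
    grid$level <- NA_real_
  } else {
    agg <- aggregate(cbind(count_m, count_total) ~ segment + bin + context,
                     data = hits, FUN = sum)
    grid <- merge(grid, agg, by = c("segment", "bin", "context"),
                  all.x = TRUE)
    grid$n_obs <- ifelse(is.na(grid$count_total), 0, grid$count_total)
    grid$level <- ifelse(grid$n_obs > 0, grid$count_m / grid$count_total,
                         NA_real_)
    grid$count_m <- grid$count_total <- NULL
  }
  grid$segment <- factor(grid$segment, levels = segs)
  grid <- grid[order(grid$segment, grid$bin, grid$context), ]
  rownames(grid) <- NULL
  grid
}

#' Gene-body methylation by expression ventile
#'
#' Ranks genes by expression, splits them into `n_groups` equal-size groups
#' (stable tie order by gene id) and reports, per group, the median TPM and
#' the count-pooled methylation level over all exonic cytosines per context
#' (the gene-body-methylation-versus-expression profile).
#'
#' @param records CX-style data.frame.
#' @param genes a `gene_models` object.
#' @param expression data.frame with `gene_id` and `tpm` (several rows per
#'   gene are averaged).
#' @param n_groups number of expression groups (default 20 = ventiles).
#' @param contexts contexts to report.
#' @return data.frame with `group`, `n_genes`, `median_tpm`, `context`,
#'   `level`.
#' @export
expression_ventile_gbm <- function(records, genes, expression,
                                   n_groups = 20,
                                   contexts = .methylation_contexts) {
  stopifnot(inherits(genes, "gene_models"),
            all(c("gene_id", "tpm") %in% names(expression)))
  if (any(expression$tpm < 0) || any(!is.finite(expression$tpm))) {
    stop("TPM values must be finite and >= 0", call. = FALSE)
  }
  expr <- aggregate(tpm ~ gene_id, data = expression, FUN = mean)
  gids <- intersect(names(genes$genes), expr$gene_id)
  if (n_groups > length(gids)) {
    stop("'n_groups' exceeds the number of genes with expression",
         call. = FALSE)
  }
  expr <- expr[match(gids, expr$gene_id), ]
  o <- order(expr$tpm, expr$gene_id)
  gids <- gids[o]
  tpm <- expr$tpm[o]
  grp <- ceiling(seq_along(gids) * n_groups / length(gids))

  r <- records[records$count_total > 0 &
                 records$context %in% contexts, , drop = FALSE]
  per_gene <- lapply(gids, function(gid) {
    g <- genes$genes[gid]
    e <- genes$exons[[gid]]
    sel <- r$chrom == as.character(seqnames(g)) & r$pos >= start(g) &
      r$pos <= end(g)
    rr <- r[sel, , drop = FALSE]
    if (nrow(rr)) {
      inx <- rep(FALSE, nrow(rr))
      for (j in seq_along(e)) {
        inx <- inx | (rr$pos >= start(e)[j] & rr$pos <= end(e)[j])
      }
      rr <- rr[inx, , drop = FALSE]
    }
    rr
  })
  out <- list()
  for (g in seq_len(n_groups)) {
    members <- which(grp == g)
    pooled <- do.call(rbind, per_gene[members])
    for (ctx in contexts) {
      sub <- pooled[pooled$context == ctx, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        group = g, n_genes = length(members),
        median_tpm = stats::median(tpm[members]), context = ctx,
        level = methylation_level(sub), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Detect demethylation valleys (DMVs)
#'
#' A covered cytosine qualifies when its per-site level is below `threshold`
#' (default 5%). Qualifying sites are clustered *within each context*
#' (genomic gap at most `max_gap`), giving per-context low-methylation
#' intervals; a DMV is the base-pair intersection of the contexts' intervals
#' (`mode = "all"`, default: the valley is demethylated in every context
#' with data) or their union (`mode = "any"`). Candidate regions are kept
#' when their span reaches `min_length`, they hold at least `min_sites`
#' covered cytosines, and the pooled level of the merged region stays below
#' the threshold in the required contexts. The per-context clustering makes
#' the call robust to isolated sites whose sampled level crosses the
#' threshold at finite depth.
#'
#' @param records CX-style data.frame.
#' @param threshold per-site and per-region level threshold, in (0, 1).
#' @param min_length minimum region span in bp (default 1000).
#' @param min_sites minimum covered cytosines in the region (default 10).
#' @param max_gap maximum gap between qualifying sites of one context in one
#'   interval (default 2000).
#' @param min_coverage minimum coverage for a site to qualify (default 4).
#' @param mode `"all"` (default) or `"any"`: how the per-context intervals
#'   combine.
#' @return a [GenomicRanges::GRanges] of DMVs with metadata `n_sites`,
#'   `level_cg`, `level_chg`, `level_chh`.
#' @export
detect_dmv <- function(records, threshold = 0.05, min_length = 1000,
                       min_sites = 10, max_gap = 2000, min_coverage = 4,
                       mode = c("all", "any")) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("'threshold' must be in (0, 1)", call. = FALSE)
  }
  covered <- records[records$count_total >= min_coverage, , drop = FALSE]
  qual <- covered$count_m / covered$count_total < threshold
  cluster_ranges <- function(pos) {
    pos <- sort(pos)
    cl <- cumsum(c(TRUE, diff(pos) > max_gap))
    lo <- tapply(pos, cl, min)
    hi <- tapply(pos, cl, max)
    IRanges(as.integer(lo), as.integer(hi))
  }
  regions <- list()
  for (ch in unique(covered$chrom)) {
    on_ch <- covered$chrom == ch
    ctx_present <- intersect(.methylation_contexts,
                             unique(covered$context[on_ch]))
    per_ctx <- lapply(ctx_present, function(ctx) {
      qpos <- covered$pos[on_ch & qual & covered$context == ctx]
      if (length(qpos) == 0L) IRanges() else cluster_ranges(qpos)
    })
    cand <- if (mode == "all") Reduce(IRanges::intersect, per_ctx)
            else IRanges::reduce(do.call(c, per_ctx))
    if (is.null(cand) || length(cand) == 0L) next
    for (k in seq_along(cand)) {
      lo <- start(cand)[k]; hi <- end(cand)[k]
      if (hi - lo + 1 < min_length) next
      inside <- covered[on_ch & covered$pos >= lo & covered$pos <= hi, ,
                        drop = FALSE]
      if (nrow(inside) < min_sites) next
      ctx_level <- vapply(.methylation_contexts, function(ctx) {
        methylation_level(inside[inside$context == ctx, , drop = FALSE])
      }, numeric(1))
      present <- !is.na(ctx_level)
      ok <- if (mode == "all") all(ctx_level[present] < threshold)
            else any(ctx_level[present] < threshold)
      if (!any(present) || !ok) next
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = lo, end = hi, n_sites = nrow(inside),
        level_cg = ctx_level[["CG"]], level_chg = ctx_level[["CHG"]],
        level_chh = ctx_level[["CHH"]], stringsAsFactors = FALSE)
    }
  }
  if (length(regions) == 0L) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(n_sites = integer(),
                                      level_cg = numeric(),
                                      level_chg = numeric(),
                                      level_chh = numeric())
    return(gr)
  }
  d <- do.call(rbind, regions)
  gr <- GRanges(d$chrom, IRanges(d$start, d$end))
  mcols(gr) <- d[, c("n_sites", "level_cg", "level_chg", "level_chh")]
  sort(gr)
}

#' Intersect DMV sets across samples
#'
#' Base-pair intersection of the union-intervals of each sample's DMV set;
#' intersected pieces shorter than `min_length` are dropped. This is the
#' cross-sample "common DMV" operation.
#'
#' @param dmv_sets list (length >= 2) of `GRanges` DMV sets.
#' @param min_length minimum retained piece length (default 1000).
#' @return a `GRanges` of common intervals.
#' @export
common_dmvs <- function(dmv_sets, min_length = 1000) {
  if (length(dmv_sets) < 2L) stop("need at least two DMV sets", call. = FALSE)
  acc <- reduce(dmv_sets[[1]])
  for (s in dmv_sets[-1]) {
    acc <- GenomicRanges::intersect(acc, reduce(s), ignore.strand = TRUE)
  }
  acc[width(acc) >= min_length]
}

#' Flag genes overlapping DMVs
#'
#' A gene is DMV-associated when its span overlaps any DMV by at least 1 bp.
#'
#' @param dmvs a `GRanges` of DMVs.
#' @param genes a `gene_models` object or a `GRanges` of gene spans.
#' @return data.frame with `gene_id` and `in_dmv`.
#' @export
annotate_dmv_genes <- function(dmvs, genes) {
  gr <- if (inherits(genes, "gene_models")) genes$genes else genes
  ids <- if (!is.null(names(gr))) names(gr) else as.character(seq_along(gr))
  data.frame(gene_id = ids,
             in_dmv = overlapsAny(gr, dmvs, ignore.strand = TRUE),
             stringsAsFactors = FALSE)
}

#' 2x2 chi-squared enrichment test
#'
#' Pearson chi-squared without continuity correction on the 2x2 contingency
#' table (e.g. transcription-factor genes inside/outside DMVs against all
#' other genes).
#'
#' @param in_class_in_dmv,in_class_out,out_class_in_dmv,out_class_out the
#'   four cell counts.
#' @return list with `chi2`, `df` (= 1), `p`.
#' @export
enrichment_chi2 <- function(in_class_in_dmv, in_class_out,
                            out_class_in_dmv, out_class_out) {
  m <- matrix(c(in_class_in_dmv, in_class_out,
                out_class_in_dmv, out_class_out), nrow = 2, byrow = TRUE)
  if (any(m < 0)) stop("cell counts must be >= 0", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal in the 2x2 table", call. = FALSE)
  }
  ct <- chisq.test(m, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = 1L, p = unname(ct$p.value))
}
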