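# Independent oracles and small fixture builders used across the suite.

# N50 by definition: the largest length L present such that contigs of
# length >= L sum to at least half the total.
brute_n50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  stop("unreachable")
}

# Benjamini-Hochberg by its definition: sort, scale by n/rank, enforce
# monotonicity from the largest p downward, restore input order.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) {
    if (n == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Global alignment score by exhaustive recursion (no memoization; inputs are
# a few bases long).
align_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      best <- max(best,
                  rec(i - 1, j - 1) + if (av[i] == bv[j]) match else mismatch)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(av), length(bv))
}

# "no more than `cap` hits, one per species" by brute force: every species'
# single best hit (bitscore, then evalue, then subject id), then the top
# `cap` of those.
brute_species_cap <- function(hits, cap) {
  keep <- lapply(split(hits, hits$species), function(h) {
    h[order(-h$bitscore, h$evalue, h$subject_id), ][1, ]
  })
  kept <- do.call(rbind, keep)
  kept <- kept[order(-kept$bitscore, kept$evalue, kept$subject_id), ]
  head(kept, cap)
}

# assemble a gene_models object directly (bypassing GFF) for fixtures
make_gene_models <- function(gene_df, exon_list) {
  genes <- GenomicRanges::GRanges(gene_df$chrom,
                                  IRanges::IRanges(gene_df$start,
                                                   gene_df$end),
                                  strand = gene_df$strand)
  genes$gene_id <- gene_df$gene_id
  genes$transcript_id <- paste0(gene_df$gene_id, ".t1")
  names(genes) <- gene_df$gene_id
  exons <- GenomicRanges::GRangesList(lapply(seq_len(nrow(gene_df)),
    function(i) {
      e <- exon_list[[i]]
      GenomicRanges::GRanges(gene_df$chrom[i],
                             IRanges::IRanges(e$start, e$end),
                             strand = gene_df$strand[i])
    }))
  names(exons) <- gene_df$gene_id
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

# cytosine records at fixed positions with exact counts
make_cx <- function(pos, count_m, count_total, context = "CG",
                    chrom = "chr1", strand = "+") {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             count_m = count_m, count_total = count_total,
             coverage_zero = count_total == 0, stringsAsFactors = FALSE)
}

# Jaccard index of two 1-based closed intervals
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  uni <- (e1 - s1 + 1) + (e2 - s2 + 1) - inter
  inter / uni
}
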