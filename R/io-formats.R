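# Readers/writers for the external formats the pipeline touches: FASTA,
# Bismark-style CX reports, GFF3 gene models, BLAST outfmt-6 tables, BED.
# Internal interval convention is the Bioconductor one (GRanges, 1-based
# closed); conversion to/from 0-based half-open happens only at the BED
# boundary. Readers are strict: malformed rows raise line-numbered errors.

#' Read a FASTA file into a DNAStringSet
#'
#' Residues are uppercased; record order is preserved; ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path path to a (multi-)FASTA file.
#' @return a [Biostrings::DNAStringSet] named by record id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("FASTA format error: '", path, "' contains no records", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) stop("FASTA record with empty id", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs a named [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named", call. = FALSE)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a per-cytosine CX report
#'
#' Expects the 7-column Bismark CX layout: chrom, 1-based position, strand,
#' methylated count, unmethylated count, context (CG/CHG/CHH), trinucleotide.
#' Rows with zero total coverage are retained and flagged `coverage_zero`;
#' downstream level computations exclude them via their zero weight.
#'
#' @param path path to a tab-separated CX report (no header).
#' @return a data.frame with columns `chrom`, `pos`, `strand`, `context`,
#'   `count_m`, `count_total`, `coverage_zero`.
#' @export
read_cx_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE,
                   col.names = c("chrom", "pos", "strand", "count_m",
                                 "count_um", "context", "trinucleotide"),
                   colClasses = c("character", "integer", "character",
                                  "integer", "integer", "character",
                                  "character"))
  bad <- which(!(dt$context %in% .methylation_contexts))
  if (length(bad)) {
    stop("unknown context token '", dt$context[bad[1]], "' at line ", bad[1],
         call. = FALSE)
  }
  bad <- which(dt$count_m < 0L | dt$count_um < 0L)
  if (length(bad)) {
    stop("negative count at line ", bad[1], call. = FALSE)
  }
  bad <- which(!(dt$strand %in% c("+", "-")))
  if (length(bad)) {
    stop("invalid strand '", dt$strand[bad[1]], "' at line ", bad[1],
         call. = FALSE)
  }
  total <- dt$count_m + dt$count_um
  data.frame(chrom = dt$chrom, pos = dt$pos, strand = dt$strand,
             context = dt$context, count_m = dt$count_m, count_total = total,
             coverage_zero = total == 0L, stringsAsFactors = FALSE)
}

#' Write cytosine records as a CX report
#'
#' @param records data.frame as returned by [read_cx_report()] or
#'   [simulate_methylome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(records, path) {
  out <- data.frame(records$chrom, records$pos, records$strand,
                    records$count_m, records$count_total - records$count_m,
                    records$context,
                    if ("trinucleotide" %in% names(records))
                      records$trinucleotide else records$context)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon features, keeps the longest transcript of each gene
#' (length = summed exon widths; ties by transcript id), and validates that
#' exons lie within their parent span on the same chromosome and strand.
#'
#' @param path path to a GFF3 file.
#' @return an object of class `gene_models`: a list with `genes` (a
#'   [GenomicRanges::GRanges] named by gene id, with `gene_id` and
#'   `transcript_id` metadata) and `exons` (a `GRangesList`, one element per
#'   gene, exons sorted by start).
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path, call. = FALSE)
  if (any(is.na(genes$ID)) || any(!nzchar(genes$ID))) {
    stop("gene feature missing ID attribute", call. = FALSE)
  }
  tx <- gr[gr$type %in% c("mRNA", "transcript")]
  exons <- gr[gr$type == "exon"]
  first_parent <- function(x) {
    p <- as.character(S4Vectors::unstrsplit(x$Parent, sep = ","))
    sub(",.*$", "", p)
  }
  if (length(tx)) {
    if (any(is.na(tx$ID)) || any(!nzchar(tx$ID))) {
      stop("transcript feature missing ID attribute", call. = FALSE)
    }
    tx_parent <- first_parent(tx)
    ex_parent <- first_parent(exons)
    tx_of_gene <- split(tx$ID, tx_parent)
  } else {
    # exon-on-gene GFFs: treat the gene itself as its single transcript
    tx <- genes
    tx_parent <- genes$ID
    ex_parent <- first_parent(exons)
    tx_of_gene <- split(genes$ID, genes$ID)
  }
  if (length(exons) == 0L) stop("no exon features in ", path, call. = FALSE)
  if (any(is.na(ex_parent) | !nzchar(ex_parent))) {
    stop("exon feature missing Parent attribute", call. = FALSE)
  }
  ex_by_tx <- split(exons, factor(ex_parent, levels = tx$ID))
  tx_len <- sum(width(ex_by_tx))

  keep_gene <- function(gid) {
    tids <- tx_of_gene[[gid]]
    if (is.null(tids) || length(tids) == 0L) {
      stop("gene '", gid, "' has no transcript", call. = FALSE)
    }
    lens <- tx_len[tids]
    if (all(lens == 0L)) stop("gene '", gid, "' has no exons", call. = FALSE)
    tids[order(-lens, tids)][1L]
  }
  gids <- genes$ID
  kept_tx <- vapply(gids, keep_gene, character(1))
  ex_kept <- ex_by_tx[kept_tx]
  names(ex_kept) <- gids
  ex_kept <- S4Vectors::endoapply(ex_kept, function(e) sort(e))

  # validation: exons within the gene span, same chrom and strand
  for (i in seq_along(gids)) {
    g <- genes[i]
    e <- ex_kept[[i]]
    if (length(e) == 0L) stop("gene '", gids[i], "' has no exons", call. = FALSE)
    if (!all(as.character(seqnames(e)) == as.character(seqnames(g))) ||
        !all(as.character(strand(e)) == as.character(strand(g)))) {
      stop("exon of gene '", gids[i], "' on a different chrom/strand",
           call. = FALSE)
    }
    if (any(start(e) < start(g)) || any(end(e) > end(g))) {
      stop("exon outside span of gene '", gids[i], "'", call. = FALSE)
    }
  }
  genes$gene_id <- gids
  genes$transcript_id <- unname(kept_tx)
  names(genes) <- gids
  structure(list(genes = genes, exons = ex_kept), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "genes,",
      sum(lengths(x$exons)), "exons (longest transcript per gene)\n")
  invisible(x)
}

#' Read a BLAST tabular (outfmt 6) file and annotate species and database
#'
#' Columns are the 12 standard outfmt-6 fields. Every subject id must be
#' resolvable through the species map; hits above the e-value cutoff are
#' dropped (the screen's pre-filter).
#'
#' @param path path to the outfmt-6 file (may be empty).
#' @param species_map_path TSV with header columns `subject_id`, `species`.
#' @param db_class one of `"out"`, `"mid"`, `"in"`: which database partition
#'   this file was searched against.
#' @param evalue_cutoff keep hits with `evalue <= evalue_cutoff`
#'   (default `1e-5`).
#' @return a data.frame of hits with `query_id`, `subject_id`, `species`,
#'   `db_class`, `bitscore`, `evalue` (plus the remaining outfmt-6 columns).
#' @export
read_blast_tab <- function(path, species_map_path, db_class,
                           evalue_cutoff = 1e-5) {
  db_class <- match.arg(db_class, c("out", "mid", "in"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  empty <- data.frame(matrix(nrow = 0, ncol = 12,
                             dimnames = list(NULL, cols)))
  if (file.size(path) == 0L) {
    hits <- empty
  } else {
    hits <- read.table(path, sep = "\t", header = FALSE, quote = "",
                       comment.char = "", stringsAsFactors = FALSE,
                       col.names = cols)
  }
  map <- read.table(species_map_path, sep = "\t", header = TRUE,
                    quote = "", stringsAsFactors = FALSE)
  if (!all(c("subject_id", "species") %in% names(map))) {
    stop("species map needs 'subject_id' and 'species' columns",
         call. = FALSE)
  }
  idx <- match(hits$subject_id, map$subject_id)
  if (anyNA(idx)) {
    missing <- unique(hits$subject_id[is.na(idx)])
    stop("subject id(s) missing from species map: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  hits$species <- map$species[idx]
  hits$db_class <- rep(db_class, nrow(hits))
  hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
}

#' Export intervals as BED
#'
#' Converts internal 1-based closed [GenomicRanges::GRanges] to the 0-based
#' half-open BED convention (BED6 when `score`/strand are available).
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  nm <- if (!is.null(names(gr))) names(gr) else rep(".", length(gr))
  sc <- if ("score" %in% names(mcols(gr))) mcols(gr)$score else
    rep(0, length(gr))
  out <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                    nm, sc, as.character(strand(gr)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file into GRanges
#'
#' @param path BED3/BED6 path.
#' @return a `GRanges` in the internal 1-based closed convention.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   stringsAsFactors = FALSE)
  strand <- if (ncol(dt) >= 6) dt[[6]] else "*"
  gr <- GRanges(dt[[1]], IRanges(dt[[2]] + 1L, dt[[3]]), strand = strand)
  if (ncol(dt) >= 4) names(gr) <- dt[[4]]
  if (ncol(dt) >= 5) mcols(gr)$score <- dt[[5]]
  gr
}
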