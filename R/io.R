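#' Read a genome (or read set) from FASTA
#'
#' Sequences are uppercased and `U` is mapped to `T` so that one canonical
#' DNA alphabet (`A`, `C`, `G`, `T`, `N`) flows through the pipeline.
#' Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("read_fasta: no such file: %s", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stopf("read_fasta: duplicate sequence id: %s",
          ids[duplicated(ids)][1])
  seqs <- chartr("u", "t", toupper(as.character(x)))
  seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) == 0L))
    stopf("read_fasta: empty sequence: %s", ids[nchar(seqs) == 0L][1])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    off <- setdiff(unique(strsplit(seqs[bad][1], "")[[1]]),
                   c("A", "C", "G", "T", "N"))
    stopf("read_fasta: illegal character '%s' in sequence %s",
          off[1], ids[bad][1])
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read flat gene models from GFF3
#'
#' Reads flat `gene` (or `transcribed_region`) features; hierarchical
#' gene/mRNA/CDS records are out of scope. Coordinates are kept 1-based
#' inclusive exactly as in the file; the source column is recorded as the
#' predictor tag (a leading `"pred"` prefix is stripped, so source `predA`
#' becomes predictor `A`). Genes shorter than 180 nt are flagged
#' `sub_minimum` but not removed — filtering happens downstream in
#' [filter_candidates()].
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature types to keep (default `"gene"`).
#' @return A data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand`, `predictors`, `sub_minimum` and, when present in the
#'   file, `accuracy_class`.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stopf("read_gff3: no such file: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stopf("read_gff3: unknown strand symbol on feature %d",
          which(strand == "*")[1])
  ids <- gr$ID %||% gr$Name
  if (is.null(ids)) ids <- sprintf("gene_%04d", seq_along(gr))
  src <- sub("^pred", "", as.character(gr$source))
  out <- data.frame(
    gene_id = as.character(ids),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand,
    predictors = src,
    sub_minimum = BiocGenerics::width(gr) < 180L,
    stringsAsFactors = FALSE)
  if (!is.null(gr$accuracy_class))
    out$accuracy_class <- as.character(gr$accuracy_class)
  rownames(out) <- NULL
  out
}

#' Write gene models (or transcribed contigs) to GFF3
#'
#' @param genes Gene-model data.frame (`gene_id`, `contig_id`, `start`,
#'   `end`, `strand`, optionally `predictors`, `accuracy_class`,
#'   `mean_depth`, `klass`).
#' @param path Output path.
#' @param feature_type GFF3 type column (default `"gene"`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, feature_type = "gene") {
  gr <- genes_to_granges(genes)
  gr$gene_id <- NULL
  gr$source <- factor(genes$predictors %||% rep("strandtag", nrow(genes)))
  gr$type <- factor(rep(feature_type, nrow(genes)))
  gr$ID <- genes$gene_id
  for (col in c("accuracy_class", "klass", "mean_depth"))
    if (!is.null(genes[[col]])) S4Vectors::mcols(gr)[[col]] <- genes[[col]]
  rtracklayer::export(gr, path, format = "gff3")
  # drop the volatile ##date directive so equal inputs give equal bytes
  lines <- readLines(path)
  writeLines(lines[!startsWith(lines, "##date")], path)
  invisible(path)
}

#' Read tabular similarity hits
#'
#' Reads 12-column tab-separated similarity hits (the standard tabular
#' search output: query, subject, percent identity, alignment length,
#' mismatches, gap opens, query start/end, subject start/end, e-value, bit
#' score). Multiple HSP rows per query-subject pair are aggregated into a
#' single hit with `evalue` the minimum over HSPs and `hsp_total_length`
#' the sum of alignment lengths. Self-hits are dropped.
#'
#' @param path Path to the hits file (may be empty).
#' @param seq_lengths Optional sequence lengths, either a named numeric
#'   vector or a 2-column data.frame (id, length). Needed downstream for
#'   coverage ratios in [qualifying_edges()].
#' @return A data.frame with columns `query_id`, `subject_id`, `evalue`,
#'   `hsp_total_length`, `query_length`, `subject_length`.
#' @export
read_hits <- function(path, seq_lengths = NULL) {
  if (!file.exists(path)) stopf("read_hits: no such file: %s", path)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), hsp_total_length = numeric(),
                      query_length = numeric(), subject_length = numeric(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 12L)
    stopf("read_hits: expected 12 tab-separated columns, found %d", ncol(d))
  names(d)[c(1, 2, 4, 11)] <- c("query_id", "subject_id", "aln_len", "evalue")
  if (any(d$evalue < 0))
    stopf("read_hits: negative e-value on row %d", which(d$evalue < 0)[1])
  d <- d[d$query_id != d$subject_id, , drop = FALSE]
  if (nrow(d) == 0L) return(empty)
  key <- paste(d$query_id, d$subject_id, sep = "\r")
  first <- !duplicated(key)
  ev <- tapply(d$evalue, key, min)
  hl <- tapply(d$aln_len, key, sum)
  ord <- key[first]
  out <- data.frame(query_id = d$query_id[first],
                    subject_id = d$subject_id[first],
                    evalue = as.numeric(ev[ord]),
                    hsp_total_length = as.numeric(hl[ord]),
                    stringsAsFactors = FALSE)
  if (is.data.frame(seq_lengths))
    seq_lengths <- setNames(as.numeric(seq_lengths[[2]]),
                            as.character(seq_lengths[[1]]))
  if (!is.null(seq_lengths)) {
    out$query_length <- unname(seq_lengths[out$query_id])
    out$subject_length <- unname(seq_lengths[out$subject_id])
  } else {
    out$query_length <- NA_real_
    out$subject_length <- NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Read rRNA (or other filter) intervals from BED
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges] (1-based inclusive, as usual in R).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("read_bed: no such file: %s", path)
  rtracklayer::import(path, format = "bed")
}

#' Read a pathway membership table
#'
#' @param path 2-column TSV: `pathway_id<TAB>gene_id`, no header.
#' @return data.frame with columns `pathway_id`, `gene_id`.
#' @export
read_pathway_map <- function(path) {
  if (!file.exists(path)) stopf("read_pathway_map: no such file: %s", path)
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(d[, 1:2], c("pathway_id", "gene_id"))
}
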