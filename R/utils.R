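# Internal helpers: coordinate convention and small sequence utilities.
#
# External formats (GFF3, BED output of rtracklayer, all user-facing tables)
# are 1-based inclusive. Internal interval arithmetic, where used, is
# 0-based half-open; the conversion lives in exactly these two functions.

to_zero_based <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

to_one_based <- function(start0, end0) {
  list(start = as.integer(start0) + 1L, end = as.integer(end0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# length (bp) of the longest run of N in each string; 0 when absent
max_n_run <- function(x) {
  vapply(x, function(s) {
    m <- gregexpr("N+", s)[[1]]
    if (m[1] == -1L) 0L else max(attr(m, "match.length"))
  }, integer(1), USE.NAMES = FALSE)
}

# gene-model data.frame -> GRanges (keeps gene_id in mcols)
genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    gene_id = genes$gene_id)
}

# extract the genomic (sense-strand) sequence of each gene as character
gene_sequences <- function(genes, genome) {
  seqs_chr <- as.character(genome)
  out <- substring(seqs_chr[genes$contig_id], genes$start, genes$end)
  minus <- genes$strand == "-"
  if (any(minus)) out[minus] <- revcomp_chr(out[minus])
  unname(out)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
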