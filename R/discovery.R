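# Strand-specific transcribed-contig discovery: maximal expressed runs,
# >180-bp filtering, classification against the annotation, genome
# expression coverage, and the per-gene antisense summary.

#' Assemble strand-specific expressed contigs from depth arrays
#'
#' A contig is a maximal run of consecutive bases whose depth on one
#' strand is at least `min_expressed_depth`; a single sub-threshold base
#' terminates the run (no gap bridging). Runs strictly longer than 180 bp
#' (length >= `min_contig_bp`) are retained with their mean depth.
#'
#' @param depth Per-contig list of `+`/`-` integer depth vectors (as from
#'   [coverage_and_counts()]).
#' @param config A [pipeline_config()].
#' @return data.frame: `contig_id`, `strand`, `start`, `end`, `length`,
#'   `mean_depth`.
#' @export
expressed_contigs <- function(depth, config = pipeline_config()) {
  out <- list()
  for (cid in names(depth)) {
    for (sd in c("+", "-")) {
      d <- depth[[cid]][[sd]]
      r <- rle(d >= config$min_expressed_depth)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= config$min_contig_bp
      if (!any(keep)) next
      s <- starts[keep]; e <- ends[keep]
      out[[length(out) + 1L]] <- data.frame(
        contig_id = cid, strand = sd, start = s, end = e,
        length = e - s + 1L,
        mean_depth = vapply(seq_along(s), function(i)
          mean(d[s[i]:e[i]]), numeric(1)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      length = integer(), mean_depth = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id, res$start, res$strand), ]
  res$region_id <- sprintf("tr%05d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Classify transcribed contigs against the annotation
#'
#' A contig overlapping (>= 1 bp) a gene on the same strand is
#' `genic_sense`; one overlapping genes only on the opposite strand is
#' `antisense`; one overlapping no gene is `intergenic`. When a contig
#' overlaps genes on both strands the same-strand call wins (conservative
#' against antisense false positives). The "non-coding" tally counts
#' intergenic + antisense contigs only, as genic-sense contigs restate the
#' annotation.
#'
#' @param contigs Output of [expressed_contigs()].
#' @param genes Gene-model data.frame.
#' @return list: `contigs` (with `klass`), `counts` (named vector:
#'   genic_sense, antisense, intergenic, noncoding_total).
#' @export
classify_contigs <- function(contigs, genes) {
  klass <- rep("intergenic", nrow(contigs))
  if (nrow(contigs) && nrow(genes)) {
    cg <- GenomicRanges::GRanges(
      seqnames = contigs$contig_id,
      ranges = IRanges::IRanges(contigs$start, contigs$end),
      strand = contigs$strand)
    gg <- genes_to_granges(genes)
    same <- GenomicRanges::countOverlaps(cg, gg) > 0
    any_ov <- GenomicRanges::countOverlaps(cg, gg, ignore.strand = TRUE) > 0
    klass[any_ov & !same] <- "antisense"
    klass[same] <- "genic_sense"
  }
  contigs$klass <- klass
  counts <- c(genic_sense = sum(klass == "genic_sense"),
              antisense = sum(klass == "antisense"),
              intergenic = sum(klass == "intergenic"))
  counts["noncoding_total"] <- counts["antisense"] + counts["intergenic"]
  list(contigs = contigs, counts = counts)
}

#' Fraction of the stranded genome expressed
#'
#' Bases with depth >= 1 on the plus strand plus those on the minus
#' strand, as a percent of single-strand genome length — the ceiling is
#' therefore 200%.
#'
#' @param depth Per-contig list of `+`/`-` depth vectors.
#' @return Percentage in `[0, 200]`.
#' @export
genome_coverage <- function(depth) {
  covered <- 0; total <- 0
  for (cid in names(depth)) {
    covered <- covered + sum(depth[[cid]][["+"]] >= 1L) +
      sum(depth[[cid]][["-"]] >= 1L)
    total <- total + length(depth[[cid]][["+"]])
  }
  if (total == 0) return(0)
  100 * covered / total
}

#' Per-gene antisense summary across two phases
#'
#' For every gene overlapped by an antisense-classified contig: the
#' largest fraction of the gene span contained in one such contig, the
#' sense and antisense normalized values in both phases, and an
#' inverse-correlation flag set when sense expression decreases while
#' antisense increases from `from` to `to` — the signature of a
#' phase-restricted repressive antisense transcript.
#'
#' @param contigs Classified contigs (with `klass`).
#' @param norm Output of [uq_normalize()].
#' @param genes Gene-model data.frame.
#' @param from,to Sample ids of the two phases.
#' @return data.frame: `gene_id`, `containment`, `sense_uq_from`,
#'   `sense_uq_to`, `antisense_uq_from`, `antisense_uq_to`, `inverse`.
#' @export
antisense_report <- function(contigs, norm, genes, from, to) {
  anti <- contigs[contigs$klass == "antisense", , drop = FALSE]
  empty <- data.frame(gene_id = character(), containment = numeric(),
                      sense_uq_from = numeric(), sense_uq_to = numeric(),
                      antisense_uq_from = numeric(),
                      antisense_uq_to = numeric(), inverse = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(anti) == 0) return(empty)
  ca <- GenomicRanges::GRanges(
    seqnames = anti$contig_id,
    ranges = IRanges::IRanges(anti$start, anti$end))
  gg <- genes_to_granges(genes)
  ov <- GenomicRanges::findOverlaps(ca, gg, ignore.strand = TRUE)
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov); sj <- S4Vectors::subjectHits(ov)
  opp <- anti$strand[qi] != genes$strand[sj]
  qi <- qi[opp]; sj <- sj[opp]
  if (!length(qi)) return(empty)
  ov_len <- pmin(anti$end[qi], genes$end[sj]) -
    pmax(anti$start[qi], genes$start[sj]) + 1L
  frac <- ov_len / (genes$end[sj] - genes$start[sj] + 1L)
  best <- tapply(frac, genes$gene_id[sj], max)
  gids <- names(best)
  nf <- norm[norm$sample_id == from, ]
  nt <- norm[norm$sample_id == to, ]
  mf <- match(gids, nf$gene_id); mt <- match(gids, nt$gene_id)
  out <- data.frame(
    gene_id = gids,
    containment = as.numeric(best),
    sense_uq_from = nf$sense_uq[mf],
    sense_uq_to = nt$sense_uq[mt],
    antisense_uq_from = nf$antisense_uq[mf],
    antisense_uq_to = nt$antisense_uq[mt],
    stringsAsFactors = FALSE)
  out$inverse <- !is.na(out$sense_uq_from) &
    out$sense_uq_to < out$sense_uq_from &
    out$antisense_uq_to > out$antisense_uq_from
  rownames(out) <- NULL
  out
}
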