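# Two-predictor gene-model consensus, accuracy classes, frameshift-artifact
# detection, and codon usage.

ACCURACY_LEVELS <- c("predicted", "hypothetical", "slightly_conserved",
                     "conserved")

#' Filter candidate gene models
#'
#' Retains genes whose genomic span contains fewer than
#' `max_internal_gap_nt` consecutive `N` bases and that comprise at least
#' `min_protein_aa` amino acids (>= 180 nt at the defaults). Everything
#' else is dropped, with the reason recorded in the `"dropped"` attribute.
#'
#' @param genes Gene-model data.frame.
#' @param genome Named [Biostrings::DNAStringSet] (or character) holding
#'   the contigs.
#' @param config A [pipeline_config()].
#' @return The retained subset, with attribute `dropped` (gene_id, reason).
#' @export
filter_candidates <- function(genes, genome, config = pipeline_config()) {
  genome_chr <- as.character(genome)
  lens <- setNames(nchar(genome_chr), names(genome_chr))
  if (any(!genes$contig_id %in% names(lens)) ||
      any(genes$start < 1L) ||
      any(genes$end > lens[genes$contig_id]))
    stopf("filter_candidates: gene outside contig bounds: %s",
          genes$gene_id[which(!genes$contig_id %in% names(lens) |
                                genes$start < 1L |
                                genes$end > lens[genes$contig_id])[1]])
  span <- substring(genome_chr[genes$contig_id], genes$start, genes$end)
  nrun <- max_n_run(span)
  len <- genes$end - genes$start + 1L
  too_short <- len < 3L * config$min_protein_aa
  gappy <- nrun >= config$max_internal_gap_nt
  keep <- !too_short & !gappy
  dropped <- data.frame(
    gene_id = genes$gene_id[!keep],
    reason = ifelse(too_short[!keep], "below_min_aa", "n_gap"),
    stringsAsFactors = FALSE)
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Assign accuracy classes and best homologs
#'
#' A gene is `conserved` when its best hit e-value is at or below
#' `homolog_evalue` (1e-10), `slightly_conserved` when in
#' (`homolog_evalue`, `nonortholog_evalue`], `hypothetical` when it has no
#' qualifying hit but was called by both predictors, and `predicted`
#' otherwise. The best hit's subject and e-value are attached as
#' `best_homolog` / `best_evalue` (recorded for any hit, qualifying or
#' not).
#'
#' @param genes Gene-model data.frame with a `predictors` column
#'   (`"A"`, `"B"`, or `"AB"`).
#' @param hits Similarity hits (as from [read_hits()]), queries being gene
#'   ids; may be `NULL` (no homology evidence).
#' @param config A [pipeline_config()].
#' @return `genes` with `best_homolog`, `best_evalue`, `accuracy_class`.
#' @export
classify_accuracy <- function(genes, hits, config = pipeline_config()) {
  best_e <- rep(NA_real_, nrow(genes))
  best_s <- rep(NA_character_, nrow(genes))
  if (!is.null(hits) && nrow(hits) > 0) {
    ord <- order(hits$query_id, hits$evalue)
    h <- hits[ord, ]
    h <- h[!duplicated(h$query_id), ]
    m <- match(genes$gene_id, h$query_id)
    best_e <- h$evalue[m]
    best_s <- h$subject_id[m]
  }
  both <- genes$predictors == "AB"
  cls <- ifelse(!is.na(best_e) & best_e <= config$homolog_evalue, "conserved",
         ifelse(!is.na(best_e) & best_e <= config$nonortholog_evalue,
                "slightly_conserved",
                ifelse(both, "hypothetical", "predicted")))
  genes$best_homolog <- best_s
  genes$best_evalue <- best_e
  genes$accuracy_class <- cls
  genes
}

#' Merge two predictors' gene sets
#'
#' Models identical in contig, strand, start and end are emitted once as
#' `common` with `predictors = "AB"`. Remaining single-predictor models are
#' kept, except that when an A-only model partially overlaps a B-only model
#' on the same strand, the one with the higher accuracy class survives
#' (ties: the longer model; then predictor A), mirroring the rule that
#' less-accurate partially-overlapping predictions are not analyzed
#' further.
#'
#' @param genes_a,genes_b Filtered gene models from predictors A and B.
#' @param hits Similarity hits used to rank overlapping models (optional).
#' @param config A [pipeline_config()].
#' @return list: `common`, `only_a`, `only_b` (overlap survivors),
#'   `merged` (all retained models, accuracy-classified), and
#'   `dropped_overlap` (loser gene ids).
#' @export
merge_predictions <- function(genes_a, genes_b, hits = NULL,
                              config = pipeline_config()) {
  key <- function(m) paste(m$contig_id, m$strand, m$start, m$end)
  ka <- key(genes_a); kb <- key(genes_b)
  common <- genes_a[ka %in% kb, , drop = FALSE]
  common$predictors <- rep("AB", nrow(common))
  only_a <- genes_a[!ka %in% kb, , drop = FALSE]
  only_b <- genes_b[!kb %in% ka, , drop = FALSE]
  only_a$predictors <- rep("A", nrow(only_a))
  only_b$predictors <- rep("B", nrow(only_b))

  dropped <- character(0)
  if (nrow(only_a) && nrow(only_b)) {
    ca <- classify_accuracy(only_a, hits, config)
    cb <- classify_accuracy(only_b, hits, config)
    gra <- genes_to_granges(ca)
    grb <- genes_to_granges(cb)
    ov <- GenomicRanges::findOverlaps(gra, grb)  # strand-aware by default
    if (length(ov)) {
      ia <- S4Vectors::queryHits(ov); ib <- S4Vectors::subjectHits(ov)
      ra <- match(ca$accuracy_class[ia], ACCURACY_LEVELS)
      rb <- match(cb$accuracy_class[ib], ACCURACY_LEVELS)
      la <- ca$end[ia] - ca$start[ia] + 1L
      lb <- cb$end[ib] - cb$start[ib] + 1L
      b_wins <- (rb > ra) | (rb == ra & lb > la)
      drop_a <- unique(ia[b_wins])
      drop_b <- unique(ib[!b_wins])
      dropped <- unique(c(paste0("A:", ca$gene_id[drop_a]),
                          paste0("B:", cb$gene_id[drop_b])))
      if (length(drop_a)) only_a <- only_a[-drop_a, , drop = FALSE]
      if (length(drop_b)) only_b <- only_b[-drop_b, , drop = FALSE]
    }
  }
  cols <- c("gene_id", "contig_id", "start", "end", "strand", "predictors")
  merged <- rbind(common[, cols], only_a[, cols], only_b[, cols])
  merged <- merged[order(merged$contig_id, merged$start, merged$strand), ]
  rownames(merged) <- NULL
  merged <- classify_accuracy(merged, hits, config)
  for (d in list(common, only_a, only_b)) rownames(d) <- NULL
  list(common = common, only_a = only_a, only_b = only_b,
       merged = merged, dropped_overlap = dropped)
}

#' Detect interrupted and overlapping ORF pairs (frameshift artifacts)
#'
#' Among homolog-bearing genes (best e-value at or below `homolog_evalue`),
#' a pair sharing the same best-homolog subject is *interrupted* when the
#' two genes lie on the same contig and strand with fewer than
#' `interrupted_max_gap_bp` intergenic bases between them (stop of the
#' upstream to start of the downstream, exclusive) and are not truly
#' orthologous to each other — their mutual e-value exceeds
#' `nonortholog_evalue`, or they have no mutual hit. A pair is
#' *overlapping* when the two same-homolog intervals intersect on the same
#' contig. Rates are pair-member counts over the homolog-bearing gene
#' count.
#'
#' @param genes Accuracy-classified gene models (see [classify_accuracy()]).
#' @param hits Similarity hits including any gene-vs-gene rows (used for
#'   the mutual-orthology test); may be `NULL`.
#' @param config A [pipeline_config()].
#' @return list: `interrupted` and `overlapping` pair data.frames, `rates`
#'   (`interrupted_rate`, `overlapping_rate`), `n_homolog_genes`, and
#'   `n_any_hit` (genes with a hit at any e-value, the looser denominator).
#' @export
detect_frameshift_artifacts <- function(genes, hits = NULL,
                                        config = pipeline_config()) {
  if (is.null(genes$best_homolog))
    stopf("detect_frameshift_artifacts: run classify_accuracy() first")
  hb <- genes[!is.na(genes$best_homolog) &
                genes$best_evalue <= config$homolog_evalue, , drop = FALSE]
  n_hb <- nrow(hb)
  mutual <- character(0)
  if (!is.null(hits) && nrow(hits)) {
    ok <- hits$evalue <= config$nonortholog_evalue
    mutual <- c(paste(hits$query_id[ok], hits$subject_id[ok], sep = "\r"),
                paste(hits$subject_id[ok], hits$query_id[ok], sep = "\r"))
  }
  empty <- data.frame(gene_1 = character(), gene_2 = character(),
                      gap_bp = integer(), stringsAsFactors = FALSE)
  interrupted <- empty
  overlapping <- empty[, 1:2]
  if (n_hb >= 2) {
    sp <- split(seq_len(n_hb), hb$best_homolog)
    ints <- list(); ovls <- list()
    for (idx in sp[lengths(sp) >= 2]) {
      pairs <- utils::combn(idx, 2)
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1, k]; j <- pairs[2, k]
        if (hb$contig_id[i] != hb$contig_id[j]) next
        o <- hb$start[i] <= hb$end[j] & hb$start[j] <= hb$end[i]
        if (o) {
          ovls[[length(ovls) + 1L]] <- data.frame(
            gene_1 = hb$gene_id[i], gene_2 = hb$gene_id[j],
            stringsAsFactors = FALSE)
          next
        }
        if (hb$strand[i] != hb$strand[j]) next
        up <- if (hb$start[i] <= hb$start[j]) i else j
        dn <- if (up == i) j else i
        gap <- hb$start[dn] - hb$end[up] - 1L
        if (gap >= config$interrupted_max_gap_bp) next
        is_ortho <- paste(hb$gene_id[i], hb$gene_id[j], sep = "\r") %in% mutual
        if (!is_ortho)
          ints[[length(ints) + 1L]] <- data.frame(
            gene_1 = hb$gene_id[up], gene_2 = hb$gene_id[dn],
            gap_bp = gap, stringsAsFactors = FALSE)
      }
    }
    if (length(ints)) interrupted <- do.call(rbind, ints)
    if (length(ovls)) overlapping <- do.call(rbind, ovls)
  }
  n_int <- length(unique(c(interrupted$gene_1, interrupted$gene_2)))
  n_ovl <- length(unique(c(overlapping$gene_1, overlapping$gene_2)))
  list(interrupted = interrupted, overlapping = overlapping,
       rates = list(
         interrupted_rate = if (n_hb) n_int / n_hb else NA_real_,
         overlapping_rate = if (n_hb) n_ovl / n_hb else NA_real_),
       n_homolog_genes = n_hb,
       n_any_hit = sum(!is.na(genes$best_homolog)))
}

#' Tabulate codon usage
#'
#' Counts all 64 codons over the in-frame gene set and reports, for each
#' codon, its relative frequency among the synonymous codons of its amino
#' acid (stop codons are grouped under `*`). Genes whose length is not a
#' multiple of 3 are skipped with a warning.
#'
#' @param genes Gene-model data.frame.
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @return data.frame: `codon`, `aa`, `count`, `rel_freq` (per-amino-acid
#'   frequencies sum to 1; `NA` for unobserved amino acids).
#' @export
codon_usage <- function(genes, genome) {
  len <- genes$end - genes$start + 1L
  bad <- len %% 3L != 0L
  if (any(bad)) {
    warning(sprintf("codon_usage: skipping %d gene(s) not in frame: %s",
                    sum(bad),
                    paste(utils::head(genes$gene_id[bad], 3), collapse = ", ")))
    genes <- genes[!bad, , drop = FALSE]
  }
  cods <- all_codons()
  counts <- setNames(integer(64), cods)
  if (nrow(genes)) {
    seqs <- gene_sequences(genes, genome)
    for (s in seqs) {
      n <- nchar(s)
      cc <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
      tb <- table(cc)
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
    }
  }
  gc_map <- Biostrings::GENETIC_CODE[cods]
  out <- data.frame(codon = cods, aa = unname(gc_map),
                    count = unname(counts), stringsAsFactors = FALSE)
  aa_tot <- tapply(out$count, out$aa, sum)
  out$rel_freq <- ifelse(aa_tot[out$aa] > 0,
                         out$count / aa_tot[out$aa], NA_real_)
  out$rel_freq <- as.numeric(out$rel_freq)
  rownames(out) <- NULL
  out
}
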