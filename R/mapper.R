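# Split-read mapping of 50-bp stranded tags. Placement is decided by the
# 5' 25-mer with at most two substitutions and no indels; a tag is kept
# only when exactly one such locus exists genome-wide. The 3' 25-mer's
# contiguous agreement is recorded but not required.
#
# The candidate search seeds on three exact segments of the 5' half
# (8 + 8 + 9 bp): with at most two mismatches spread over three segments,
# at least one segment matches exactly, so the seeded search finds every
# qualifying locus. Matching runs in "oriented space": each contig is
# indexed forward and reverse-complemented, and minus-strand placements
# are reported back in plus-strand coordinates with a strand flag.

SEED_OFFSETS <- c(0L, 8L, 16L)
SEED_LENGTHS <- c(8L, 8L, 9L)

#' Build the k-mer position index of a genome
#'
#' Indexes every seed k-mer of both strands of every contig so that all
#' occurrences of a 25-mer (up to the configured mismatch budget) can be
#' located. Minus-strand occurrences are reported in plus-strand
#' coordinates with a strand flag. Contigs shorter than `k` are skipped
#' with a warning.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or character vector).
#' @param k Anchor length the index serves (the 5' half, default 25).
#' @return An opaque index object for [map_tags()] / [kmer_positions()].
#' @export
build_index <- function(genome, k = 25L) {
  genome_chr <- as.character(genome)
  ids <- names(genome_chr)
  lens <- nchar(genome_chr)
  short <- lens < k
  if (any(short)) {
    warning(sprintf("build_index: skipping contig(s) shorter than %d bp: %s",
                    k, paste(ids[short], collapse = ", ")))
    genome_chr <- genome_chr[!short]
    ids <- ids[!short]; lens <- lens[!short]
  }
  if (!length(genome_chr)) stopf("build_index: no contig of length >= %d", k)
  # oriented sequences: odd slots forward, even slots reverse-complement
  oriented <- character(2L * length(ids))
  oriented[seq(1L, by = 2L, length.out = length(ids))] <- genome_chr
  oriented[seq(2L, by = 2L, length.out = length(ids))] <-
    revcomp_chr(genome_chr)
  # position encoding: code = (slot - 1) * M + pos, M > max contig length
  M <- max(lens) + 64
  seed_tab <- lapply(unique(SEED_LENGTHS), function(sl) {
    keys <- character(0); codes <- numeric(0)
    kms <- lapply(seq_along(oriented), function(si) {
      L <- nchar(oriented[si])
      p <- seq_len(L - sl + 1L)
      list(km = substring(oriented[si], p, p + sl - 1L),
           code = (si - 1) * M + p)
    })
    km <- unlist(lapply(kms, `[[`, "km"), use.names = FALSE)
    code <- unlist(lapply(kms, `[[`, "code"), use.names = FALSE)
    sp <- split(code, km)
    list(keys = names(sp), map = unname(sp))
  })
  names(seed_tab) <- as.character(unique(SEED_LENGTHS))
  structure(list(k = as.integer(k), contig_ids = ids, lens = lens,
                 oriented = oriented, M = M, seeds = seed_tab),
            class = "tag_index")
}

# all exact occurrences of a k-mer (any length >= 8), via seeding on its
# first 8-mer and verifying; plus-strand coordinates of the leftmost base
# of the k-mer's footprint, with strand flag
#' Exact occurrences of a k-mer in an indexed genome
#'
#' @param index A `tag_index` from [build_index()].
#' @param kmer Query k-mer (length >= 8).
#' @return data.frame (`contig_id`, `strand`, `start`, `end`): plus-strand
#'   coordinates of each occurrence (on the minus strand, the reported
#'   interval is the plus-strand footprint of the reverse complement).
#' @export
kmer_positions <- function(index, kmer) {
  stopifnot(inherits(index, "tag_index"))
  kl <- nchar(kmer)
  if (kl < 8L) stopf("kmer_positions: k-mer must be >= 8 bp")
  st <- index$seeds[["8"]]
  m <- match(substr(kmer, 1L, 8L), st$keys)
  out <- data.frame(contig_id = character(), strand = character(),
                    start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  if (is.na(m)) return(out)
  code <- st$map[[m]]
  si <- code %/% index$M + 1L
  p <- as.integer(code %% index$M)
  ok <- p + kl - 1L <= nchar(index$oriented[si])
  si <- si[ok]; p <- p[ok]
  if (!length(p)) return(out)
  hit <- substring(index$oriented[si], p, p + kl - 1L) == kmer
  si <- si[hit]; p <- p[hit]
  if (!length(p)) return(out)
  ci <- (si + 1L) %/% 2L
  fwd <- si %% 2L == 1L
  L <- index$lens[ci]
  data.frame(contig_id = index$contig_ids[ci],
             strand = ifelse(fwd, "+", "-"),
             start = ifelse(fwd, p, L - (p + kl - 1L) + 1L),
             end = ifelse(fwd, p + kl - 1L, L - p + 1L),
             stringsAsFactors = FALSE)
}

# vectorized mismatch count between equal-length strings
string_mismatches <- function(a, b, len) {
  mm <- integer(length(a))
  for (j in seq_len(len))
    mm <- mm + (substr(a, j, j) != substr(b, j, j))
  mm
}

#' Map a batch of 50-bp tags
#'
#' Implements the split-read contract: candidate loci are genome positions
#' where the 5' 25-mer aligns with at most `max_mismatch_5prime`
#' substitutions (no indels); a tag is accepted iff exactly one candidate
#' exists genome-wide. Whether the 3' 25-mer also matches contiguously and
#' exactly is recorded, not required. Rejections are classed `multi_mapped`
#' (several candidate loci) or `unmapped` (none).
#'
#' @param reads [Biostrings::DNAStringSet] or character vector of 50-bp
#'   tags.
#' @param index A `tag_index` from [build_index()].
#' @param config A [pipeline_config()].
#' @return list: `alignments` (accepted tags: `read_id`, `contig_id`,
#'   `strand`, `start`, `end` — plus-strand footprint of the full tag,
#'   clipped at contig ends — `five_prime_pos`, `mismatches`,
#'   `three_prime_match`), `status` (`read_id`, one of
#'   accepted/multi_mapped/unmapped), `summary` (`total`, `aligned`,
#'   `uniquely_aligned`).
#' @export
map_tags <- function(reads, index, config = pipeline_config()) {
  stopifnot(inherits(index, "tag_index"))
  rchr <- as.character(reads)
  ids <- names(rchr) %||% sprintf("read%06d", seq_along(rchr))
  if (any(nchar(rchr) != config$read_len))
    stopf("map_tags: all reads must be %d bp (read %s is %d bp)",
          config$read_len,
          ids[which(nchar(rchr) != config$read_len)[1]],
          nchar(rchr)[which(nchar(rchr) != config$read_len)[1]])
  n <- length(rchr)
  half <- substr(rchr, 1L, config$half_len)

  cand_read <- integer(0); cand_code <- numeric(0)
  for (s in seq_along(SEED_OFFSETS)) {
    off <- SEED_OFFSETS[s]; sl <- SEED_LENGTHS[s]
    st <- index$seeds[[as.character(sl)]]
    q <- substr(half, off + 1L, off + sl)
    m <- match(q, st$keys)
    ok <- which(!is.na(m))
    if (!length(ok)) next
    pos_list <- st$map[m[ok]]
    nper <- lengths(pos_list)
    cand_read <- c(cand_read, rep(ok, nper))
    cand_code <- c(cand_code, unlist(pos_list, use.names = FALSE) - off)
  }
  # drop candidates whose 25-mer would start off the oriented sequence
  si <- as.integer(cand_code %/% index$M) + 1L
  p <- as.integer(cand_code %% index$M)
  keep <- si >= 1L & si <= length(index$oriented) & p >= 1L
  keep[keep] <- p[keep] + config$half_len - 1L <=
    nchar(index$oriented[si[keep]])
  cand_read <- cand_read[keep]; si <- si[keep]; p <- p[keep]
  # dedupe (read, locus)
  key <- (cand_read - 1) * (2 * length(index$contig_ids) * index$M) +
    (si - 1) * index$M + p
  dup <- duplicated(key)
  cand_read <- cand_read[!dup]; si <- si[!dup]; p <- p[!dup]

  g25 <- substring(index$oriented[si], p, p + config$half_len - 1L)
  mm <- string_mismatches(g25, half[cand_read], config$half_len)
  ok <- mm <= config$max_mismatch_5prime
  nc <- tabulate(cand_read[ok], nbins = n)

  accepted <- which(nc == 1L)
  sel <- ok & cand_read %in% accepted
  a_read <- cand_read[sel]; a_si <- si[sel]; a_p <- p[sel]; a_mm <- mm[sel]

  ci <- (a_si + 1L) %/% 2L
  fwd <- a_si %% 2L == 1L
  L <- index$lens[ci]
  rl <- config$read_len
  p_end <- pmin(a_p + rl - 1L, L)
  full <- a_p + rl - 1L <= L
  tpm <- rep(FALSE, length(a_read))
  if (any(full)) {
    g3 <- substring(index$oriented[a_si[full]], a_p[full] + config$half_len,
                    a_p[full] + rl - 1L)
    tpm[full] <- g3 == substr(rchr[a_read[full]], config$half_len + 1L, rl)
  }
  alignments <- data.frame(
    read_id = ids[a_read],
    contig_id = index$contig_ids[ci],
    strand = ifelse(fwd, "+", "-"),
    start = ifelse(fwd, a_p, L - p_end + 1L),
    end = ifelse(fwd, p_end, L - a_p + 1L),
    five_prime_pos = ifelse(fwd, a_p, L - a_p + 1L),
    mismatches = a_mm,
    three_prime_match = tpm,
    stringsAsFactors = FALSE)
  alignments <- alignments[order(match(alignments$read_id, ids)), ]
  rownames(alignments) <- NULL

  status <- rep("unmapped", n)
  status[nc >= 2L] <- "multi_mapped"
  status[nc == 1L] <- "accepted"
  list(alignments = alignments,
       status = data.frame(read_id = ids, status = status,
                           stringsAsFactors = FALSE),
       summary = data.frame(total = n,
                            aligned = sum(nc >= 1L),
                            uniquely_aligned = sum(nc == 1L)))
}

#' Map a single 50-bp tag
#'
#' @param read A single 50-bp sequence.
#' @param index A `tag_index`.
#' @param config A [pipeline_config()].
#' @return list: `alignment` (one-row data.frame or `NULL`), `status`,
#'   `reason` (`NA` when accepted, else `multi_mapped` / `unmapped`).
#' @export
map_tag <- function(read, index, config = pipeline_config()) {
  res <- map_tags(setNames(as.character(read)[1], "tag"), index, config)
  st <- res$status$status[1]
  list(alignment = if (st == "accepted") res$alignments else NULL,
       status = st,
       reason = if (st == "accepted") NA_character_ else st)
}

#' Remove alignments falling in rRNA intervals
#'
#' Drops alignments whose (plus-strand) start position lies inside any
#' rRNA interval, strand-blind, and reports how many were removed.
#'
#' @param alignments Alignment data.frame from [map_tags()].
#' @param rrna [GenomicRanges::GRanges] of rRNA intervals (see
#'   [read_bed()]).
#' @return list: `kept` (alignments), `filtered_count`.
#' @export
filter_rrna <- function(alignments, rrna) {
  if (nrow(alignments) == 0)
    return(list(kept = alignments, filtered_count = 0L))
  pts <- GenomicRanges::GRanges(
    seqnames = alignments$contig_id,
    ranges = IRanges::IRanges(start = alignments$start, width = 1L))
  hit <- GenomicRanges::countOverlaps(pts, rrna, ignore.strand = TRUE) > 0
  list(kept = alignments[!hit, , drop = FALSE],
       filtered_count = sum(hit))
}

#' Per-gene stranded counts and per-base stranded depth
#'
#' A tag is counted for a gene as *sense* when the tag's genomic strand
#' equals the gene's strand and its 5' position lies within the gene span,
#' *antisense* when the strands differ; tags starting outside every gene
#' are unassigned but still contribute depth. Depth is incremented over
#' each tag's full footprint on the tag's strand.
#'
#' @param alignments Unique alignments (after [filter_rrna()]).
#' @param genes Gene-model data.frame.
#' @param genome_lens Named integer vector of contig lengths.
#' @return list: `counts` (`gene_id`, `sense`, `antisense` for every
#'   gene), `depth` (per contig: list with `+` and `-` integer vectors),
#'   `unassigned` (tag count), and the reconciliation always holds:
#'   sense + antisense + unassigned = number of alignments.
#' @export
coverage_and_counts <- function(alignments, genes, genome_lens) {
  counts <- data.frame(gene_id = genes$gene_id,
                       sense = 0L, antisense = 0L,
                       stringsAsFactors = FALSE)
  unassigned <- nrow(alignments)
  if (nrow(alignments)) {
    pts <- GenomicRanges::GRanges(
      seqnames = alignments$contig_id,
      ranges = IRanges::IRanges(start = alignments$five_prime_pos,
                                width = 1L))
    gr <- genes_to_granges(genes)
    ov <- GenomicRanges::findOverlaps(pts, gr, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(ov); sj <- S4Vectors::subjectHits(ov)
    same <- alignments$strand[qi] == genes$strand[sj]
    # one gene per tag: prefer the same-strand gene when models overlap
    ord <- order(qi, !same)
    first <- !duplicated(qi[ord])
    qi <- qi[ord][first]; sj <- sj[ord][first]; same <- same[ord][first]
    sense_tab <- table(factor(sj[same], levels = seq_len(nrow(genes))))
    anti_tab <- table(factor(sj[!same], levels = seq_len(nrow(genes))))
    counts$sense <- as.integer(sense_tab)
    counts$antisense <- as.integer(anti_tab)
    unassigned <- nrow(alignments) - length(unique(qi))
  }
  depth <- lapply(names(genome_lens), function(cid) {
    per_strand <- lapply(c("+", "-"), function(sd) {
      sel <- alignments$contig_id == cid & alignments$strand == sd
      if (!any(sel)) return(integer(genome_lens[[cid]]))
      cov <- IRanges::coverage(
        IRanges::IRanges(start = alignments$start[sel],
                         end = alignments$end[sel]),
        width = genome_lens[[cid]])
      as.integer(cov)
    })
    names(per_strand) <- c("+", "-")
    per_strand
  })
  names(depth) <- names(genome_lens)
  list(counts = counts, depth = depth, unassigned = unassigned)
}

#' Alignment-rate accounting for one or more samples
#'
#' @param summary_df data.frame with columns `sample_id`, `total`,
#'   `aligned`, `uniquely_aligned`.
#' @return The input with `aligned_pct` and `uniquely_aligned_pct` added
#'   (percent of total reads).
#' @export
alignment_rates <- function(summary_df) {
  summary_df$aligned_pct <- 100 * summary_df$aligned / summary_df$total
  summary_df$uniquely_aligned_pct <-
    100 * summary_df$uniquely_aligned / summary_df$total
  summary_df
}
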