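# Synthetic study system: a toy intronless genome with genes on both
# strands, planted homopolymer frameshifts, planted condition-restricted
# antisense transcription, two noisy gene predictors, simulated similarity
# hits, and stranded 50-bp tag samples.

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

sense_codons <- function() setdiff(all_codons(), STOP_CODONS)

# Default codon weights: mild third-position bias (C favoured over T,
# T over A, A over G) giving a clear, recoverable codon-usage signature
# (e.g. TTC preferred over TTT for Phe) and coding GC near 45%.
default_codon_weights <- function() {
  cods <- sense_codons()
  third <- substr(cods, 3, 3)
  w <- c(C = 1.6, T = 1.2, A = 0.8, G = 0.6)[third]
  setNames(as.numeric(w), cods)
}

rand_dna <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

make_orf <- function(len_nt, weights) {
  stopifnot(len_nt %% 3 == 0, len_nt >= 9)
  n_int <- len_nt / 3 - 2L
  body <- sample(names(weights), n_int, replace = TRUE, prob = weights)
  paste0("ATG", paste(body, collapse = ""),
         sample(STOP_CODONS, 1, prob = c(0.5, 0.2, 0.3)))
}

#' Generate a synthetic toy genome with truth annotation
#'
#' Places intronless genes (ATG start, single terminal stop, length a
#' multiple of 3 and at least 180 bp) on both strands with intergenic gaps
#' of at least 200 bp, targets a genome GC of `gc_target` (45% by default)
#' via the intergenic base composition, designates a subset of long genes
#' as antisense-planted (antisense transcription in the stationary phase
#' only) and another subset as frameshifted: one base is deleted inside a
#' planted `AAAAAA` homopolymer mid-gene, emulating a pyrosequencing
#' homopolymer under-call that splits the ORF. Also reserves rRNA
#' intervals, assigns a per-gene homology class and subject, a pathway
#' membership, and a log-normal expression profile per condition.
#'
#' Gene lengths are drawn from a bimodal mixture (short 180-270 bp, long
#' 390-540 bp) so that a 100-kb / 200-gene packing is feasible while long
#' genes can host split fragments that survive the 60-aa filter.
#'
#' @param n_contigs Number of contigs.
#' @param contig_len_bp Length of each contig (>= 10 kb).
#' @param n_genes Total gene count across contigs.
#' @param seed Integer seed; the full truth set is deterministic under it.
#' @param gc_target Genome GC fraction to aim for (within about 2%).
#' @param antisense_fraction Fraction of genes planted with
#'   stationary-phase antisense transcription.
#' @param frameshift_fraction Fraction of genes broken by a homopolymer
#'   deletion.
#' @param n_rrna Number of rRNA intervals to reserve.
#' @param codon_weights Named weights over the 61 sense codons (defaults
#'   to a mild third-position bias).
#' @param n_pathways Number of synthetic pathways genes are assigned to.
#'
#' @return A list of class `"truth_set"`: `genome` (DNAStringSet), `genes`
#'   (truth gene models with `frameshift`, `indel_offset`, `aa_len`),
#'   `antisense_genes`, `frameshift_genes`, `homology` (gene_id,
#'   subject_id, evalue, class), `expression` (gene_id, condition,
#'   sense_rate, antisense_rate; expected tag count = rate x depth_mean),
#'   `rrna` (intervals), `pathways`, `codon_weights`, `params`.
#' @export
make_genome <- function(n_contigs = 1L, contig_len_bp = 1e5, n_genes = 200L,
                        seed = 1L, gc_target = 0.45,
                        antisense_fraction = 0.10,
                        frameshift_fraction = 0.10,
                        n_rrna = 2L, codon_weights = NULL,
                        n_pathways = 20L) {
  if (contig_len_bp < 1e4)
    stopf("make_genome: contig_len_bp must be >= 10 kb (limiting parameter: contig_len_bp)")
  set.seed(as.integer(seed))
  weights <- codon_weights %||% default_codon_weights()

  n_fs <- round(frameshift_fraction * n_genes)
  n_as <- round(antisense_fraction * n_genes)
  n_long <- max(round(0.30 * n_genes), n_fs + n_as)
  if (n_long > n_genes)
    stopf("make_genome: not enough genes for the requested antisense/frameshift fractions (limiting parameter: n_genes)")
  n_short <- n_genes - n_long

  len_long <- 390L + 3L * sample(0:30, n_long, replace = TRUE)
  len_short <- 180L + 3L * sample(0:20, n_short, replace = TRUE)
  lens <- sample(c(len_long, len_short))          # shuffled placement order
  is_long <- lens >= 390L

  rrna_len <- rep(800L, n_rrna)
  min_gap <- 200L

  # feasibility: every block plus a minimum gap before it, plus one
  # trailing gap, must fit each contig
  need <- sum(lens) + sum(rrna_len) +
    (n_genes + n_rrna + n_contigs) * min_gap
  if (need > n_contigs * contig_len_bp)
    stopf(paste0("make_genome: cannot place %d genes of total %d bp with ",
                 ">=%d bp gaps in %d x %d bp (limiting parameter: n_genes)"),
          n_genes, sum(lens), min_gap, n_contigs, contig_len_bp)

  long_ids <- which(is_long)
  fs_idx <- sort(sample(long_ids, n_fs))
  as_pool <- setdiff(long_ids, fs_idx)
  if (length(as_pool) < n_as)
    stopf("make_genome: not enough long genes for antisense planting (limiting parameter: antisense_fraction)")

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)

  # build ORF sequences (5'->3' of the gene), planting frameshifts
  orf_seq <- character(n_genes)
  indel_offset <- rep(NA_integer_, n_genes)
  for (i in seq_len(n_genes)) {
    s <- make_orf(lens[i], weights)
    if (i %in% fs_idx) {
      m <- lens[i] / 3L
      jr <- seq(65L, m - 65L)                # codon index, both sides >=190 nt
      j <- jr[sample.int(length(jr), 1)]
      substr(s, 3L * j - 2L, 3L * j + 3L) <- "AAAAAA"
      d <- 3L * j                             # delete inside the A-run
      s <- paste0(substr(s, 1L, d - 1L), substr(s, d + 1L, lens[i]))
      indel_offset[i] <- d
      lens[i] <- lens[i] - 1L
    }
    orf_seq[i] <- s
  }

  # assign blocks (genes then rRNA) to contigs in balanced runs
  block_len <- c(lens, rrna_len)
  block_is_rrna <- c(rep(FALSE, n_genes), rep(TRUE, n_rrna))
  contig_of <- sort(rep(seq_len(n_contigs), length.out = length(block_len)))

  contig_ids <- sprintf("ctg%02d", seq_len(n_contigs))
  genome <- setNames(character(n_contigs), contig_ids)
  gene_tab <- vector("list", n_contigs)

  # coding GC realized so far, to solve the intergenic composition
  coding_seq <- paste(orf_seq, collapse = "")
  gc_coding <- sum(strsplit(coding_seq, "")[[1]] %in% c("G", "C"))
  n_inter_total <- n_contigs * contig_len_bp - sum(block_len)
  p_gc_inter <- (gc_target * n_contigs * contig_len_bp -
                   gc_coding - 0.45 * sum(rrna_len)) / n_inter_total
  p_gc_inter <- min(max(p_gc_inter, 0.20), 0.80)

  rrna_rows <- list()
  rr <- 0L
  for (ci in seq_len(n_contigs)) {
    bl <- which(contig_of == ci)
    bl <- sample(bl)                          # shuffle block order in contig
    slack <- contig_len_bp - sum(block_len[bl]) - (length(bl) + 1L) * min_gap
    extra <- if (slack > 0) {
      as.vector(stats::rmultinom(1, slack, rep(1, length(bl) + 1L)))
    } else rep(0L, length(bl) + 1L)
    gaps <- min_gap + extra
    pieces <- character(2L * length(bl) + 1L)
    rows <- list()
    pos <- 0L
    for (k in seq_along(bl)) {
      b <- bl[k]
      pieces[2L * k - 1L] <- rand_dna(gaps[k], p_gc_inter)
      pos <- pos + gaps[k]
      start <- pos + 1L
      if (block_is_rrna[b]) {
        sq <- rand_dna(block_len[b], 0.45)
        rr <- rr + 1L
        rrna_rows[[rr]] <- data.frame(
          contig_id = contig_ids[ci], start = start,
          end = pos + block_len[b], name = sprintf("rrna%02d", rr),
          stringsAsFactors = FALSE)
      } else {
        sq <- if (strands[b] == "+") orf_seq[b] else revcomp_chr(orf_seq[b])
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_ids[b], contig_id = contig_ids[ci],
          start = start, end = pos + block_len[b], strand = strands[b],
          length = block_len[b], aa_len = block_len[b] %/% 3L,
          frameshift = b %in% fs_idx, indel_offset = indel_offset[b],
          stringsAsFactors = FALSE)
      }
      pieces[2L * k] <- sq
      pos <- pos + block_len[b]
    }
    pieces[2L * length(bl) + 1L] <- rand_dna(contig_len_bp - pos, p_gc_inter)
    genome[ci] <- paste(pieces, collapse = "")
    gene_tab[[ci]] <- do.call(rbind, rows)
  }
  genes <- do.call(rbind, gene_tab)
  genes <- genes[order(genes$gene_id), ]
  rownames(genes) <- NULL
  rrna <- do.call(rbind, rrna_rows)

  # homology: frameshift genes are forced homolog-bearing (interrupted-ORF
  # detection is homology driven); others drawn conserved/slight/none
  hclass <- sample(c("conserved", "slight", "none"), n_genes,
                   replace = TRUE, prob = c(0.55, 0.12, 0.33))
  hclass[match(gene_ids[fs_idx], gene_ids)] <- "conserved"
  evalue <- rep(NA_real_, n_genes)
  evalue[hclass == "conserved"] <- 10^-runif(sum(hclass == "conserved"), 10.5, 50)
  evalue[hclass == "slight"] <- 10^-runif(sum(hclass == "slight"), 5.2, 9.8)
  homology <- data.frame(
    gene_id = gene_ids,
    subject_id = sprintf("SCER|y%04d", seq_len(n_genes)),
    evalue = evalue, class = hclass, stringsAsFactors = FALSE)
  homology$subject_id[hclass == "none"] <- NA_character_

  # expression: lognormal across genes (mean 1), lognormal condition
  # factors; planted antisense genes get stationary-only antisense
  # transcription and a 10x sense suppression in stationary phase
  rel <- rlnorm(n_genes, 0, 1.7)
  rel <- rel / mean(rel)
  f_log <- rlnorm(n_genes, 0, 0.6)
  f_stat <- rlnorm(n_genes, 0, 0.6)
  # planted antisense genes are the most strongly expressed eligible long
  # genes (an ADH1-like abundant transcript), and they follow the CuADH1
  # program deterministically: expressed sense in log phase, 10x
  # suppressed in stationary, where the antisense transcript appears
  # instead. Selecting (not overwriting) expression levels keeps the
  # marginal log-normal calibration of the genome intact, and the fixed
  # condition factors make the sense:antisense inversion a property of
  # the truth set itself, not of the noise draw.
  as_idx <- as_pool[order(rel[as_pool], decreasing = TRUE)][seq_len(n_as)]
  as_idx <- sort(as_idx)
  is_as <- seq_len(n_genes) %in% as_idx
  f_log[is_as] <- 1
  f_stat[is_as] <- 0.1
  anti_stat <- ifelse(is_as, runif(n_genes, 0.8, 2.0), 0)
  glen <- genes$length[match(gene_ids, genes$gene_id)]
  expression <- rbind(
    data.frame(gene_id = gene_ids, condition = "log",
               sense_rate = rel * f_log * glen / 50,
               antisense_rate = 0, stringsAsFactors = FALSE),
    data.frame(gene_id = gene_ids, condition = "stationary",
               sense_rate = rel * f_stat * glen / 50,
               antisense_rate = anti_stat * glen / 50,
               stringsAsFactors = FALSE))

  pathways <- data.frame(
    pathway_id = sample(sprintf("pw%02d", seq_len(n_pathways)),
                        n_genes, replace = TRUE),
    gene_id = gene_ids, stringsAsFactors = FALSE)

  structure(list(
    genome = {
      g <- Biostrings::DNAStringSet(genome); names(g) <- contig_ids; g
    },
    genes = genes,
    antisense_genes = gene_ids[as_idx],
    frameshift_genes = gene_ids[fs_idx],
    homology = homology,
    expression = expression,
    rrna = rrna,
    pathways = pathways,
    codon_weights = weights,
    params = list(n_contigs = n_contigs, contig_len_bp = contig_len_bp,
                  n_genes = n_genes, seed = as.integer(seed),
                  gc_target = gc_target)),
    class = "truth_set")
}

# fragments of a split gene in ORF (5'->3') coordinates, then mapped to
# genomic coordinates. Frameshifted genes split at the planted indel; other
# genes split near the midpoint (fragments frame-preserving; short genes
# may yield sub-minimum fragments, which downstream filtering removes).
split_fragments <- function(gene, min_frag = 180L) {
  L <- gene$length
  if (gene$frameshift && !is.na(gene$indel_offset)) {
    d <- gene$indel_offset
    f1 <- 3L * ((d - 1L) %/% 3L)
  } else {
    f1 <- 3L * (L %/% 6L)
  }
  g_max <- L - f1 - min_frag
  gap <- if (g_max >= 3L) sample.int(min(g_max, 60L), 1) else 0L
  x <- f1 + gap + 1L
  f2 <- L - x + 1L
  f2 <- 3L * (f2 %/% 3L)                      # frame-preserving tail
  x <- L - f2 + 1L
  a_orf <- c(1L, f1)
  b_orf <- c(x, L)
  to_genomic <- function(ab) {
    if (gene$strand == "+") c(gene$start + ab[1] - 1L, gene$start + ab[2] - 1L)
    else c(gene$end - ab[2] + 1L, gene$end - ab[1] + 1L)
  }
  ga <- to_genomic(a_orf); gb <- to_genomic(b_orf)
  data.frame(gene_id = paste0(gene$gene_id, c("a", "b")),
             contig_id = gene$contig_id,
             start = c(ga[1], gb[1]), end = c(ga[2], gb[2]),
             strand = gene$strand,
             gap_bp = x - f1 - 1L,
             stringsAsFactors = FALSE)
}

#' Emulate two noisy gene predictors
#'
#' Starting from the truth annotation, each predictor independently misses
#' genes at `miss_rate`; a `split_rate` fraction of genes is emitted as two
#' adjacent in-frame fragments separated by a sub-600-bp gap (interrupted
#' ORFs — genome-planted frameshift genes are split first, at their indel);
#' and a 20% subset of remaining models per predictor gets its 5' boundary
#' jittered by up to `jitter_bp` (rounded to codons, length kept >= 180 bp).
#' Splitting models the broken assembly, so both predictors emit the same
#' fragment pair for a split gene.
#'
#' @param truth A `truth_set` from [make_genome()].
#' @param miss_rate,split_rate Per-gene probabilities in `[0, 1]`.
#' @param jitter_bp Maximum 5'-boundary jitter in bp (0 disables).
#' @param seed Integer seed.
#' @return list with `genes_a`, `genes_b` (predictor models),
#'   `split_records` (gene_id, fragment ids, gap), `common_count` (number
#'   of models identical in A and B by contig/strand/start/end), and
#'   per-predictor `missed` / `jittered` bookkeeping.
#' @export
corrupt_predictions <- function(truth, miss_rate = 0.05, split_rate = 0.10,
                                jitter_bp = 9L, seed = 1L) {
  stopifnot(inherits(truth, "truth_set"))
  if (miss_rate < 0 || miss_rate > 1 || split_rate < 0 || split_rate > 1)
    stopf("corrupt_predictions: rates must lie in [0, 1]")
  set.seed(as.integer(seed))
  genes <- truth$genes
  n <- nrow(genes)

  n_split <- round(split_rate * n)
  fs <- intersect(truth$frameshift_genes, genes$gene_id)
  split_ids <- if (n_split <= length(fs)) {
    sample(fs, n_split)
  } else {
    c(fs, sample(setdiff(genes$gene_id, fs), n_split - length(fs)))
  }

  frags <- list()
  for (gid in sort(split_ids)) {
    frags[[gid]] <- split_fragments(genes[genes$gene_id == gid, ])
  }
  split_records <- if (length(frags)) {
    do.call(rbind, lapply(names(frags), function(gid) {
      f <- frags[[gid]]
      data.frame(gene_id = gid, frag_a = f$gene_id[1], frag_b = f$gene_id[2],
                 gap_bp = f$gap_bp[1], stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene_id = character(), frag_a = character(),
               frag_b = character(), gap_bp = integer(),
               stringsAsFactors = FALSE)
  }

  base_models <- function() {
    keep <- !(genes$gene_id %in% split_ids)
    full <- genes[keep, c("gene_id", "contig_id", "start", "end", "strand")]
    rbind(full, do.call(rbind, c(lapply(frags, function(f)
      f[, c("gene_id", "contig_id", "start", "end", "strand")]),
      list(full[0, ]))))
  }

  one_predictor <- function(tag) {
    m <- base_models()
    miss <- genes$gene_id[rbinom(n, 1, miss_rate) == 1]
    m <- m[!(m$gene_id %in% miss) & !(sub("[ab]$", "", m$gene_id) %in% miss), ]
    jittered <- character(0)
    if (jitter_bp >= 3) {
      elig <- which(!grepl("[ab]$", m$gene_id))
      jit <- sample(elig, size = round(0.2 * length(elig)))
      for (i in jit) {
        k <- sample.int(jitter_bp %/% 3L, 1) * 3L
        len <- m$end[i] - m$start[i] + 1L
        if (len - k < 180L) next
        if (m$strand[i] == "+") m$start[i] <- m$start[i] + k
        else m$end[i] <- m$end[i] - k
        jittered <- c(jittered, m$gene_id[i])
      }
    }
    m$predictors <- tag
    rownames(m) <- NULL
    list(models = m, missed = miss, jittered = jittered)
  }

  a <- one_predictor("A")
  b <- one_predictor("B")
  key <- function(m) paste(m$contig_id, m$strand, m$start, m$end)
  common_count <- length(intersect(key(a$models), key(b$models)))

  list(genes_a = a$models, genes_b = b$models,
       split_records = split_records,
       common_count = common_count,
       missed_a = a$missed, missed_b = b$missed,
       jittered_a = a$jittered, jittered_b = b$jittered)
}

#' Simulate similarity hits for predictor models
#'
#' Emits 12-column tabular hits: each model whose parent gene is
#' homolog-bearing hits the parent's reference subject at the parent's
#' e-value (so both fragments of a split gene share a best homolog and have
#' no mutual hit — the frameshift-artifact signature). For conserved genes,
#' cross-species orthologs in two pseudo-species (`SPA`, `SPB`) are emitted
#' with strong e-values and high coverage, including the subject-subject
#' edge, so triangle families can form.
#'
#' @param truth A `truth_set`.
#' @param models Model data.frame (e.g. merged or per-predictor models);
#'   fragment ids `g0001a`/`g0001b` inherit the parent's homology.
#' @param seed Integer seed.
#' @param cross_species Emit the pseudo-species ortholog block?
#' @return list: `rows` (12-column data.frame ready for [write_hits()]),
#'   `seq_lengths` (named aa lengths for every id involved).
#' @export
simulate_hits <- function(truth, models, seed = 1L, cross_species = TRUE) {
  stopifnot(inherits(truth, "truth_set"))
  set.seed(as.integer(seed))
  models <- models[!duplicated(models$gene_id), , drop = FALSE]
  hom <- truth$homology
  parent <- sub("[ab]$", "", models$gene_id)
  hi <- match(parent, hom$gene_id)
  aa_model <- (models$end - models$start + 1L) %/% 3L
  aa_parent <- truth$genes$aa_len[match(parent, truth$genes$gene_id)]

  row12 <- function(q, s, len, ev) {
    data.frame(V1 = q, V2 = s, V3 = round(runif(length(q), 55, 95), 1),
               V4 = len, V5 = 0L, V6 = 0L, V7 = 1L, V8 = len,
               V9 = 1L, V10 = len, V11 = ev,
               V12 = round(len * 2.1), stringsAsFactors = FALSE)
  }
  cov_len <- function(a) pmax(30L, round(0.9 * a))

  keep <- !is.na(hi) & hom$class[hi] != "none"
  rows <- row12(models$gene_id[keep], hom$subject_id[hi][keep],
                cov_len(aa_model[keep]), hom$evalue[hi][keep])
  lens <- c(setNames(aa_model, models$gene_id),
            setNames(aa_parent, hom$subject_id[hi])[keep])

  if (cross_species) {
    # per conserved parent: ortholog presence and e-values drawn once and
    # shared by all of the parent's models, so fragments of one split gene
    # agree on their best homolog (they are parts of the same protein)
    cons <- hom$gene_id[hom$class == "conserved" &
                          hom$gene_id %in% parent]
    has_a <- setNames(rbinom(length(cons), 1, 0.8) == 1, cons)
    has_b <- setNames(rbinom(length(cons), 1, 0.8) == 1, cons)
    ev_a <- setNames(10^-runif(length(cons), 25, 60), cons)
    ev_b <- setNames(10^-runif(length(cons), 25, 60), cons)
    spa <- setNames(sprintf("SPA|p%04d", match(cons, hom$gene_id)), cons)
    spb <- setNames(sprintf("SPB|p%04d", match(cons, hom$gene_id)), cons)
    mi <- which(parent %in% cons)
    pm <- parent[mi]
    sa <- mi[has_a[pm]]; sb <- mi[has_b[pm]]
    ss <- cons[has_a[cons] & has_b[cons]]
    aa_par_cons <- setNames(aa_parent, parent)[cons]
    rows <- rbind(rows,
                  row12(models$gene_id[sa], spa[parent[sa]],
                        cov_len(aa_model[sa]), ev_a[parent[sa]]),
                  row12(models$gene_id[sb], spb[parent[sb]],
                        cov_len(aa_model[sb]), ev_b[parent[sb]]),
                  row12(spa[ss], spb[ss], cov_len(aa_par_cons[ss]),
                        10^-runif(length(ss), 25, 60)))
    lens <- c(lens, setNames(aa_par_cons, spa[cons]),
              setNames(aa_par_cons, spb[cons]))
  }
  lens <- lens[!duplicated(names(lens)) & !is.na(names(lens))]
  rownames(rows) <- NULL
  list(rows = rows, seq_lengths = lens)
}

#' Write 12-column tabular hits
#'
#' @param rows 12-column data.frame (as from [simulate_hits()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate a stranded 50-bp tag sample
#'
#' Draws Poisson tag counts per gene from the truth expression profile
#' (expected count = profile rate x `depth_mean`), placing each 50-bp tag
#' uniformly within its gene on the transcript's strand. Planted antisense
#' genes additionally emit reverse-strand tags, but only in the
#' `stationary` condition. A fraction of tags receives 1-3 uniform
#' substitutions; an rRNA fraction is drawn from the reserved rRNA
#' intervals. Tag sequencing errors are substitutions only — indels live in
#' the assembly, not the tags.
#'
#' @param truth A `truth_set`.
#' @param condition `"log"` or `"stationary"`.
#' @param depth_mean Expected coverage depth multiplier.
#' @param seed Integer seed (fixed seed gives identical read sets).
#' @param error_frac Fraction of tags carrying substitutions.
#' @param rrna_frac Target fraction of rRNA tags among all tags.
#' @return list: `reads` (named DNAStringSet), `truth` (per-read origin:
#'   contig, plus-strand footprint start/end, strand, 5' position, origin
#'   feature, class sense/antisense/rrna, n_err), `expected_total`.
#' @export
simulate_tags <- function(truth, condition, depth_mean = 20, seed = 1L,
                          error_frac = 0.02, rrna_frac = 0.02) {
  stopifnot(inherits(truth, "truth_set"))
  if (!condition %in% c("log", "stationary"))
    stopf("simulate_tags: condition must be 'log' or 'stationary', got '%s'",
          condition)
  if (depth_mean <= 0) stopf("simulate_tags: depth_mean must be > 0")
  set.seed(as.integer(seed))
  genome_chr <- as.character(truth$genome)
  genes <- truth$genes
  prof <- truth$expression[truth$expression$condition == condition, ]
  prof <- prof[match(genes$gene_id, prof$gene_id), ]

  draw_from_span <- function(n, contig, lo, hi, strand) {
    # 50-bp footprints fully inside [lo, hi]; 5' end depends on strand
    off <- sample.int(hi - lo + 1L - 49L, n, replace = TRUE) - 1L
    fstart <- lo + off
    fend <- fstart + 49L
    seq50 <- substring(genome_chr[contig], fstart, fend)
    if (strand == "-") seq50 <- revcomp_chr(seq50)
    data.frame(contig_id = contig, start = fstart, end = fend,
               strand = strand,
               five_prime_pos = if (strand == "+") fstart else fend,
               seq = seq50, stringsAsFactors = FALSE)
  }

  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ns <- rpois(1, prof$sense_rate[i] * depth_mean)
    na <- rpois(1, prof$antisense_rate[i] * depth_mean)
    if (ns > 0) {
      d <- draw_from_span(ns, g$contig_id, g$start, g$end, g$strand)
      d$origin <- g$gene_id; d$class <- "sense"
      out[[length(out) + 1L]] <- d
    }
    if (na > 0) {
      anti <- if (g$strand == "+") "-" else "+"
      d <- draw_from_span(na, g$contig_id, g$start, g$end, anti)
      d$origin <- g$gene_id; d$class <- "antisense"
      out[[length(out) + 1L]] <- d
    }
  }
  n_gene_reads <- sum(vapply(out, nrow, integer(1)))
  n_rrna <- rpois(1, rrna_frac / (1 - rrna_frac) * n_gene_reads)
  if (n_rrna > 0 && nrow(truth$rrna) > 0) {
    pick <- sample.int(nrow(truth$rrna), n_rrna, replace = TRUE)
    for (r in seq_len(nrow(truth$rrna))) {
      k <- sum(pick == r)
      if (k == 0) next
      rv <- truth$rrna[r, ]
      d <- draw_from_span(k, rv$contig_id, rv$start, rv$end,
                          sample(c("+", "-"), 1))
      d$origin <- rv$name; d$class <- "rrna"
      out[[length(out) + 1L]] <- d
    }
  }
  tab <- do.call(rbind, out)
  if (is.null(tab) || nrow(tab) == 0L)
    stopf("simulate_tags: no reads generated; increase depth_mean")
  tab <- tab[sample.int(nrow(tab)), ]          # shuffle read order
  tab$read_id <- sprintf("r%07d", seq_len(nrow(tab)))

  # substitution errors
  tab$n_err <- 0L
  err <- which(runif(nrow(tab)) < error_frac)
  if (length(err)) {
    bases <- c("A", "C", "G", "T")
    for (i in err) {
      k <- sample.int(3L, 1)
      pos <- sample.int(50L, k)
      s <- strsplit(tab$seq[i], "")[[1]]
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
      tab$seq[i] <- paste(s, collapse = "")
      tab$n_err[i] <- k
    }
  }
  reads <- Biostrings::DNAStringSet(tab$seq)
  names(reads) <- tab$read_id
  truth_tab <- tab[, c("read_id", "contig_id", "start", "end", "strand",
                       "five_prime_pos", "origin", "class", "n_err")]
  rownames(truth_tab) <- NULL
  list(reads = reads, truth = truth_tab,
       expected_total = sum((prof$sense_rate + prof$antisense_rate) *
                              depth_mean))
}

#' Draw raw stranded counts directly from the truth expression profile
#'
#' Bypasses read simulation and mapping: Poisson counts per gene per
#' condition, useful for exercising normalization and HEG calling at
#' larger gene numbers.
#'
#' @param truth A `truth_set`.
#' @param conditions Conditions to draw (default both phases).
#' @param depth_mean Depth multiplier.
#' @param seed Integer seed.
#' @return A long counts data.frame (`gene_id`, `sample_id`, `sense`,
#'   `antisense`) suitable for [uq_normalize()].
#' @export
counts_from_profile <- function(truth, conditions = c("log", "stationary"),
                                depth_mean = 20, seed = 1L) {
  stopifnot(inherits(truth, "truth_set"))
  set.seed(as.integer(seed))
  out <- lapply(conditions, function(cond) {
    p <- truth$expression[truth$expression$condition == cond, ]
    data.frame(gene_id = p$gene_id, sample_id = cond,
               sense = rpois(nrow(p), p$sense_rate * depth_mean),
               antisense = rpois(nrow(p), p$antisense_rate * depth_mean),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write the rRNA intervals of a truth set as BED
#'
#' @param truth A `truth_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rrna_bed <- function(truth, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = truth$rrna$contig_id,
    ranges = IRanges::IRanges(start = truth$rrna$start,
                              end = truth$rrna$end),
    name = truth$rrna$name)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
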