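# Orchestration: run the stages in dependency order against a synthetic
# study system, persisting every stage's outputs as plain-text formats and
# a JSON manifest that makes the run reproducible from config + seed.

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# depth arrays <-> run-length TSV (contig, strand, start, end, depth)
depth_to_runs <- function(depth) {
  out <- list()
  for (cid in names(depth)) for (sd in c("+", "-")) {
    d <- depth[[cid]][[sd]]
    r <- rle(d)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    keep <- r$values > 0L
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      contig_id = cid, strand = sd, start = s[keep], end = e[keep],
      depth = r$values[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(contig_id = character(), strand = character(),
                      start = integer(), end = integer(), depth = integer()))
  do.call(rbind, out)
}

runs_to_depth <- function(runs, genome_lens) {
  depth <- lapply(genome_lens, function(L)
    list(`+` = integer(L), `-` = integer(L)))
  for (i in seq_len(nrow(runs))) {
    v <- depth[[runs$contig_id[i]]][[runs$strand[i]]]
    v[runs$start[i]:runs$end[i]] <- runs$depth[i]
    depth[[runs$contig_id[i]]][[runs$strand[i]]] <- v
  }
  depth
}

PIPELINE_STAGES <- c("simulate", "consensus", "families", "map", "quant",
                     "discover")

#' Run the full pipeline on a synthetic study system
#'
#' Executes the stages in dependency order — simulate, consensus,
#' families, map, quant, discover — writing each stage's outputs under
#' `out_dir` in plain-text formats (FASTA, GFF3, BED, TSV) plus a
#' `manifest.json` recording the configuration, the root seed, per-stage
#' row counts and the MD5 of every output file. A rerun with the same seed
#' and parameters is byte-identical. A subset of stages can be rerun
#' against existing intermediates via `stages`; all required inputs are
#' checked before any stage runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed; all stage seeds derive from it.
#' @param config A [pipeline_config()].
#' @param n_contigs,contig_len_bp,n_genes Genome shape (see
#'   [make_genome()]).
#' @param depth_mean Simulated coverage depth.
#' @param miss_rate,split_rate,jitter_bp Predictor noise (see
#'   [corrupt_predictions()]).
#' @param error_frac,rrna_frac Read noise (see [simulate_tags()]).
#' @param conditions Phases to simulate.
#' @param stages Stages to run (default all).
#' @param quiet Suppress per-stage progress messages?
#' @return Invisibly, a list with the manifest and the key in-memory
#'   results of the stages that ran.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = pipeline_config(),
                         n_contigs = 1L, contig_len_bp = 1e5,
                         n_genes = 200L, depth_mean = 20,
                         miss_rate = 0.05, split_rate = 0.10,
                         jitter_bp = 9L, error_frac = 0.02,
                         rrna_frac = 0.02,
                         conditions = c("log", "stationary"),
                         stages = PIPELINE_STAGES, quiet = FALSE) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  say <- function(fmt, ...) if (!quiet)
    message(sprintf("[strandtag %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  seed <- as.integer(seed)

  # inputs required by the requested stages must pre-exist when the stage
  # producing them is not being run
  need <- character(0)
  if (!"simulate" %in% stages)
    need <- c(need, p("genome.fasta"), p("predictor_a.gff3"),
              p("predictor_b.gff3"), p("hits.tsv"), p("seq_lengths.tsv"),
              p("rrna.bed"), p("pathways.tsv"),
              vapply(conditions, function(cd) p("reads_", cd, ".fasta"), ""))
  if (!"consensus" %in% stages && any(c("map", "quant", "discover") %in% stages))
    need <- c(need, p("merged.gff3"))
  if (!"map" %in% stages && any(c("quant", "discover") %in% stages))
    need <- c(need, p("counts.tsv"),
              vapply(conditions, function(cd) p("depth_", cd, ".tsv"), ""))
  if (!"quant" %in% stages && "discover" %in% stages)
    need <- c(need, p("normalized.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stopf("run_pipeline: missing required input(s): %s",
          paste(missing, collapse = ", "))

  manifest <- list(seed = seed,
                   config = unclass(config),
                   params = list(n_contigs = n_contigs,
                                 contig_len_bp = contig_len_bp,
                                 n_genes = n_genes, depth_mean = depth_mean,
                                 miss_rate = miss_rate,
                                 split_rate = split_rate,
                                 jitter_bp = jitter_bp,
                                 error_frac = error_frac,
                                 rrna_frac = rrna_frac,
                                 conditions = conditions),
                   stages = stages, counts = list())
  results <- list()

  ## ---- simulate -------------------------------------------------------
  truth <- NULL
  if ("simulate" %in% stages) {
    say("simulate: genome %d x %d bp, %d genes", n_contigs, contig_len_bp,
        n_genes)
    truth <- make_genome(n_contigs, contig_len_bp, n_genes, seed = seed)
    preds <- corrupt_predictions(truth, miss_rate, split_rate, jitter_bp,
                                 seed = seed + 1L)
    models <- rbind(preds$genes_a, preds$genes_b)
    hits_sim <- simulate_hits(truth, models, seed = seed + 2L)
    write_fasta(truth$genome, p("genome.fasta"))
    write_gff3(cbind(truth$genes[, c("gene_id", "contig_id", "start",
                                     "end", "strand")],
                     predictors = "truth"), p("truth.gff3"))
    write_gff3(preds$genes_a, p("predictor_a.gff3"))
    write_gff3(preds$genes_b, p("predictor_b.gff3"))
    write_hits(hits_sim$rows, p("hits.tsv"))
    write_tsv(data.frame(id = names(hits_sim$seq_lengths),
                         length = unname(hits_sim$seq_lengths)),
              p("seq_lengths.tsv"))
    write_rrna_bed(truth, p("rrna.bed"))
    utils::write.table(truth$pathways[, c("pathway_id", "gene_id")],
                       p("pathways.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    write_tsv(preds$split_records, p("truth_splits.tsv"))
    write_tsv(data.frame(gene_id = truth$antisense_genes),
              p("truth_antisense.tsv"))
    write_tsv(truth$expression, p("truth_expression.tsv"))
    for (i in seq_along(conditions)) {
      cd <- conditions[i]
      tags <- simulate_tags(truth, cd, depth_mean, seed = seed + 2L + i,
                            error_frac = error_frac, rrna_frac = rrna_frac)
      write_fasta(tags$reads, p("reads_", cd, ".fasta"))
      write_tsv(tags$truth, p("reads_", cd, ".truth.tsv"))
    }
    manifest$counts$simulate <- list(genes = nrow(truth$genes),
                                     split = nrow(preds$split_records),
                                     common_models = preds$common_count)
    results$truth <- truth
    results$predictions <- preds
  }

  genome <- if (!is.null(truth)) truth$genome else read_fasta(p("genome.fasta"))
  genome_lens <- setNames(Biostrings::width(genome), names(genome))
  seq_lengths <- {
    sl <- read_tsv(p("seq_lengths.tsv"))
    setNames(sl$length, sl$id)
  }
  hits <- read_hits(p("hits.tsv"), seq_lengths)

  ## ---- consensus ------------------------------------------------------
  merged <- NULL
  if ("consensus" %in% stages) {
    say("consensus: merging predictors")
    ga <- filter_candidates(read_gff3(p("predictor_a.gff3")), genome, config)
    gb <- filter_candidates(read_gff3(p("predictor_b.gff3")), genome, config)
    mg <- merge_predictions(ga, gb, hits, config)
    merged <- mg$merged
    art <- detect_frameshift_artifacts(merged, hits, config)
    cu <- codon_usage(merged, genome)
    write_gff3(merged, p("merged.gff3"))
    write_tsv(art$interrupted, p("interrupted_pairs.tsv"))
    write_tsv(art$overlapping, p("overlapping_pairs.tsv"))
    write_tsv(cu, p("codon_usage.tsv"))
    manifest$counts$consensus <- list(
      common = nrow(mg$common), only_a = nrow(mg$only_a),
      only_b = nrow(mg$only_b), merged = nrow(merged),
      interrupted_pairs = nrow(art$interrupted),
      n_homolog_genes = art$n_homolog_genes)
    results$merge <- mg
    results$artifacts <- art
  }
  if (is.null(merged) && any(c("map", "quant", "discover") %in% stages))
    merged <- read_gff3(p("merged.gff3"))

  ## ---- families -------------------------------------------------------
  if ("families" %in% stages) {
    say("families: triangle clustering")
    fams <- triangle_cluster(qualifying_edges(hits, config))
    write_tsv(fams, p("families.tsv"))
    manifest$counts$families <- list(
      families = length(unique(fams$family_id)),
      clustered_proteins = nrow(fams))
    results$families <- fams
  }

  ## ---- map ------------------------------------------------------------
  counts_long <- NULL
  depths <- list()
  if ("map" %in% stages) {
    say("map: indexing genome")
    idx <- build_index(genome, config$half_len)
    rrna <- read_bed(p("rrna.bed"))
    summaries <- list()
    counts_list <- list()
    for (cd in conditions) {
      say("map: sample '%s'", cd)
      reads <- read_fasta(p("reads_", cd, ".fasta"))
      mp <- map_tags(reads, idx, config)
      fr <- filter_rrna(mp$alignments, rrna)
      cc <- coverage_and_counts(fr$kept, merged, genome_lens)
      counts_list[[cd]] <- cbind(cc$counts, sample_id = cd)
      depths[[cd]] <- cc$depth
      summaries[[cd]] <- cbind(sample_id = cd, mp$summary,
                               rrna_filtered = fr$filtered_count)
      write_tsv(depth_to_runs(cc$depth), p("depth_", cd, ".tsv"))
    }
    counts_long <- do.call(rbind, counts_list)
    counts_long <- counts_long[, c("gene_id", "sample_id", "sense",
                                   "antisense")]
    rownames(counts_long) <- NULL
    summary_df <- alignment_rates(do.call(rbind, summaries))
    rownames(summary_df) <- NULL
    write_tsv(counts_long, p("counts.tsv"))
    write_tsv(summary_df, p("mapping_summary.tsv"))
    manifest$counts$map <- as.list(setNames(summary_df$uniquely_aligned,
                                            paste0("unique_", conditions)))
    results$mapping_summary <- summary_df
  }
  if (is.null(counts_long) && any(c("quant", "discover") %in% stages))
    counts_long <- read_tsv(p("counts.tsv"))
  if (!length(depths) && "discover" %in% stages)
    for (cd in conditions)
      depths[[cd]] <- runs_to_depth(read_tsv(p("depth_", cd, ".tsv")),
                                    genome_lens)

  ## ---- quant ----------------------------------------------------------
  norm <- NULL
  if ("quant" %in% stages) {
    say("quant: upper-quartile normalization")
    norm <- uq_normalize(counts_long)
    heg <- call_heg(norm, config)
    pw <- pathway_heg_fraction(heg, read_pathway_map(p("pathways.tsv")),
                               config)
    fc <- if (length(conditions) >= 2)
      fold_changes(norm, conditions[1], conditions[2]) else NULL
    write_tsv(norm, p("normalized.tsv"))
    write_tsv(data.frame(sample_id = rep(names(heg), lengths(heg)),
                         gene_id = unlist(heg, use.names = FALSE)),
              p("heg.tsv"))
    write_tsv(pw, p("pathway_report.tsv"))
    if (!is.null(fc)) write_tsv(fc, p("fold_changes.tsv"))
    manifest$counts$quant <- list(
      heg = lapply(heg, length),
      upper_quartiles = as.list(attr(norm, "upper_quartiles")))
    results$norm <- norm
    results$heg <- heg
    results$pathways <- pw
  }
  if (is.null(norm) && "discover" %in% stages) {
    norm <- read_tsv(p("normalized.tsv"))
  }

  ## ---- discover -------------------------------------------------------
  if ("discover" %in% stages) {
    counts_per_class <- list()
    coverages <- list()
    anti <- NULL
    for (cd in conditions) {
      say("discover: sample '%s'", cd)
      ec <- expressed_contigs(depths[[cd]], config)
      cl <- classify_contigs(ec, merged)
      counts_per_class[[cd]] <- cl$counts
      coverages[[cd]] <- genome_coverage(depths[[cd]])
      gff <- cl$contigs
      gff$gene_id <- gff$region_id
      write_gff3(gff, p("contigs_", cd, ".gff3"),
                 feature_type = "transcribed_region")
      if (cd == conditions[length(conditions)] && length(conditions) >= 2)
        anti <- antisense_report(cl$contigs, norm, merged,
                                 conditions[1], conditions[2])
    }
    class_df <- do.call(rbind, lapply(names(counts_per_class), function(cd)
      data.frame(sample_id = cd, t(counts_per_class[[cd]]))))
    write_tsv(class_df, p("contig_class_counts.tsv"))
    write_tsv(data.frame(sample_id = conditions,
                         coverage_pct = unlist(coverages)),
              p("genome_coverage.tsv"))
    if (!is.null(anti)) write_tsv(anti, p("antisense_report.tsv"))
    manifest$counts$discover <- lapply(counts_per_class, as.list)
    results$contig_classes <- counts_per_class
    results$antisense <- anti
    results$coverage <- coverages
  }

  ## ---- manifest -------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest$files <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$files) <- files
  manifest$package_version <- as.character(utils::packageVersion("strandtag"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done")
  results$manifest <- manifest
  invisible(results)
}
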