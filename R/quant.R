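# Upper-quartile normalization, high-expression-gene calling, pathway HEG
# fractions, and fold changes.

#' Upper-quartile normalization of stranded counts
#'
#' For each sample, the upper quartile (75th percentile, linear
#' interpolation between order statistics — `quantile` type 7) is computed
#' over the sense counts of *retained* genes — genes with a nonzero sense
#' count in at least one sample; genes at zero across every sample are
#' excluded from the quartile but still normalized (to 0) and reported.
#' Every cell, sense and antisense alike, is divided by its sample's
#' quartile, so both strand classes share one per-sample scale.
#'
#' @param counts Long data.frame: `gene_id`, `sample_id`, `sense`,
#'   `antisense` (non-negative integers).
#' @return The input with `sense_uq` and `antisense_uq` columns and an
#'   `upper_quartiles` attribute (named per-sample vector). Errors if any
#'   sample's quartile is 0.
#' @export
uq_normalize <- function(counts) {
  stopifnot(all(c("gene_id", "sample_id", "sense", "antisense") %in%
                  names(counts)))
  if (any(counts$sense < 0) || any(counts$antisense < 0))
    stopf("uq_normalize: negative counts")
  tot <- tapply(counts$sense, counts$gene_id, sum)
  retained <- names(tot)[tot > 0]
  if (!length(retained))
    stopf("uq_normalize: no gene with a nonzero count in any sample")
  samples <- unique(counts$sample_id)
  uqs <- vapply(samples, function(s) {
    x <- counts$sense[counts$sample_id == s & counts$gene_id %in% retained]
    as.numeric(quantile(x, 0.75, type = 7, names = FALSE))
  }, numeric(1))
  names(uqs) <- samples
  if (any(uqs == 0))
    stopf("uq_normalize: upper quartile is 0 in sample '%s'",
          names(uqs)[uqs == 0][1])
  q <- uqs[counts$sample_id]
  counts$sense_uq <- counts$sense / q
  counts$antisense_uq <- counts$antisense / q
  attr(counts, "upper_quartiles") <- uqs
  counts
}

#' Call high-expression genes (HEGs)
#'
#' A gene is a HEG in a sample when its normalized sense value strictly
#' exceeds `heg_uq_threshold` (10 at the default — roughly the top 2% of
#' genes under a realistic expression distribution).
#'
#' @param norm Output of [uq_normalize()].
#' @param config A [pipeline_config()].
#' @return Named list (one element per sample) of HEG gene-id vectors.
#' @export
call_heg <- function(norm, config = pipeline_config()) {
  sel <- norm$sense_uq > config$heg_uq_threshold
  out <- split(norm$gene_id[sel], norm$sample_id[sel])
  samples <- unique(norm$sample_id)
  missing <- setdiff(samples, names(out))
  out[missing] <- list(character(0))
  out[samples]
}

#' Pathways enriched in high-expression genes
#'
#' For each pathway and sample, the fraction of member genes called HEG;
#' pathways whose fraction strictly exceeds `pathway_heg_fraction` are
#' flagged `reported`. Pathways with no members are skipped with a
#' warning.
#'
#' @param heg_sets Named list from [call_heg()].
#' @param pathway_map data.frame `pathway_id`, `gene_id`.
#' @param config A [pipeline_config()].
#' @return data.frame: `pathway_id`, `sample_id`, `n_members`, `n_heg`,
#'   `fraction`, `reported`.
#' @export
pathway_heg_fraction <- function(heg_sets, pathway_map,
                                 config = pipeline_config()) {
  members <- split(pathway_map$gene_id, pathway_map$pathway_id)
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning("pathway_heg_fraction: skipping empty pathway(s): ",
            paste(names(members)[empty], collapse = ", "))
    members <- members[!empty]
  }
  out <- do.call(rbind, lapply(names(heg_sets), function(s) {
    heg <- heg_sets[[s]]
    data.frame(pathway_id = names(members),
               sample_id = s,
               n_members = lengths(members),
               n_heg = vapply(members, function(g)
                 sum(g %in% heg), integer(1)),
               stringsAsFactors = FALSE)
  }))
  out$fraction <- out$n_heg / out$n_members
  out$reported <- out$fraction > config$pathway_heg_fraction
  rownames(out) <- NULL
  out
}

ratio_flag <- function(num, den) {
  ifelse(den > 0, "ok", ifelse(num > 0, "infinite", "undefined"))
}

safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Fold changes between phases and between strands
#'
#' Cross-phase comparisons are computed on normalized (uq) values;
#' within-phase antisense:sense comparisons on raw tag counts — mirroring
#' which numbers each kind of ratio is meaningful on. Ratios with a zero
#' denominator are flagged `infinite` (numerator positive) or `undefined`
#' (both zero) and reported as `NA`.
#'
#' @param norm Output of [uq_normalize()] (needs `sense`, `antisense`,
#'   `sense_uq`, `antisense_uq`).
#' @param from,to Sample ids of the two phases being compared
#'   (`to / from`).
#' @return data.frame per gene: `sense_fold`, `antisense_fold`
#'   (normalized, to/from, with `*_flag`), `as_ratio_from`, `as_ratio_to`
#'   (raw antisense/sense within each phase, with flags).
#' @export
fold_changes <- function(norm, from, to) {
  a <- norm[norm$sample_id == from, ]
  b <- norm[norm$sample_id == to, ]
  b <- b[match(a$gene_id, b$gene_id), ]
  data.frame(
    gene_id = a$gene_id,
    sense_fold = safe_ratio(b$sense_uq, a$sense_uq),
    sense_flag = ratio_flag(b$sense_uq, a$sense_uq),
    antisense_fold = safe_ratio(b$antisense_uq, a$antisense_uq),
    antisense_flag = ratio_flag(b$antisense_uq, a$antisense_uq),
    as_ratio_from = safe_ratio(a$antisense, a$sense),
    as_ratio_from_flag = ratio_flag(a$antisense, a$sense),
    as_ratio_to = safe_ratio(b$antisense, b$sense),
    as_ratio_to_flag = ratio_flag(b$antisense, b$sense),
    stringsAsFactors = FALSE)
}
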