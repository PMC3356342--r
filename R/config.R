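#' Pipeline configuration
#'
#' All cut-offs used across the pipeline, each defaulting to the value the
#' analysis is defined with. Thresholds are strictly positive.
#'
#' @param min_protein_aa Minimum retained protein length in amino acids
#'   (genes shorter than 3x this in nucleotides are dropped).
#' @param max_internal_gap_nt A gene spanning a run of this many (or more)
#'   consecutive `N` bases is dropped; runs shorter than this are tolerated.
#' @param homolog_evalue BLASTP e-value at or below which a gene counts as
#'   homolog-bearing ("conserved").
#' @param family_evalue E-value cut for protein-family edges.
#' @param family_min_coverage HSP coverage of the shorter sequence that a
#'   family edge must strictly exceed.
#' @param nonortholog_evalue Pairs with mutual e-value above this (or no
#'   mutual hit) are considered non-orthologous when testing whether two
#'   same-homolog ORFs are a frameshift artifact; also the upper bound of
#'   the "slightly conserved" accuracy band.
#' @param interrupted_max_gap_bp Two same-homolog ORFs closer than this
#'   (intergenic bases, exclusive) form an interrupted pair.
#' @param read_len Tag length in bp.
#' @param half_len Length of the 5' half that decides placement.
#' @param max_mismatch_5prime Maximum substitutions tolerated in the 5' half.
#' @param heg_uq_threshold A gene is a high-expression gene (HEG) when its
#'   normalized sense value strictly exceeds this.
#' @param min_contig_bp Minimum length of a reported transcribed contig
#'   (contigs must be *more than* 180 bp, i.e. at least 181).
#' @param min_expressed_depth Per-base depth a position must reach to count
#'   as expressed when assembling transcribed contigs.
#' @param pathway_heg_fraction Pathways whose HEG fraction strictly exceeds
#'   this are reported.
#' @param rng_seed Root seed recorded in run manifests.
#'
#' @return A list with class `"pipeline_config"`.
#' @export
pipeline_config <- function(min_protein_aa = 60,
                            max_internal_gap_nt = 10,
                            homolog_evalue = 1e-10,
                            family_evalue = 1e-20,
                            family_min_coverage = 0.50,
                            nonortholog_evalue = 1e-5,
                            interrupted_max_gap_bp = 600,
                            read_len = 50,
                            half_len = 25,
                            max_mismatch_5prime = 2,
                            heg_uq_threshold = 10,
                            min_contig_bp = 181,
                            min_expressed_depth = 2,
                            pathway_heg_fraction = 0.10,
                            rng_seed = 1L) {
  cfg <- list(min_protein_aa = min_protein_aa,
              max_internal_gap_nt = max_internal_gap_nt,
              homolog_evalue = homolog_evalue,
              family_evalue = family_evalue,
              family_min_coverage = family_min_coverage,
              nonortholog_evalue = nonortholog_evalue,
              interrupted_max_gap_bp = interrupted_max_gap_bp,
              read_len = read_len,
              half_len = half_len,
              max_mismatch_5prime = max_mismatch_5prime,
              heg_uq_threshold = heg_uq_threshold,
              min_contig_bp = min_contig_bp,
              min_expressed_depth = min_expressed_depth,
              pathway_heg_fraction = pathway_heg_fraction,
              rng_seed = as.integer(rng_seed))
  num <- cfg[setdiff(names(cfg), "rng_seed")]
  bad <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1L && x > 0, logical(1))]
  if (length(bad))
    stop("pipeline_config: thresholds must be single positive numbers: ",
         paste(bad, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}
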