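# COG-style protein families: qualifying similarity edges, triangle
# (3-clique) seeding, and iterative merging of clusters sharing >= 2
# members.

#' Build the qualifying similarity edge set
#'
#' An undirected edge joins proteins `p` and `q` when some aggregated hit
#' in either direction has e-value at or below `family_evalue` (1e-20) AND
#' HSP total length covering strictly more than `family_min_coverage` of
#' the *shorter* of the two sequences. Self-pairs never form edges.
#'
#' @param hits Aggregated hits from [read_hits()] with `query_length` and
#'   `subject_length` populated.
#' @param config A [pipeline_config()].
#' @return data.frame of unique undirected edges (`from`, `to`, with
#'   `from < to` lexicographically).
#' @export
qualifying_edges <- function(hits, config = pipeline_config()) {
  empty <- data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  if (anyNA(hits$query_length) || anyNA(hits$subject_length))
    stopf("qualifying_edges: query/subject lengths are required for the coverage ratio (pass seq_lengths to read_hits)")
  cov <- hits$hsp_total_length / pmin(hits$query_length, hits$subject_length)
  ok <- hits$evalue <= config$family_evalue & cov > config$family_min_coverage
  if (!any(ok)) return(empty)
  a <- hits$query_id[ok]; b <- hits$subject_id[ok]
  from <- pmin(a, b); to <- pmax(a, b)
  keep <- from != to & !duplicated(paste(from, to, sep = "\r"))
  data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE)
}

# one pass: find cluster pairs sharing >= min_shared members
shared_pairs <- function(clusters, min_shared = 2L) {
  memb <- data.frame(
    member = unlist(clusters, use.names = FALSE),
    cl = rep(seq_along(clusters), lengths(clusters)))
  sp <- split(memb$cl, memb$member)
  sp <- sp[lengths(sp) >= 2L]
  if (!length(sp)) return(NULL)
  pair_keys <- unlist(lapply(sp, function(cls) {
    cls <- sort(unique(cls))
    if (length(cls) < 2L) return(character(0))
    cmb <- utils::combn(cls, 2L)
    paste(cmb[1, ], cmb[2, ])
  }), use.names = FALSE)
  if (!length(pair_keys)) return(NULL)
  tb <- table(pair_keys)
  hot <- names(tb)[tb >= min_shared]
  if (!length(hot)) return(NULL)
  do.call(rbind, strsplit(hot, " "))
}

#' Cluster proteins into families by iterative triangle merging
#'
#' Seeds one cluster per 3-clique of the edge graph, then repeatedly
#' merges any two clusters sharing at least `min_shared` members until no
#' such pair remains (the merge step operates on a derived graph whose
#' nodes are clusters and whose edges are sharing relations, taking
#' connected components, iterated to a fixpoint). Proteins belonging to no
#' 3-clique remain unclustered; the output partitions the clustered
#' proteins.
#'
#' The result is invariant to edge order and merge order: families are
#' reported sorted by their smallest member, members sorted within each
#' family.
#'
#' @param edges Edge data.frame from [qualifying_edges()].
#' @param min_shared Minimum shared members that triggers a merge
#'   (default 2).
#' @return data.frame (`family_id`, `protein_id`); every family has at
#'   least 3 members and families are disjoint.
#' @export
triangle_cluster <- function(edges, min_shared = 2L) {
  empty <- data.frame(family_id = character(), protein_id = character(),
                      stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(edges) == 0) return(empty)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g)
  tri <- igraph::triangles(g)
  if (!length(tri)) return(empty)
  vn <- igraph::V(g)$name
  tm <- matrix(vn[as.integer(tri)], nrow = 3L)
  clusters <- lapply(seq_len(ncol(tm)), function(k) sort(tm[, k]))
  clusters <- unique(clusters)

  repeat {
    pr <- shared_pairs(clusters, min_shared)
    if (is.null(pr)) break
    all_ids <- as.character(seq_along(clusters))
    cg <- igraph::graph_from_edgelist(pr, directed = FALSE)
    cg <- cg + igraph::vertices(setdiff(all_ids, igraph::V(cg)$name))
    comp <- igraph::components(cg)$membership[all_ids]
    merged <- unname(lapply(split(seq_along(clusters), comp), function(ix)
      sort(unique(unlist(clusters[ix], use.names = FALSE)))))
    if (length(merged) == length(clusters)) { clusters <- merged; break }
    clusters <- merged
  }

  ord <- order(vapply(clusters, `[`, character(1), 1L))
  clusters <- clusters[ord]
  data.frame(
    family_id = rep(sprintf("fam%04d", seq_along(clusters)),
                    lengths(clusters)),
    protein_id = unlist(clusters, use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Label proteins as shared, unique, or specific
#'
#' A protein is `unique` when it has no cross-species hit at or below
#' `homolog_evalue` (1e-10), and `specific` when additionally it is
#' un-annotated in every other species; otherwise `shared`.
#'
#' @param protein_ids Character vector of this species' protein ids.
#' @param hits_cross Cross-species hits (queries = `protein_ids`).
#' @param annotated_elsewhere Named logical: is the protein annotated in
#'   any other species? Missing names default to `FALSE`.
#' @param config A [pipeline_config()].
#' @return data.frame (`protein_id`, `label`).
#' @export
classify_unique_specific <- function(protein_ids, hits_cross,
                                     annotated_elsewhere = NULL,
                                     config = pipeline_config()) {
  has_hit <- rep(FALSE, length(protein_ids))
  if (!is.null(hits_cross) && nrow(hits_cross)) {
    ok <- hits_cross$evalue <= config$homolog_evalue
    has_hit <- protein_ids %in% hits_cross$query_id[ok]
  }
  ann <- rep(FALSE, length(protein_ids))
  if (!is.null(annotated_elsewhere)) {
    m <- match(protein_ids, names(annotated_elsewhere))
    ann[!is.na(m)] <- annotated_elsewhere[m[!is.na(m)]]
  }
  label <- ifelse(has_hit, "shared", ifelse(ann, "unique", "specific"))
  data.frame(protein_id = protein_ids, label = label,
             stringsAsFactors = FALSE)
}
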