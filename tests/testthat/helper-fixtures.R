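# Shared fixture builders and independent oracles. Everything is built in
# code at test time; no binary fixtures.

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

write_tmp_gff <- function(rows) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", rows), f)
  f
}

gff_row <- function(contig, source, start, end, strand, id,
                    type = "gene") {
  sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
          contig, source, type, start, end, strand, id)
}

write_tmp_hits <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  if (length(rows) == 0) file.create(f) else writeLines(rows, f)
  f
}

hit_row <- function(q, s, len, evalue) {
  paste(q, s, "90.0", len, 0, 0, 1, len, 1, len,
        format(evalue, scientific = TRUE), round(len * 2), sep = "\t")
}

gene_row <- function(gene_id, contig_id = "c1", start = 1L, end = 300L,
                     strand = "+", predictors = "A") {
  data.frame(gene_id = gene_id, contig_id = contig_id,
             start = as.integer(start), end = as.integer(end),
             strand = strand, predictors = predictors,
             stringsAsFactors = FALSE)
}

random_dna <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## ---- independent oracles ----------------------------------------------

# brute-force triangle clustering: exhaustive triple enumeration followed
# by naive repeated pairwise merging, restarted after every merge
oracle_triangle_cluster <- function(edges) {
  if (nrow(edges) == 0) return(list())
  vs <- sort(unique(c(edges$from, edges$to)))
  adj <- matrix(FALSE, length(vs), length(vs), dimnames = list(vs, vs))
  for (i in seq_len(nrow(edges))) {
    adj[edges$from[i], edges$to[i]] <- TRUE
    adj[edges$to[i], edges$from[i]] <- TRUE
  }
  cl <- list()
  n <- length(vs)
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (adj[i, j] && adj[i, k] && adj[j, k])
        cl[[length(cl) + 1L]] <- vs[c(i, j, k)]
    }
  }
  repeat {
    merged <- FALSE
    for (i in seq_along(cl)) {
      for (j in seq_along(cl)) {
        if (j <= i) next
        if (length(intersect(cl[[i]], cl[[j]])) >= 2) {
          cl[[i]] <- sort(union(cl[[i]], cl[[j]]))
          cl[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  unname(lapply(cl, sort))
}

families_as_sets <- function(fam) {
  unname(lapply(split(fam$protein_id, fam$family_id), sort))
}

same_partition <- function(a, b) {
  setequal(vapply(a, paste, "", collapse = ","),
           vapply(b, paste, "", collapse = ","))
}

random_edge_df <- function(n_vertices, p_edge) {
  vs <- sprintf("v%02d", seq_len(n_vertices))
  pairs <- t(utils::combn(vs, 2))
  sel <- stats::runif(nrow(pairs)) < p_edge
  data.frame(from = pairs[sel, 1], to = pairs[sel, 2],
             stringsAsFactors = FALSE)
}

# exhaustive-scan mapping oracle using Biostrings as the independent
# reference: all loci where the 5' 25-mer matches with <= 2 substitutions
oracle_map_read <- function(read, genome_fwd, genome_rev, half_len = 25,
                            max_mm = 2) {
  pat <- Biostrings::DNAString(substr(read, 1, half_len))
  hits <- list()
  for (ori in c("+", "-")) {
    subj <- if (ori == "+") genome_fwd else genome_rev
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm,
                                  with.indels = FALSE)
    if (length(m))
      hits[[ori]] <- data.frame(ori = ori, p = BiocGenerics::start(m))
  }
  do.call(rbind, c(hits, list(data.frame(ori = character(),
                                         p = integer()))))
}

# type-7 (linear interpolation) 75th percentile by explicit sort-and-index
oracle_p75 <- function(x) {
  x <- sort(x)
  h <- (length(x) - 1) * 0.75 + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
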