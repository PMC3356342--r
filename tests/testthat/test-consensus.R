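make_toy_genome <- function() {
  # 1200 bp contig with an N-free zone and two N runs of length 9 and 10
  set.seed(99)
  s <- random_dna(1200)
  substr(s, 401, 409) <- strrep("N", 9)    # 9-N run inside 361-540
  substr(s, 701, 710) <- strrep("N", 10)   # 10-N run inside 661-840
  Biostrings::DNAStringSet(c(c1 = s))
}

test_that("candidate filtering applies the 60-aa and 10-N rules at their boundaries", {
  genome <- make_toy_genome()
  genes <- rbind(
    gene_row("ok60aa", start = 1, end = 180),        # exactly 60 aa, no N
    gene_row("short59", start = 1, end = 177),       # 59 aa
    gene_row("nine_n", start = 361, end = 540),      # spans the 9-N run
    gene_row("ten_n", start = 661, end = 840))       # spans the 10-N run
  out <- filter_candidates(genes, genome)
  expect_setequal(out$gene_id, c("ok60aa", "nine_n"))
  drop <- attr(out, "dropped")
  expect_equal(drop$reason[drop$gene_id == "short59"], "below_min_aa")
  expect_equal(drop$reason[drop$gene_id == "ten_n"], "n_gap")

  expect_error(filter_candidates(gene_row("oob", start = 1100, end = 1300),
                                 genome), "outside")
})

test_that("prediction merging finds exact common models and keeps singletons", {
  a <- rbind(gene_row("x1", start = 100, end = 399),
             gene_row("a_only", start = 2000, end = 2299))
  b <- rbind(gene_row("x1", start = 100, end = 399, predictors = "B"))
  m <- merge_predictions(a, b)
  expect_equal(m$common$gene_id, "x1")
  expect_equal(m$common$predictors, "AB")
  expect_equal(m$only_a$gene_id, "a_only")
  expect_equal(nrow(m$only_b), 0L)
  # the unmatched A model survives as a single-predictor gene
  expect_true("a_only" %in% m$merged$gene_id)
  expect_equal(m$merged$accuracy_class[m$merged$gene_id == "a_only"],
               "predicted")
})

test_that("merging is symmetric up to the A/B labels", {
  set.seed(21)
  tr <- make_genome(1, 5e4, 60, seed = 21)
  pr <- corrupt_predictions(tr, 0.15, 0.1, 9, seed = 8)
  swap_tag <- function(m) { m$predictors <- NULL; m }
  m1 <- merge_predictions(pr$genes_a, pr$genes_b)
  m2 <- merge_predictions(pr$genes_b, pr$genes_a)
  key <- function(d) sort(paste(d$contig_id, d$strand, d$start, d$end))
  expect_identical(key(m1$common), key(m2$common))
  expect_identical(key(m1$only_a), key(m2$only_b))
  expect_identical(key(m1$only_b), key(m2$only_a))
})

test_that("same-strand partial overlaps are resolved by accuracy, not lost", {
  a <- gene_row("gA", start = 100, end = 399)
  b <- gene_row("gB", start = 250, end = 549, predictors = "B")
  hits <- data.frame(query_id = "gA", subject_id = "ref1", evalue = 1e-30,
                     hsp_total_length = 90, query_length = 100,
                     subject_length = 100, stringsAsFactors = FALSE)
  m <- merge_predictions(a, b, hits)
  expect_equal(m$only_a$gene_id, "gA")      # conserved beats predicted
  expect_equal(nrow(m$only_b), 0L)
  # opposite strands: both survive
  b2 <- gene_row("gB", start = 250, end = 549, strand = "-",
                 predictors = "B")
  m2 <- merge_predictions(a, b2)
  expect_equal(nrow(m2$only_a) + nrow(m2$only_b), 2L)
})

test_that("accuracy classes follow the e-value bands and predictor evidence", {
  genes <- rbind(gene_row("strong", predictors = "A"),
                 gene_row("mid", predictors = "AB"),
                 gene_row("none_ab", predictors = "AB"),
                 gene_row("none_a", predictors = "A"),
                 gene_row("weak_hit", predictors = "AB"))
  hits <- data.frame(
    query_id = c("strong", "mid", "weak_hit"),
    subject_id = c("r1", "r2", "r3"),
    evalue = c(1e-12, 1e-7, 1e-3),
    hsp_total_length = 90, query_length = 100, subject_length = 100,
    stringsAsFactors = FALSE)
  out <- classify_accuracy(genes, hits)
  cls <- setNames(out$accuracy_class, out$gene_id)
  expect_equal(cls[["strong"]], "conserved")
  expect_equal(cls[["mid"]], "slightly_conserved")
  expect_equal(cls[["none_ab"]], "hypothetical")
  expect_equal(cls[["none_a"]], "predicted")
  # a hit weaker than 1e-5 is not a qualifying hit
  expect_equal(cls[["weak_hit"]], "hypothetical")
})

frameshift_fixture <- function(gap) {
  genes <- rbind(
    gene_row("up", start = 1000, end = 1299, predictors = "AB"),
    gene_row("down", start = 1300 + gap, end = 1599 + gap,
             predictors = "AB"),
    gene_row("other", start = 9000, end = 9299, predictors = "AB"))
  hits <- data.frame(
    query_id = c("up", "down", "other"),
    subject_id = c("sameRef", "sameRef", "otherRef"),
    evalue = 1e-30, hsp_total_length = 90,
    query_length = 100, subject_length = 100, stringsAsFactors = FALSE)
  classify_accuracy(genes, hits)
}

test_that("interrupted ORF detection applies the strict 600-bp gap boundary", {
  g599 <- frameshift_fixture(599)
  art <- detect_frameshift_artifacts(g599)
  expect_equal(nrow(art$interrupted), 1L)
  expect_equal(art$interrupted$gap_bp, 599L)
  expect_equal(art$rates$interrupted_rate, 2 / 3)
  expect_equal(art$n_homolog_genes, 3L)

  g600 <- frameshift_fixture(600)
  expect_equal(nrow(detect_frameshift_artifacts(g600)$interrupted), 0L)
})

test_that("a truly orthologous mutual hit vetoes the interrupted call", {
  g <- frameshift_fixture(100)
  mutual <- data.frame(query_id = "up", subject_id = "down", evalue = 1e-20,
                       hsp_total_length = 90, query_length = 100,
                       subject_length = 100, stringsAsFactors = FALSE)
  expect_equal(nrow(detect_frameshift_artifacts(g, mutual)$interrupted), 0L)
  weak_mutual <- transform(mutual, evalue = 1e-3)
  expect_equal(nrow(detect_frameshift_artifacts(g, weak_mutual)$interrupted), 1L)
})

test_that("overlapping same-homolog ORFs are reported as overlapping pairs", {
  genes <- rbind(gene_row("o1", start = 100, end = 399, predictors = "AB"),
                 gene_row("o2", start = 300, end = 599, predictors = "AB"))
  hits <- data.frame(query_id = c("o1", "o2"), subject_id = "ref",
                     evalue = 1e-30, hsp_total_length = 90,
                     query_length = 100, subject_length = 100,
                     stringsAsFactors = FALSE)
  art <- detect_frameshift_artifacts(classify_accuracy(genes, hits))
  expect_equal(nrow(art$overlapping), 1L)
  expect_equal(nrow(art$interrupted), 0L)
  expect_equal(art$rates$overlapping_rate, 1)
})

test_that("planted split genes are recovered at high recall", {
  tr <- make_genome(1, 1e5, 200, seed = 13)
  pr <- corrupt_predictions(tr, 0.05, 0.10, 9, seed = 6)
  hs <- simulate_hits(tr, rbind(pr$genes_a, pr$genes_b), seed = 7)
  f <- tempfile(); write_hits(hs$rows, f)
  hits <- read_hits(f, hs$seq_lengths)
  ga <- filter_candidates(pr$genes_a, tr$genome)
  gb <- filter_candidates(pr$genes_b, tr$genome)
  mg <- merge_predictions(ga, gb, hits)
  art <- detect_frameshift_artifacts(mg$merged, hits)
  det <- apply(art$interrupted[, c("gene_1", "gene_2")], 1,
               function(p) paste(sort(p), collapse = " "))
  planted <- apply(pr$split_records[, c("frag_a", "frag_b")], 1,
                   function(p) paste(sort(p), collapse = " "))
  expect_gte(mean(planted %in% det), 0.95)
  # merged output never violates the retention filters
  expect_true(all(mg$merged$end - mg$merged$start + 1L >= 180))
})

test_that("codon usage counts and synonymous frequencies are exact", {
  genome <- Biostrings::DNAStringSet(c(c1 = "ATGTTTTAA"))
  g <- gene_row("one", start = 1, end = 9)
  cu <- codon_usage(g, genome)
  got <- setNames(cu$count, cu$codon)
  expect_equal(got[["ATG"]], 1L)
  expect_equal(got[["TTT"]], 1L)
  expect_equal(got[["TAA"]], 1L)
  expect_equal(sum(cu$count), 3L)

  sums <- tapply(cu$rel_freq, cu$aa, sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))

  expect_warning(codon_usage(gene_row("bad", start = 1, end = 8), genome),
                 "frame")
})

test_that("codon usage recovers the generator's third-position bias", {
  tr <- make_genome(2, 4e5, 1200, seed = 17)
  cu <- codon_usage(tr$genes[!tr$genes$frameshift, ], tr$genome)
  w <- tr$codon_weights
  aa_of <- Biostrings::GENETIC_CODE[names(w)]
  for (cod in c("TTT", "TTC", "TAT", "TAC", "GGA", "GGC")) {
    syn <- names(w)[aa_of == aa_of[[cod]]]
    expected <- w[[cod]] / sum(w[syn])
    got <- cu$rel_freq[cu$codon == cod]
    expect_lt(abs(got - expected), 0.02)
  }
  # the generator's signature: TTC preferred over TTT, TAC over TAT
  expect_gt(cu$rel_freq[cu$codon == "TTC"], cu$rel_freq[cu$codon == "TTT"])
})
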