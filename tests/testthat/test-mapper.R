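# A 20-kb toy genome with a 400-bp duplicated block so that multi-mapping
# is exercised.
mapper_genome <- function(seed = 5) {
  set.seed(seed)
  s <- random_dna(20000)
  dup <- substr(s, 3001, 3400)
  substr(s, 15001, 15400) <- dup
  Biostrings::DNAStringSet(c(chr = s))
}

mutate_bases <- function(read, positions) {
  s <- strsplit(read, "")[[1]]
  for (p in positions) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  paste(s, collapse = "")
}

test_that("k-mer index lookups equal a naive full scan", {
  set.seed(31)
  genome <- Biostrings::DNAStringSet(c(g = random_dna(10000)))
  idx <- build_index(genome)
  gchr <- as.character(genome)[[1]]
  grev <- strandtag:::revcomp_chr(gchr)
  naive_scan <- function(kmer) {
    L <- nchar(gchr); k <- nchar(kmer)
    hits <- list()
    for (p in seq_len(L - k + 1)) {
      if (substr(gchr, p, p + k - 1) == kmer)
        hits[[length(hits) + 1]] <- c("+", p, p + k - 1)
      if (substr(grev, p, p + k - 1) == kmer)
        hits[[length(hits) + 1]] <- c("-", L - (p + k - 1) + 1, L - p + 1)
    }
    hits
  }
  for (i in 1:15) {
    p <- sample.int(9975, 1)
    kmer <- substr(gchr, p, p + 24)
    if (i %% 3 == 0) kmer <- strandtag:::revcomp_chr(kmer)
    got <- kmer_positions(idx, kmer)
    want <- naive_scan(kmer)
    expect_equal(nrow(got), length(want))
    got_key <- sort(paste(got$strand, got$start, got$end))
    want_key <- sort(vapply(want, paste, "", collapse = " "))
    expect_identical(got_key, want_key)
  }
})

test_that("palindromic loci are reported once per strand", {
  pal <- strrep("ACGT", 6)  # 24 bp, its own reverse complement
  set.seed(8)
  g <- Biostrings::DNAStringSet(c(p = paste0(random_dna(5000), pal,
                                             random_dna(5000))))
  got <- kmer_positions(build_index(g), pal)
  expect_equal(nrow(got), 2L)
  expect_setequal(got$strand, c("+", "-"))
  expect_equal(unique(got$start), 5001L)
})

test_that("split-read mapping accepts unique loci and applies the mismatch budget", {
  genome <- mapper_genome()
  idx <- build_index(genome)
  gchr <- as.character(genome)[[1]]

  # error-free read from a unique locus
  r0 <- substr(gchr, 7001, 7050)
  res <- map_tag(r0, idx)
  expect_equal(res$status, "accepted")
  expect_equal(res$alignment$start, 7001L)
  expect_equal(res$alignment$mismatches, 0L)
  expect_true(res$alignment$three_prime_match)

  # two substitutions in the 5' half: still placed
  r2 <- mutate_bases(r0, c(3, 17))
  expect_equal(map_tag(r2, idx)$status, "accepted")
  expect_equal(map_tag(r2, idx)$alignment$mismatches, 2L)

  # three substitutions in the 5' half: over budget
  r3 <- mutate_bases(r0, c(3, 11, 21))
  expect_equal(map_tag(r3, idx)$reason, "unmapped")

  # mismatches in the 3' half do not affect placement, only the record
  r3p <- mutate_bases(r0, c(30, 40))
  res3p <- map_tag(r3p, idx)
  expect_equal(res3p$status, "accepted")
  expect_equal(res3p$alignment$mismatches, 0L)
  expect_false(res3p$alignment$three_prime_match)

  # read from the duplicated block: rejected as multi-mapped
  rd <- substr(gchr, 3101, 3150)
  expect_equal(map_tag(rd, idx)$reason, "multi_mapped")

  # minus-strand read reports plus-strand coordinates
  rm <- strandtag:::revcomp_chr(substr(gchr, 9001, 9050))
  resm <- map_tag(rm, idx)
  expect_equal(resm$status, "accepted")
  expect_equal(resm$alignment$strand, "-")
  expect_equal(resm$alignment$start, 9001L)
  expect_equal(resm$alignment$five_prime_pos, 9050L)

  expect_error(map_tag(substr(gchr, 1, 49), idx), "50")
})

test_that("mapping equals the exhaustive scan on random reads", {
  genome <- mapper_genome(seed = 6)
  idx <- build_index(genome)
  gchr <- as.character(genome)[[1]]
  gfwd <- Biostrings::DNAString(gchr)
  grev <- Biostrings::reverseComplement(gfwd)
  set.seed(77)
  n <- 1000
  reads <- character(n)
  for (i in seq_len(n)) {
    kind <- sample(c("clean", "mut", "rand"), 1, prob = c(.45, .35, .2))
    if (kind == "rand") {
      reads[i] <- random_dna(50)
    } else {
      p <- sample.int(19951, 1)
      r <- substr(gchr, p, p + 49)
      if (sample(c(TRUE, FALSE), 1)) r <- strandtag:::revcomp_chr(r)
      if (kind == "mut")
        r <- mutate_bases(r, sample.int(50, sample.int(4, 1)))
      reads[i] <- r
    }
  }
  got <- map_tags(reads, idx)
  for (i in seq_len(n)) {
    orc <- oracle_map_read(reads[i], gfwd, grev)
    want <- if (nrow(orc) == 1) "accepted"
            else if (nrow(orc) == 0) "unmapped" else "multi_mapped"
    expect_equal(got$status$status[i], want)
    if (want == "accepted") {
      a <- got$alignments[got$alignments$read_id == got$status$read_id[i], ]
      L <- nchar(gchr)
      expect_equal(a$five_prime_pos,
                   if (orc$ori == "+") orc$p else L - orc$p + 1)
      expect_equal(a$strand, orc$ori)
    }
  }
  expect_true(all(got$summary$uniquely_aligned <= got$summary$aligned))
  expect_true(got$summary$aligned <= got$summary$total)
})

test_that("short contigs are skipped with a warning", {
  g <- Biostrings::DNAStringSet(c(tiny = "ACGTACGT",
                                  ok = paste(rep("ACGT", 20), collapse = "")))
  expect_warning(idx <- build_index(g), "tiny")
  expect_equal(idx$contig_ids, "ok")
})

test_that("rRNA filtering drops alignments starting inside intervals only", {
  aln <- data.frame(read_id = c("r1", "r2", "r3"),
                    contig_id = "c1", strand = "+",
                    start = c(150, 201, 100), end = c(199, 250, 149),
                    five_prime_pos = c(150, 201, 100),
                    mismatches = 0L, three_prime_match = TRUE,
                    stringsAsFactors = FALSE)
  rrna <- GenomicRanges::GRanges("c1", IRanges::IRanges(120, 200))
  fr <- filter_rrna(aln, rrna)
  # r1 starts at 150 (inside); r2 at 201 (1 bp past the end) and r3 at
  # 100 (before the interval) are kept
  expect_setequal(fr$kept$read_id, c("r2", "r3"))
  expect_equal(fr$filtered_count, 1L)
})

test_that("stranded counting assigns tags by 5' position and reconciles", {
  genes <- rbind(gene_row("plus_g", start = 1000, end = 1299, strand = "+"),
                 gene_row("minus_g", start = 2000, end = 2299, strand = "-"))
  aln <- data.frame(
    read_id = c("s1", "a1", "i1", "m1"),
    contig_id = "c1",
    strand = c("+", "-", "+", "-"),
    start = c(1100, 1150, 5000, 2100),
    end = c(1149, 1199, 5049, 2149),
    five_prime_pos = c(1100, 1199, 5000, 2149),
    mismatches = 0L, three_prime_match = TRUE, stringsAsFactors = FALSE)
  cc <- coverage_and_counts(aln, genes, c(c1 = 10000L))
  cts <- setNames(split(cc$counts[, c("sense", "antisense")],
                        cc$counts$gene_id),
                  unique(cc$counts$gene_id))
  expect_equal(cc$counts$sense[cc$counts$gene_id == "plus_g"], 1L)
  expect_equal(cc$counts$antisense[cc$counts$gene_id == "plus_g"], 1L)
  expect_equal(cc$counts$sense[cc$counts$gene_id == "minus_g"], 1L)
  expect_equal(cc$unassigned, 1L)
  expect_equal(sum(cc$counts$sense) + sum(cc$counts$antisense) +
                 cc$unassigned, nrow(aln))
  # depth covers the footprints on the right strands
  expect_equal(sum(cc$depth$c1[["+"]]), 100L)
  expect_equal(sum(cc$depth$c1[["-"]]), 100L)
  expect_equal(cc$depth$c1[["+"]][1100], 1L)
  expect_equal(cc$depth$c1[["-"]][1199], 1L)
})

test_that("error-free synthetic reads recover their recorded origin", {
  tr <- make_genome(1, 5e4, 60, seed = 23)
  tg <- simulate_tags(tr, "log", 10, seed = 3, error_frac = 0)
  idx <- build_index(tr$genome)
  mp <- map_tags(tg$reads, idx)
  m <- merge(mp$alignments, tg$truth, by = "read_id")
  agree <- m$start.x == m$start.y & m$end.x == m$end.y &
    m$strand.x == m$strand.y & m$contig_id.x == m$contig_id.y
  expect_gte(mean(agree), 0.999)
})
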