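counts_df <- function(genes, samples, sense, antisense = 0) {
  d <- expand.grid(gene_id = genes, sample_id = samples,
                   stringsAsFactors = FALSE)
  d$sense <- sense
  d$antisense <- antisense
  d
}

test_that("upper-quartile normalization matches its order-statistic definition", {
  # constant column: quartile c, every normalized value 1
  d <- counts_df(sprintf("g%02d", 1:8), "s1", sense = 7L)
  n <- uq_normalize(d)
  expect_equal(unname(attr(n, "upper_quartiles")["s1"]), 7)
  expect_true(all(n$sense_uq == 1))

  # genes at zero across all samples are excluded from the quartile but
  # still reported, normalized to 0
  d <- rbind(counts_df(sprintf("g%02d", 1:8), "s1", sense = 7L),
             counts_df("zzz", "s1", sense = 0L))
  n <- uq_normalize(d)
  expect_equal(unname(attr(n, "upper_quartiles")["s1"]), 7)
  expect_equal(n$sense_uq[n$gene_id == "zzz"], 0)

  # 1..100: frozen type-7 value, cross-checked against the sort-and-index
  # oracle
  d <- counts_df(sprintf("g%03d", 1:100), "s1", sense = 1:100)
  n <- uq_normalize(d)
  q <- unname(attr(n, "upper_quartiles")["s1"])
  expect_equal(q, 75.25)
  expect_equal(q, oracle_p75(1:100))

  # antisense shares the sample's quartile
  d$antisense <- rep(151L, 100)
  n <- uq_normalize(d)
  expect_equal(unique(n$antisense_uq), 151 / 75.25)
})

test_that("post-normalization percentile and scale equivariance hold", {
  tr <- make_genome(1, 6e4, 100, seed = 29)
  cts <- counts_from_profile(tr, depth_mean = 25, seed = 4)
  n <- uq_normalize(cts)
  retained <- names(which(tapply(cts$sense, cts$gene_id, sum) > 0))
  for (s in unique(n$sample_id)) {
    x <- n$sense_uq[n$sample_id == s & n$gene_id %in% retained]
    expect_lt(abs(quantile(x, 0.75, type = 7, names = FALSE) - 1), 1e-9)
  }
  # multiplying one sample's raw counts by c leaves its normalized values
  # unchanged
  scaled <- cts
  sel <- scaled$sample_id == "log"
  scaled$sense[sel] <- scaled$sense[sel] * 13L
  scaled$antisense[sel] <- scaled$antisense[sel] * 13L
  n2 <- uq_normalize(scaled)
  expect_equal(n2$sense_uq[sel], n$sense_uq[sel])
  expect_equal(n2$antisense_uq[sel], n$antisense_uq[sel])
})

test_that("an all-zero sample is a hard error naming the sample", {
  d <- rbind(counts_df("g1", "good", sense = 10L),
             counts_df("g1", "empty", sense = 0L))
  d$sense[d$sample_id == "good"] <- 10L
  expect_error(uq_normalize(d), "empty")
})

test_that("HEG calling uses a strict threshold", {
  d <- data.frame(gene_id = c("CuHxt6", "CuHxt10", "edge"),
                  sample_id = "log",
                  sense = c(100L, 1L, 10L), antisense = 0L,
                  sense_uq = c(52.84, 0.17, 10), antisense_uq = 0,
                  stringsAsFactors = FALSE)
  heg <- call_heg(d)
  expect_equal(heg$log, "CuHxt6")      # 52.84 in, 0.17 out, 10 exactly out
})

test_that("pathway HEG fractions apply the strict 10% rule", {
  pw <- data.frame(pathway_id = rep(c("pwA", "pwB"), each = 10),
                   gene_id = sprintf("g%02d", 1:20),
                   stringsAsFactors = FALSE)
  heg <- list(log = c("g01", "g02", "g11"))  # pwA: 2/10, pwB: 1/10
  out <- pathway_heg_fraction(heg, pw)
  expect_true(out$reported[out$pathway_id == "pwA"])
  expect_false(out$reported[out$pathway_id == "pwB"])
  expect_equal(out$fraction, c(0.2, 0.1))

  # planted enrichment in synthetic data is recovered exactly
  tr <- make_genome(1, 1e5, 200, seed = 31)
  cts <- counts_from_profile(tr, depth_mean = 20, seed = 5)
  n <- uq_normalize(cts)
  hegs <- call_heg(n)
  planted <- data.frame(pathway_id = "hot", gene_id = hegs$log,
                        stringsAsFactors = FALSE)
  out <- pathway_heg_fraction(hegs, rbind(pw, planted))
  expect_equal(out$fraction[out$pathway_id == "hot" &
                              out$sample_id == "log"], 1)
})

test_that("fold changes ratio the right quantities with the right flags", {
  expr <- utils::read.delim(
    system.file("extdata", "cutilis_expression.tsv", package = "strandtag"),
    stringsAsFactors = FALSE)
  fc <- fold_changes(expr, "log", "stationary")
  adh1 <- fc[fc$gene_id == "cut01g0000110", ][1, ]
  # raw within-phase tag ratio: 226,551 / 145,562, printed as 1.6
  expect_equal(round(adh1$as_ratio_to, 1), 1.6)
  expect_equal(adh1$as_ratio_to, 226551 / 145562, tolerance = 1e-12)
  # normalized cross-phase antisense ratio: 81.83 / 0.88
  expect_equal(adh1$antisense_fold, 81.83 / 0.88, tolerance = 1e-12)
  # equal values give ratio 1
  d <- data.frame(gene_id = "g", sample_id = c("log", "stationary"),
                  sense = c(5L, 5L), antisense = c(2L, 2L),
                  sense_uq = c(1.5, 1.5), antisense_uq = c(0.4, 0.4),
                  stringsAsFactors = FALSE)
  expect_equal(fold_changes(d, "log", "stationary")$sense_fold, 1)
  # zero denominators are flagged, not divided
  d2 <- data.frame(gene_id = "g", sample_id = c("log", "stationary"),
                   sense = c(0L, 3L), antisense = c(0L, 0L),
                   sense_uq = c(0, 1), antisense_uq = c(0, 0),
                   stringsAsFactors = FALSE)
  fc2 <- fold_changes(d2, "log", "stationary")
  expect_equal(fc2$sense_flag, "infinite")
  expect_equal(fc2$antisense_flag, "undefined")
  expect_true(is.na(fc2$sense_fold))
})
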