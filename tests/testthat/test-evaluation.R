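# PR/AUPR machinery, baselines, FRiP QC and entropy.

test_that("aupr: perfect separation and hand-checked 20-point case", {
  expect_equal(aupr(c(0.9, 0.8, 0.7, 0.2, 0.1), c(1, 1, 1, 0, 0)), 1)
  set.seed(61)
  scores <- round(runif(20), 2)
  labels <- rbinom(20, 1, 0.4)
  if (sum(labels) %in% c(0, 20)) labels[1:2] <- c(0, 1)
  expect_equal(aupr(scores, labels), oracle_aupr(scores, labels),
               tolerance = 1e-12)
  expect_error(aupr(1:4, rep(1, 4)), "both classes")
})

test_that("aupr equals threshold enumeration on random instances incl. ties", {
  set.seed(62)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    # coarse rounding forces tied scores
    scores <- round(runif(n), sample(1:2, 1))
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0) labels[sample(n, 1)] <- 1
    if (sum(labels) == n) labels[sample(n, 1)] <- 0
    expect_equal(aupr(scores, labels), oracle_aupr(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("aupr is invariant under strictly monotone score transforms", {
  set.seed(63)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, 0.2)
  base <- aupr(scores, labels)
  expect_equal(aupr(plogis(scores), labels), base, tolerance = 1e-12)
  expect_equal(aupr(exp(scores), labels), base, tolerance = 1e-12)
  expect_equal(aupr(rank(scores, ties.method = "min"), labels), base,
               tolerance = 1e-12)
})

test_that("baselines rank by single features and error on missing columns", {
  set.seed(64)
  n <- 400
  atac <- rlnorm(n)
  motif <- rnorm(n)
  labels <- as.integer(rank(atac) > n - 20) # labels purely ATAC-driven
  feats <- data.frame(atac_mean = atac, affinity_pscore = motif)
  b <- baselines(feats, labels)
  expect_equal(b$atac_aupr, 1)
  expect_lt(b$motif_aupr, 0.3) # independent feature stays near prevalence
  expect_error(baselines(feats[, 1, drop = FALSE], labels), "affinity_pscore")
})

test_that("precision_threshold finds the smallest workable cutoff", {
  curve <- pr_curve(c(0.9, 0.8, 0.6, 0.4, 0.3), c(1, 1, 0, 1, 0))
  # hand enumeration: thresholds 0.9, 0.8 give precision 1
  got <- precision_threshold(curve, 0.99)
  expect_true(got$reachable)
  expect_equal(got$threshold, 0.8)
  # precision 0.75 reached at threshold 0.4 (3 TP / 4 called)
  expect_equal(precision_threshold(curve, 0.75)$threshold, 0.4)
  out <- precision_threshold(pr_curve(c(0.2, 0.9), c(1, 0)), 0.9)
  expect_false(out$reachable)
})

test_that("frip matches a per-read loop and flips exactly at 0.02", {
  set.seed(65)
  n <- 300
  start <- sample(0:10000, n)
  reads <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                      start = start, end = start + 50)
  pstart <- sample(0:10000, 15)
  peaks <- data.frame(chrom = sample(c("chr1", "chr2"), 15, TRUE),
                      start = pstart, end = pstart + 400)
  got <- frip(reads, peaks)
  want <- mean(vapply(seq_len(n), function(i) {
    mid <- floor((reads$start[i] + reads$end[i]) / 2)
    any(peaks$chrom == reads$chrom[i] & peaks$start <= mid & mid < peaks$end)
  }, logical(1)))
  expect_equal(got, want)
  # extremes
  inpeak <- data.frame(chrom = "chr1", start = 100, end = 150)
  onepeak <- data.frame(chrom = "chr1", start = 0, end = 1000)
  expect_equal(frip(inpeak, onepeak), 1)
  expect_equal(frip(inpeak, data.frame(chrom = "chr1", start = 5000,
                                       end = 6000)), 0)
  expect_equal(frip(inpeak, peaks[0, ]), 0)
  # monotone as peaks are added
  expect_gte(frip(reads, rbind(peaks, onepeak)), got)
  # QC pass flag flips exactly at the 0.02 cutoff
  mk_reads <- function(n_in, n_out) rbind(
    data.frame(chrom = "chr1", start = seq_len(n_in) * 2,
               end = seq_len(n_in) * 2 + 10),
    data.frame(chrom = "chr1", start = 5000 + seq_len(n_out) * 100,
               end = 5000 + seq_len(n_out) * 100 + 10))
  peak <- data.frame(chrom = "chr1", start = 0, end = 300)
  f_pass <- frip(mk_reads(2, 98), peak)
  expect_equal(f_pass, 0.02)
  expect_true(qc_record("d1", f_pass)$pass)
  f_fail <- frip(mk_reads(1, 99), peak)
  expect_false(qc_record("d2", f_fail)$pass)
})

test_that("expression entropy: uniform, one-hot, and the direct formula", {
  expect_equal(expression_entropy(rep(3, 80)), log2(80), tolerance = 1e-12)
  expect_equal(expression_entropy(c(10, 0, 0, 0)), 0)
  set.seed(67)
  v <- rexp(25)
  p <- v / sum(v)
  expect_equal(expression_entropy(v), -sum(p * log2(p)), tolerance = 1e-12)
  expect_error(expression_entropy(rep(0, 5)), "all-zero")
  expect_error(expression_entropy(5), ">= 2")
})

test_that("relative performance reproduces the ChIP-signal normalization", {
  expect_equal(relative_performance(0.4, 0.4), 1)
  # a model at 0.31 against a 0.34 ChIP-signal bound reaches ~92%
  expect_equal(relative_performance(0.31, 0.34), 0.912, tolerance = 0.005)
  expect_error(relative_performance(0.3, 0), "> 0")
})

test_that("pooled PR concatenates pairs before thresholding", {
  s1 <- c(0.9, 0.1); l1 <- c(1, 0)
  s2 <- c(0.8, 0.7); l2 <- c(0, 1)
  pooled <- pooled_pr_curve(list(s1, s2), list(l1, l2))
  expect_equal(pooled$aupr, aupr(c(s1, s2), c(l1, l2)))
  expect_equal(pooled$n_pos, 2)
})
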