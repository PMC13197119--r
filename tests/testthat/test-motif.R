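# PWM scanning, total affinity, and the -log(0.0001 + p) affinity p-score.

consensus_pwm <- function(seq_str, pseudocount = 0.01) {
  codes <- match(strsplit(seq_str, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix(0, nrow = length(codes), ncol = 4)
  m[cbind(seq_along(codes), codes)] <- 1
  pwm_matrix("cons", m, pseudocount = pseudocount)
}

test_that("scan_max_score edge cases: short sequence and no positive site", {
  p <- consensus_pwm("ACGTAC")
  expect_equal(scan_max_score("ACG", p), 0)
  # a maximally mismatching sequence scores 0 (all sites negative)
  expect_equal(scan_max_score("TTTTTTTT", consensus_pwm("ACACAC")), 0)
  expect_error(scan_max_score("ACGZ", p), "invalid characters")
})

test_that("consensus match equals the per-position hand sum", {
  p <- consensus_pwm("ACGTAC")
  # per-position log-odds of the consensus base under uniform background
  hand <- sum(log(p$probs[cbind(1:6, match(strsplit("ACGTAC", "")[[1]],
                                           c("A", "C", "G", "T")))] / 0.25))
  got <- scan_max_score(paste0("TT", "ACGTAC", "GG"), p)
  expect_equal(got, hand, tolerance = 1e-12)
})

test_that("scan matches the brute-force offset x strand oracle on random sequences", {
  set.seed(11)
  for (i in 1:10) {
    pwm <- random_pwm(L = sample(5:9, 1))
    seq <- random_dna(200, with_n = (i %% 3 == 0))
    want <- oracle_site_scores(seq, pwm)
    got <- site_scores(seq, pwm)
    expect_equal(sort(got), sort(want), tolerance = 1e-9)
    pos <- want[want > 0]
    expect_equal(scan_max_score(seq, pwm),
                 if (length(pos)) max(pos) else 0, tolerance = 1e-9)
  }
})

test_that("scan_max_score is strand-symmetric", {
  set.seed(12)
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  for (i in 1:10) {
    pwm <- random_pwm()
    seq <- random_dna(80)
    expect_equal(scan_max_score(seq, pwm), scan_max_score(rc(seq), pwm),
                 tolerance = 1e-12)
  }
})

test_that("total_affinity: edge cases and two-term single-placement identity", {
  pwm <- random_pwm(L = 8)
  expect_equal(total_affinity("ACGT", pwm), 0)
  seq <- random_dna(8) # exactly one placement per strand
  s <- site_scores(seq, pwm)
  expect_length(s, 2)
  expect_equal(total_affinity(seq, pwm), exp(s[1]) + exp(s[2]),
               tolerance = 1e-12)
})

test_that("total_affinity dominates the max site and grows under appending", {
  set.seed(13)
  for (i in 1:10) {
    pwm <- random_pwm()
    s <- random_dna(60)
    ms <- scan_max_score(s, pwm)
    if (ms > 0) expect_gte(total_affinity(s, pwm), exp(ms))
    expect_gte(total_affinity(paste0(s, random_dna(20)), pwm),
               total_affinity(s, pwm))
    # duplication roughly doubles affinity (boundary placements only add)
    expect_gte(total_affinity(paste0(s, s), pwm), 2 * total_affinity(s, pwm) * 0.999)
  }
})

test_that("affinity_pscore implements the smoothed counting formula", {
  pwm <- consensus_pwm("ACGTACGT")
  set.seed(14)
  controls <- replicate(99, random_dna(40))
  # sequence with three consensus hits beats every random control
  seq <- paste0("ACGTACGT", "ACGTACGT", "ACGTACGT")
  expect_gt(total_affinity(seq, pwm),
            max(vapply(controls, total_affinity, numeric(1), pwm = pwm)))
  expect_equal(affinity_pscore(seq, pwm, controls), -log(1e-4 + 1 / 100),
               tolerance = 1e-12)
  # worst case: affinity below all controls -> p = 1, score at the floor
  worst <- affinity_pscore("TTTT", consensus_pwm("ACACACAC"), controls)
  expect_equal(worst, -log(1e-4 + 1), tolerance = 1e-12)
  expect_error(affinity_pscore(seq, pwm, character(0)), "empty control")
})

test_that("affinity_pscore is monotone in total affinity for fixed controls", {
  pwm <- consensus_pwm("ACGTAC")
  set.seed(15)
  ctl_aff <- runif(100, 0, 50)
  seqs <- c("TTTTTTTT", "ACGTACTT", paste0("ACGTAC", "ACGTAC"))
  affs <- vapply(seqs, total_affinity, numeric(1), pwm = pwm)
  scores <- vapply(seqs, affinity_pscore, numeric(1), pwm = pwm,
                   control_affinities = ctl_aff)
  expect_equal(order(affs), order(scores))
  # score range invariant
  expect_true(all(scores > -log(1.0001) - 1e-12))
  expect_true(all(scores <= -log(1e-4) + 1e-12))
})

test_that("TRANSFAC round trip preserves PWMs", {
  set.seed(16)
  pwms <- list(TFa = random_pwm("TFa", 6), TFb = random_pwm("TFb", 9))
  path <- tempfile(fileext = ".transfac")
  write_transfac(pwms, path)
  # written probabilities already carry the pseudocount; read with 0
  back <- read_transfac(path, pseudocount = 0)
  expect_equal(names(back), c("TFa", "TFb"))
  expect_equal(unname(back$TFa$probs), unname(pwms$TFa$probs),
               tolerance = 1e-5)
  expect_equal(pwm_consensus(back$TFb), pwm_consensus(pwms$TFb))
})

test_that("pwm_matrix validates shape and normalizes rows", {
  expect_error(pwm_matrix("x", matrix(1, 3, 4)), "length")
  expect_error(pwm_matrix("x", matrix(1, 6, 3)), "4 columns")
  p <- pwm_matrix("x", matrix(c(8, 1, 1, 0), 5, 4, byrow = TRUE))
  expect_equal(rowSums(p$probs), rep(1, 5), tolerance = 1e-9)
})
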