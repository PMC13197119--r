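# Independent reference implementations used as oracles. These deliberately
# take different computational routes than the package code.

# Rule-by-rule interpreter for ternary label aggregation: rules as data,
# evaluated in order, first match wins.
oracle_aggregate <- function(labels) {
  n <- length(labels)
  cnt <- table(factor(labels, levels = c("B", "A", "U")))
  env <- list(fB = cnt[["B"]] / n, fA = cnt[["A"]] / n,
              nB = cnt[["B"]], nA = cnt[["A"]])
  rules <- list(
    list(test = function(e) e$fB >= 0.40, out = "B"),
    list(test = function(e) e$fB >= 0.20 && e$fA >= 0.30, out = "B"),
    list(test = function(e) e$nB >= 1 && e$fA < 0.20, out = "A"),
    list(test = function(e) e$fA >= 0.20 && e$nB == 0, out = "A"))
  for (r in rules) if (r$test(env)) return(r$out)
  "U"
}

# Exhaustive per-threshold PR enumeration: for every distinct score taken as
# a cutoff, classify scores >= cutoff as positive and measure precision and
# recall directly.
oracle_aupr <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  prec <- rec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    called <- scores >= thr[i]
    tp <- sum(labels == 1 & called)
    prec[i] <- tp / sum(called)
    rec[i] <- tp / npos
  }
  sum(diff(c(0, rec)) * prec)
}

# Two-sided Fisher exact p by explicit hypergeometric enumeration: sum the
# probabilities of all tables with the observed margins that are no more
# likely than the observed table (probability method, with the classic
# relative tolerance).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n_ <- c + d       # row 2 total
  k <- a + c        # col 1 total
  if (m == 0 || n_ == 0 || k == 0 || (b + d) == 0) return(1)
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force PWM scan: explicit loops over offsets and positions, forward
# and reverse-complement strands.
oracle_site_scores <- function(seq, pwm, background = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  lo <- log(sweep(pwm$probs, 2, background / sum(background), "/"))
  one_strand <- function(s) {
    L <- nrow(lo); n <- nchar(s)
    if (n < L) return(numeric(0))
    out <- numeric(n - L + 1)
    for (off in seq_len(n - L + 1)) {
      sc <- 0
      for (j in seq_len(L)) {
        ch <- substr(s, off + j - 1, off + j - 1)
        if (ch != "N") sc <- sc + lo[j, match(ch, bases)]
      }
      out[off] <- sc
    }
    out
  }
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  c(one_strand(seq), one_strand(rc(seq)))
}

# Per-base track summarization: expand the track to a base-level vector.
oracle_summarize <- function(track, region) {
  vals <- rep(0, region$end - region$start)
  for (i in seq_len(nrow(track))) {
    if (track$chrom[i] != region$chrom) next
    from <- max(track$start[i], region$start)
    to <- min(track$end[i], region$end)
    if (from < to)
      vals[(from - region$start + 1):(to - region$start)] <- track$value[i]
  }
  c(min = min(vals), mean = mean(vals), max = max(vals))
}

# Random DNA string helper
random_dna <- function(len, with_n = FALSE) {
  alphabet <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_pwm <- function(tf = "TFX", L = 6) {
  m <- matrix(runif(L * 4), nrow = L)
  pwm_matrix(tf, m / rowSums(m))
}
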