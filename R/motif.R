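# PWM scanning (max log-odds site score, MOODS-style "score > 0" site
# threshold), Boltzmann total-affinity scoring, and the empirical-p-value
# -log(0.0001 + p) transform used as the final motif feature.

BASES <- c("A", "C", "G", "T")

#' Construct a position-probability matrix for one TF
#'
#' @param tf_name TF name the motif belongs to.
#' @param probs L x 4 matrix of base probabilities, columns in A, C, G, T
#'   order; rows are motif positions (L >= 4). Raw count matrices are
#'   accepted and normalized.
#' @param pseudocount small positive value added to every probability before
#'   renormalization (default 0.01), so log-odds stay finite.
#' @return an object of class \code{tfb_pwm}.
#' @examples
#' m <- matrix(0.25, nrow = 6, ncol = 4)
#' pwm_matrix("TF1", m)
#' @export
pwm_matrix <- function(tf_name, probs, pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("probs must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 4) stop("motif length must be >= 4")
  if (any(probs < 0) || any(!is.finite(probs))) stop("invalid probabilities")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  probs <- probs / rowSums(probs)          # accept counts
  probs <- probs + pseudocount
  probs <- probs / rowSums(probs)
  if (pseudocount == 0 && any(probs == 0))
    stop("zero probabilities require a positive pseudocount")
  colnames(probs) <- BASES
  structure(list(tf_name = tf_name, probs = probs, pseudocount = pseudocount),
            class = "tfb_pwm")
}

#' @export
print.tfb_pwm <- function(x, ...) {
  cat("PWM for", x$tf_name, "- length", nrow(x$probs), "bp\n")
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param pwm a \code{tfb_pwm}.
#' @export
pwm_consensus <- function(pwm) {
  paste0(BASES[apply(pwm$probs, 1, which.max)], collapse = "")
}

seq_to_codes <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c(BASES, "N"))
  if (any(bad))
    stop("invalid characters in sequence: ",
         paste(unique(chars[bad]), collapse = ", "))
  codes <- match(chars, BASES)  # N -> NA
  codes
}

revcomp_codes <- function(codes) {
  rev(ifelse(is.na(codes), NA, 5L - codes))
}

# log-odds scores of every placement of the PWM on one strand.
# N positions contribute 0 (background log-odds).
site_scores_one_strand <- function(codes, logodds) {
  L <- nrow(logodds)
  n <- length(codes)
  n_off <- n - L + 1L
  if (n_off < 1L) return(numeric(0))
  pos <- outer(seq_len(n_off) - 1L, seq_len(L), "+")      # n_off x L indices
  base <- matrix(codes[pos], nrow = n_off)
  contrib <- matrix(0, nrow = n_off, ncol = L)
  ok <- !is.na(base)
  contrib[ok] <- logodds[cbind(col(base)[ok], base[ok])]
  rowSums(contrib)
}

#' All site scores of a PWM along a sequence, both strands
#'
#' @param seq DNA string over \{A, C, G, T, N\}.
#' @param pwm a \code{tfb_pwm}.
#' @param background base frequencies in A, C, G, T order (default uniform).
#' @return numeric vector of log-odds scores at every offset on both strands
#'   (forward placements first); length 0 when the sequence is shorter than
#'   the motif.
#' @export
site_scores <- function(seq, pwm, background = rep(0.25, 4)) {
  stopifnot(length(background) == 4, all(background > 0))
  background <- background / sum(background)
  logodds <- log(sweep(pwm$probs, 2, background, "/"))
  codes <- seq_to_codes(seq)
  c(site_scores_one_strand(codes, logodds),
    site_scores_one_strand(revcomp_codes(codes), logodds))
}

#' Maximum PWM site score in a region
#'
#' Scans both strands at every offset and returns the log-odds score of the
#' strongest predicted binding site among sites scoring above zero (the
#' MOODS-style site threshold). Regions with no positive-scoring site, or
#' shorter than the motif, score exactly 0.
#'
#' @inheritParams site_scores
#' @return a nonnegative scalar score.
#' @examples
#' p <- pwm_matrix("TF1", diag(4)[c(1, 2, 3, 4, 1, 2), ])
#' scan_max_score(strrep("A", 3), p)  # shorter than motif -> 0
#' @export
scan_max_score <- function(seq, pwm, background = rep(0.25, 4)) {
  s <- site_scores(seq, pwm, background)
  s <- s[s > 0]
  if (length(s) == 0L) return(0)
  max(s)
}

#' Total binding affinity of a sequence to a TF
#'
#' Boltzmann-weight surrogate of TRAP's total affinity: the sum of
#' exponentiated log-odds scores over every placement on both strands, so
#' weak sites contribute cumulatively rather than being thresholded away.
#' Monotone nondecreasing when sequence is appended.
#'
#' @inheritParams site_scores
#' @return a nonnegative scalar; 0 for sequences shorter than the motif.
#' @export
total_affinity <- function(seq, pwm, background = rep(0.25, 4)) {
  s <- site_scores(seq, pwm, background)
  if (length(s) == 0L) return(0)
  sum(exp(s))
}

#' Empirical affinity p-score against control sequences
#'
#' Tests whether the total affinity of \code{seq} exceeds the affinities of a
#' control set, with add-one smoothing:
#' \deqn{p = (1 + \#\{controls \ge affinity(seq)\}) / (1 + \#controls)}
#' and returns the transformed score \eqn{-\log(0.0001 + p)} (natural log),
#' bounded in \eqn{(-\log 1.0001, -\log 0.0001]}.
#'
#' @param seq DNA string.
#' @param pwm a \code{tfb_pwm}.
#' @param controls character vector of control DNA sequences (>= 50
#'   recommended; must be non-empty). Precomputed control affinities may be
#'   passed via \code{control_affinities} to amortize scanning.
#' @param background base frequencies.
#' @param control_affinities optional numeric vector of precomputed control
#'   total affinities (overrides \code{controls}).
#' @return the \eqn{-\log(0.0001 + p)} score.
#' @export
affinity_pscore <- function(seq, pwm, controls = NULL,
                            background = rep(0.25, 4),
                            control_affinities = NULL) {
  if (is.null(control_affinities)) {
    if (is.null(controls) || length(controls) == 0L)
      stop("empty control set")
    control_affinities <- vapply(
      controls, total_affinity, numeric(1), pwm = pwm,
      background = background, USE.NAMES = FALSE)
  }
  if (length(control_affinities) == 0L) stop("empty control set")
  if (length(control_affinities) < 50L)
    warning("fewer than 50 control sequences; p-values will be coarse")
  a <- total_affinity(seq, pwm, background)
  p <- (1 + sum(control_affinities >= a)) / (1 + length(control_affinities))
  -log(1e-4 + p)
}

#' Scan a set of region sequences with a set of PWMs
#'
#' Convenience wrapper producing the per-(region, TF) motif feature table:
#' maximum site score, total affinity, number of positive-scoring sites, and
#' the control-based affinity p-score.
#'
#' @param seqs named character vector (or \code{Biostrings::DNAStringSet})
#'   of region sequences; names are region ids.
#' @param pwms named list of \code{tfb_pwm} objects.
#' @param controls character vector of control sequences (optional; when
#'   absent the \code{affinity_pscore} column is omitted).
#' @param background base frequencies.
#' @return data.frame with columns region_id, tf, max_score, total_affinity,
#'   n_sites and (optionally) affinity_pscore.
#' @export
scan_region_motifs <- function(seqs, pwms, controls = NULL,
                               background = rep(0.25, 4)) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  stopifnot(!is.null(names(seqs)), !is.null(names(pwms)))
  out <- vector("list", length(pwms))
  for (k in seq_along(pwms)) {
    pwm <- pwms[[k]]
    ctl_aff <- if (!is.null(controls))
      vapply(controls, total_affinity, numeric(1), pwm = pwm,
             background = background, USE.NAMES = FALSE)
    rows <- lapply(seq_along(seqs), function(i) {
      s <- site_scores(seqs[[i]], pwm, background)
      pos <- s[s > 0]
      aff <- if (length(s)) sum(exp(s)) else 0
      r <- data.frame(region_id = names(seqs)[i], tf = names(pwms)[k],
                      max_score = if (length(pos)) max(pos) else 0,
                      total_affinity = aff, n_sites = length(pos),
                      stringsAsFactors = FALSE)
      if (!is.null(controls)) {
        p <- (1 + sum(ctl_aff >= aff)) / (1 + length(ctl_aff))
        r$affinity_pscore <- -log(1e-4 + p)
      }
      r
    })
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read PWMs from a TRANSFAC-format file
#'
#' Parses minimal TRANSFAC records: \code{ID}/\code{NA} name lines, numbered
#' count rows (position, A, C, G, T counts), \code{//} record separators.
#'
#' @param path file path.
#' @param pseudocount passed to \code{\link{pwm_matrix}}.
#' @return named list of \code{tfb_pwm}.
#' @export
read_transfac <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  pwms <- list()
  name <- NULL
  rows <- list()
  flush <- function() {
    if (!is.null(name) && length(rows) > 0) {
      m <- do.call(rbind, rows)
      pwms[[name]] <<- pwm_matrix(name, m, pseudocount = pseudocount)
    }
    name <<- NULL; rows <<- list()
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" ) next
    if (startsWith(ln, "//")) { flush(); next }
    if (grepl("^(ID|NA)\\s+", ln)) {
      nm <- sub("^(ID|NA)\\s+", "", ln)
      if (is.null(name)) name <- nm
      next
    }
    if (grepl("^[0-9]+\\s", ln)) {
      parts <- strsplit(ln, "\\s+")[[1]]
      rows[[length(rows) + 1L]] <- as.numeric(parts[2:5])
    }
  }
  flush()
  pwms
}

#' Write PWMs in TRANSFAC format
#'
#' @param pwms named list of \code{tfb_pwm}.
#' @param path output file.
#' @export
write_transfac <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pwm in pwms) {
    writeLines(c(paste("ID", pwm$tf_name),
                 paste("NA", pwm$tf_name),
                 "P0\tA\tC\tG\tT"), con)
    for (i in seq_len(nrow(pwm$probs))) {
      writeLines(paste(c(sprintf("%02d", i),
                         formatC(pwm$probs[i, ], format = "f", digits = 6)),
                       collapse = "\t"), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
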