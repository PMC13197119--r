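# AUPR-centric evaluation for heavily imbalanced binding labels, the ATAC
# and motif baselines, and QC analyses (FRiP discard rule, expression
# entropy, ChIP-signal relative performance).

#' Precision-recall curve and AUPR
#'
#' Computes the precision-recall curve over all score thresholds, grouping
#' tied scores, and the area under it by step-wise (average-precision)
#' integration: \eqn{AP = \sum_k (R_k - R_{k-1}) P_k} over distinct
#' thresholds. Step integration is used instead of trapezoids, which
#' overestimate under class imbalance.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical); both classes required.
#' @return object of class \code{tfb_pr}: list with \code{points}
#'   (threshold, recall, precision), \code{aupr}, \code{n_pos}, \code{n_neg}.
#' @examples
#' pr <- pr_curve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' pr$aupr  # 1: perfect separation
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute a PR curve")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  thr <- s[!duplicated(s)]
  tp <- cumsum(tp_g)
  pred_pos <- cumsum(n_g)
  precision <- tp / pred_pos
  recall <- tp / n_pos
  ap <- sum(diff(c(0, recall)) * precision)
  structure(list(points = data.frame(threshold = thr,
                                     recall = unname(recall),
                                     precision = unname(precision)),
                 aupr = unname(ap), n_pos = n_pos, n_neg = n_neg),
            class = "tfb_pr")
}

#' @export
print.tfb_pr <- function(x, ...) {
  cat(sprintf("PR curve: AUPR = %.4f (%d positives / %d negatives)\n",
              x$aupr, x$n_pos, x$n_neg))
  invisible(x)
}

#' Area under the precision-recall curve
#' @inheritParams pr_curve
#' @return scalar AUPR in [0, 1].
#' @export
aupr <- function(scores, labels) pr_curve(scores, labels)$aupr

#' ATAC and motif-scan baseline AUPRs
#'
#' Ranks regions by mean ATAC signal alone and by the motif affinity
#' p-score alone; under ~2% prevalence the reference values at full scale
#' are ~0.2 (ATAC) and ~0.11 (motif), both well above the prevalence
#' baseline but far below a trained model.
#'
#' @param features data.frame with columns \code{atac_mean} and
#'   \code{affinity_pscore} (names configurable).
#' @param labels binary labels aligned with rows of \code{features}.
#' @param atac_col,motif_col column names for the two baselines.
#' @return list with \code{atac_aupr} and \code{motif_aupr}.
#' @export
baselines <- function(features, labels, atac_col = "atac_mean",
                      motif_col = "affinity_pscore") {
  for (col in c(atac_col, motif_col))
    if (!col %in% names(features))
      stop("missing baseline feature column: ", col)
  list(atac_aupr = aupr(features[[atac_col]], labels),
       motif_aupr = aupr(features[[motif_col]], labels))
}

#' Smallest score threshold reaching a target precision
#'
#' @param curve a \code{tfb_pr} object.
#' @param target_precision target in (0, 1).
#' @return list with \code{threshold} (NA when unreachable), the realized
#'   \code{precision}, and \code{reachable}.
#' @export
precision_threshold <- function(curve, target_precision) {
  stopifnot(inherits(curve, "tfb_pr"),
            target_precision > 0, target_precision < 1)
  pts <- curve$points
  ok <- pts$precision >= target_precision
  if (!any(ok))
    return(list(threshold = NA_real_, precision = NA_real_,
                reachable = FALSE))
  i <- max(which(ok))  # thresholds are in decreasing order
  list(threshold = pts$threshold[i], precision = pts$precision[i],
       reachable = TRUE)
}

#' Fraction of reads in peaks (FRiP)
#'
#' The fraction of reads whose midpoint falls inside any peak — the
#' signal-to-noise QC statistic for ChIP-seq; datasets below 0.02 FRiP
#' should be discarded (neither their ground-truth labels nor models
#' trained on them are reliable).
#'
#' @param reads data.frame with chrom, start, end (0-based half-open).
#' @param peaks data.frame with chrom, start, end; empty -> FRiP 0.
#' @return fraction in [0, 1].
#' @export
frip <- function(reads, peaks) {
  if (nrow(reads) == 0L) stop("empty read set")
  if (nrow(peaks) == 0L) return(0)
  mid <- floor((reads$start + reads$end) / 2)
  inside <- logical(nrow(reads))
  for (ch in unique(reads$chrom)) {
    ri <- which(reads$chrom == ch)
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (nrow(pk) == 0L) next
    gr_m <- IRanges::IRanges(start = mid[ri] + 1L, width = 1L)
    gr_p <- IRanges::IRanges(start = pk$start + 1L, end = pk$end)
    inside[ri] <- IRanges::overlapsAny(gr_m, gr_p)
  }
  mean(inside)
}

#' ChIP-seq dataset QC record
#'
#' @param dataset_id dataset identifier.
#' @param frip FRiP fraction.
#' @param pbc1,pbc2 optional PCR bottlenecking coefficients (metadata only).
#' @param frip_cutoff discard threshold (default 0.02).
#' @return one-row data.frame with a \code{pass} flag
#'   (\code{frip >= frip_cutoff}).
#' @export
qc_record <- function(dataset_id, frip, pbc1 = NA_real_, pbc2 = NA_real_,
                      frip_cutoff = 0.02) {
  stopifnot(frip >= 0, frip <= 1)
  data.frame(dataset_id = dataset_id, frip = frip, pbc1 = pbc1, pbc2 = pbc2,
             pass = frip >= frip_cutoff, stringsAsFactors = FALSE)
}

#' Expression entropy of a TPM profile
#'
#' Shannon entropy (bits) of the TPM profile normalized to probabilities,
#' with 0 log 0 = 0. Low entropy marks tissue-specific expression; the
#' maximum, log2(n_conditions), marks uniform ubiquitous expression.
#'
#' @param tpm_profile nonnegative vector over >= 2 conditions, sum > 0.
#' @return entropy in bits.
#' @examples
#' expression_entropy(rep(1, 80))  # log2(80) = 6.32 bits
#' @export
expression_entropy <- function(tpm_profile) {
  if (length(tpm_profile) < 2) stop("need >= 2 conditions")
  if (any(tpm_profile < 0)) stop("negative TPM")
  total <- sum(tpm_profile)
  if (total <= 0) stop("all-zero expression profile")
  p <- tpm_profile / total
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Performance relative to the ChIP-signal upper bound
#'
#' Ratio of a model's AUPR to the AUPR obtained by ranking regions by the
#' quantitative ChIP-seq signal itself — an effective upper bound set by
#' assay noise. Values near 1 mean the model has little headroom left.
#'
#' @param model_aupr model AUPR.
#' @param chip_signal_aupr AUPR of the mean ChIP-signal ranking (> 0).
#' @return the fraction \code{model_aupr / chip_signal_aupr}.
#' @export
relative_performance <- function(model_aupr, chip_signal_aupr) {
  if (chip_signal_aupr <= 0) stop("chip_signal_aupr must be > 0")
  model_aupr / chip_signal_aupr
}

#' Pooled PR curve across TF-cell pairs
#'
#' Concatenates (score, label) pairs across prediction sets before
#' thresholding, yielding one overall curve.
#'
#' @param score_sets list of numeric score vectors.
#' @param label_sets list of matching binary label vectors.
#' @return a \code{tfb_pr} object.
#' @export
pooled_pr_curve <- function(score_sets, label_sets) {
  stopifnot(length(score_sets) == length(label_sets))
  pr_curve(unlist(score_sets, use.names = FALSE),
           unlist(label_sets, use.names = FALSE))
}
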