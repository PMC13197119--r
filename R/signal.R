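# Per-region summarization of numeric signal tracks (ATAC, footprint, ReMap,
# conservation), quantile normalization, differential accessibility, and
# expression normalization.

#' Construct a signal track from interval data
#'
#' A track is a set of non-overlapping 0-based half-open intervals with a
#' numeric value each (bedGraph semantics); bases not covered by any interval
#' are treated as 0 signal by default.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param value numeric signal values (finite).
#' @param name feature label for the track.
#' @param cell optional cell-type tag (NA for cell-type-agnostic genomic
#'   tracks such as ReMap or conservation).
#' @return a \code{tfb_track} data.frame.
#' @export
signal_track <- function(chrom, start, end, value, name = "signal",
                         cell = NA_character_) {
  if (any(!is.finite(value))) stop("track values must be finite")
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("malformed interval in track")
  tr <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   value = as.numeric(value), stringsAsFactors = FALSE)
  attr(tr, "name") <- name
  attr(tr, "cell") <- cell
  class(tr) <- c("tfb_track", "data.frame")
  tr
}

#' Read a bedGraph file as a signal track
#'
#' @param path bedGraph file (chrom, start, end, value; no header).
#' @inheritParams signal_track
#' @export
read_bedgraph <- function(path, name = "signal", cell = NA_character_) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  signal_track(tab[[1]], tab[[2]], tab[[3]], tab[[4]], name = name, cell = cell)
}

#' Write a signal track as bedGraph
#' @param track a \code{tfb_track}.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  write.table(track[, c("chrom", "start", "end", "value")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summarize a signal track over regions (min, mean, max)
#'
#' Computes the minimum, coverage-weighted mean, and maximum signal over the
#' bases of each region. Bases without track coverage count as 0 signal
#' (bedGraph gap convention) unless \code{uncovered = "skip"}, in which case
#' they are excluded from the statistics (regions with no coverage at all
#' then return NA).
#'
#' @param track a \code{tfb_track}.
#' @param regions region data.frame.
#' @param uncovered \code{"zero"} (default) or \code{"skip"}.
#' @return data.frame with region_id, min, mean, max.
#' @export
summarize_track <- function(track, regions, uncovered = c("zero", "skip")) {
  uncovered <- match.arg(uncovered)
  if (any(regions$end - regions$start <= 0)) stop("zero-length region")
  gr_r <- regions_to_granges(regions)
  gr_t <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_t)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_r)[qh], IRanges::ranges(gr_t)[sh]))
  v <- track$value[sh]

  n <- nrow(regions)
  width_r <- regions$end - regions$start
  sum_v <- rep(0, n); cov_w <- rep(0, n)
  min_v <- rep(Inf, n); max_v <- rep(-Inf, n)
  for (k in seq_along(qh)) {
    i <- qh[k]
    sum_v[i] <- sum_v[i] + v[k] * w[k]
    cov_w[i] <- cov_w[i] + w[k]
    if (v[k] < min_v[i]) min_v[i] <- v[k]
    if (v[k] > max_v[i]) max_v[i] <- v[k]
  }
  if (uncovered == "zero") {
    gap <- width_r - cov_w
    mean_v <- sum_v / width_r
    min_v <- ifelse(gap > 0, pmin(min_v, 0), min_v)
    max_v <- ifelse(gap > 0, pmax(max_v, 0), max_v)
    min_v[cov_w == 0] <- 0; max_v[cov_w == 0] <- 0
  } else {
    mean_v <- ifelse(cov_w > 0, sum_v / cov_w, NA_real_)
    min_v[cov_w == 0] <- NA_real_; max_v[cov_w == 0] <- NA_real_
  }
  data.frame(region_id = regions$region_id, min = min_v, mean = mean_v,
             max = max_v, stringsAsFactors = FALSE)
}

#' Quantile normalization across columns
#'
#' Forces every column of a regions x cells matrix onto a common reference
#' distribution (the mean of the sorted columns), so accessibility is
#' comparable across cell types. Ties are averaged. Delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' @param mat numeric matrix with >= 2 columns, no NAs.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("quantile normalization needs >= 2 columns")
  if (any(is.na(mat))) stop("NAs not allowed in quantile normalization")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Differential accessibility of a region in a target cell type
#'
#' The mean ATAC signal in the target cell minus the mean of the means
#' across all other cell types; positive values flag cell-type-specific
#' accessibility.
#'
#' @param mean_atac named numeric vector of per-cell mean ATAC values for
#'   one region (>= 2 cells).
#' @param target_cell name of the target cell.
#' @return a scalar delta.
#' @examples
#' delta_atac(c(liver = 5, lung = 1, heart = 1, kidney = 1), "liver")
#' @export
delta_atac <- function(mean_atac, target_cell) {
  if (length(mean_atac) < 2) stop("delta_atac needs >= 2 cells")
  if (!target_cell %in% names(mean_atac)) stop("unknown target cell")
  others <- mean_atac[setdiff(names(mean_atac), target_cell)]
  unname(mean_atac[[target_cell]] - mean(others))
}

#' Normalize a TPM expression table
#'
#' Applies log(1 + TPM) and then z-scores over the full set of entries
#' (not per gene). The transform statistics (mu, sigma) are attached as
#' attributes and can be frozen from a training partition and re-applied to
#' held-out data via \code{stats}, avoiding test-time leakage. A sigma floor
#' of 1e-8 guards constant tables.
#'
#' @param tbl numeric matrix / data.frame, genes x conditions, TPM >= 0.
#' @param stats optional list(mu, sigma) frozen from a training partition.
#' @return matrix of z-scored log(1+TPM) with attributes \code{mu},
#'   \code{sigma}.
#' @export
normalize_expression <- function(tbl, stats = NULL) {
  m <- as.matrix(tbl)
  if (any(m < 0, na.rm = TRUE)) stop("negative TPM values")
  lg <- log1p(m)
  if (is.null(stats)) {
    mu <- mean(lg)
    sigma <- max(sd(as.vector(lg)), 1e-8)
  } else {
    mu <- stats$mu; sigma <- max(stats$sigma, 1e-8)
  }
  out <- (lg - mu) / sigma
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

#' Read a long-format TPM table (gene, condition, TPM) into a matrix
#' @param path TSV with header columns gene, condition, tpm.
#' @return genes x conditions numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  genes <- sort(unique(tab$gene)); conds <- sort(unique(tab$condition))
  m <- matrix(0, nrow = length(genes), ncol = length(conds),
              dimnames = list(genes, conds))
  m[cbind(match(tab$gene, genes), match(tab$condition, conds))] <- tab$tpm
  m
}
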