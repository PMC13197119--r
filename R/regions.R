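# Region representation and harmonization of overlapping ground-truth bins
# into one ternary {B, A, U} label per region. Coordinates are 0-based
# half-open (BED convention) throughout.

#' Construct and validate a set of genomic regions
#'
#' Regions are the atomic prediction unit: short (by default at most 350 bp)
#' candidate regulatory elements with a stable \code{region_id}.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param region_id stable unique string keys; autogenerated
#'   (\code{chrom:start-end}) when \code{NULL}.
#' @param max_length maximum allowed region length in bp (default 350).
#' @return a \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{region_id}.
#' @examples
#' region_set("chr1", 100, 450)
#' @export
region_set <- function(chrom, start, end, region_id = NULL, max_length = 350L) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("malformed interval: NA coordinates")
  if (any(start >= end))
    stop("malformed interval: start must be < end (0-based half-open)")
  if (any(end - start > max_length))
    stop("region longer than max_length (", max_length, " bp)")
  if (is.null(region_id))
    region_id <- paste0(chrom, ":", start, "-", end)
  if (anyDuplicated(region_id))
    stop("region_id values must be unique")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             region_id = as.character(region_id), stringsAsFactors = FALSE)
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    region_id = if ("region_id" %in% names(regions)) regions$region_id else NULL)
}

#' Bins overlapping a region by at least a fraction of the bin
#'
#' Selects every ground-truth bin whose overlap with \code{region} covers at
#' least \code{min_frac} of the bin's own length (the DREAM-style ">= 50% of
#' the bin intersecting the region" rule). Overlaps are computed on 0-based
#' half-open coordinates; bins on chromosomes absent from the region are
#' simply not returned.
#'
#' @param region a single-row region data.frame (or list with \code{chrom},
#'   \code{start}, \code{end}).
#' @param bins data.frame of bins with \code{chrom}, \code{start}, \code{end}
#'   (extra columns are carried through).
#' @param min_frac minimum overlap as a fraction of bin length, in (0, 1].
#' @return the subset of \code{bins} passing the rule, sorted by
#'   (chrom, start, end) so the result is invariant to input order.
#' @examples
#' bins <- data.frame(chrom = "chr1", start = c(90, 80), end = c(140, 120))
#' overlap_bins(list(chrom = "chr1", start = 100, end = 300), bins)
#' @export
overlap_bins <- function(region, bins, min_frac = 0.5) {
  stopifnot(min_frac > 0, min_frac <= 1)
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L)
    region <- as.list(region)
  }
  if (region$start >= region$end) stop("malformed interval: region start >= end")
  if (nrow(bins) == 0L) return(bins)
  if (any(bins$start >= bins$end)) stop("malformed interval in bins")
  ov <- pmin(region$end, bins$end) - pmax(region$start, bins$start)
  keep <- bins$chrom == region$chrom & ov >= min_frac * (bins$end - bins$start)
  out <- bins[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate overlapping bin labels into one ternary region label
#'
#' Applies the label-harmonization rules in fixed priority order (first match
#' wins), with fractions taken over the overlapping bins of the region:
#' \enumerate{
#'   \item frac(B) >= 0.40 -> B
#'   \item frac(B) >= 0.20 and frac(A) >= 0.30 -> B
#'   \item count(B) >= 1 and frac(A) < 0.20 -> A
#'   \item frac(A) >= 0.20 and count(B) = 0 -> A
#'   \item otherwise -> U
#' }
#' B marks confidently bound, A ambiguous (excluded from training and
#' evaluation downstream), U unbound.
#'
#' @param bin_labels character vector over \{"B", "A", "U"\}; non-empty.
#' @return a single label, one of \code{"B"}, \code{"A"}, \code{"U"}.
#' @examples
#' aggregate_labels(c("B", "B", "U", "U", "U")) # 40% B -> "B"
#' @export
aggregate_labels <- function(bin_labels) {
  if (length(bin_labels) == 0L)
    stop("region has no overlapping bins; caller decides drop-or-U policy")
  if (!all(bin_labels %in% c("B", "A", "U")))
    stop("labels must be in {B, A, U}")
  n <- length(bin_labels)
  nb <- sum(bin_labels == "B")
  na_ <- sum(bin_labels == "A")
  fb <- nb / n
  fa <- na_ / n
  if (fb >= 0.40) return("B")
  if (fb >= 0.20 && fa >= 0.30) return("B")
  if (nb >= 1L && fa < 0.20) return("A")
  if (fa >= 0.20 && nb == 0L) return("A")
  "U"
}

#' Build a ternary label set over (region, TF, cell) triples
#'
#' For each (TF, cell) pair, intersects the regions with that pair's labeled
#' bins (\code{\link{overlap_bins}} rule) and aggregates the overlapping bin
#' labels (\code{\link{aggregate_labels}}) into one label per region.
#'
#' @param regions region data.frame (see \code{\link{region_set}}).
#' @param bin_labels data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{tf}, \code{cell}, \code{label} columns; one row per labeled bin.
#' @param min_frac minimum bin-overlap fraction (default 0.5).
#' @param empty_policy what to do with regions that overlap no bins of a
#'   pair: \code{"drop"} (default) omits them, \code{"U"} labels them unbound.
#' @return data.frame with columns \code{region_id}, \code{tf}, \code{cell},
#'   \code{label}.
#' @export
build_labelset <- function(regions, bin_labels, min_frac = 0.5,
                           empty_policy = c("drop", "U")) {
  empty_policy <- match.arg(empty_policy)
  req <- c("chrom", "start", "end", "tf", "cell", "label")
  if (!all(req %in% names(bin_labels)))
    stop("bin_labels must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(bin_labels[, req]))
    stop("duplicate (bin, tf, cell) entries in bin_labels")
  if (!all(bin_labels$label %in% c("B", "A", "U")))
    stop("labels must be in {B, A, U}")

  gr_regions <- regions_to_granges(regions)
  pairs <- unique(bin_labels[, c("tf", "cell")])
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    sub <- bin_labels[bin_labels$tf == pairs$tf[k] &
                      bin_labels$cell == pairs$cell[k], , drop = FALSE]
    gr_bins <- GenomicRanges::GRanges(
      seqnames = sub$chrom,
      ranges = IRanges::IRanges(start = sub$start + 1L, end = sub$end))
    hits <- GenomicRanges::findOverlaps(gr_regions, gr_bins)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr_regions)[qh], IRanges::ranges(gr_bins)[sh]))
    keep <- ov >= min_frac * (sub$end[sh] - sub$start[sh])
    qh <- qh[keep]; sh <- sh[keep]
    lab_by_region <- split(sub$label[sh], regions$region_id[qh])
    agg <- vapply(lab_by_region, aggregate_labels, character(1))
    ids <- names(agg)
    if (empty_policy == "U") {
      missing_ids <- setdiff(regions$region_id, ids)
      ids <- c(ids, missing_ids)
      agg <- c(agg, setNames(rep("U", length(missing_ids)), missing_ids))
    }
    ord <- match(intersect(regions$region_id, ids), ids)
    out[[k]] <- data.frame(region_id = ids[ord], tf = pairs$tf[k],
                           cell = pairs$cell[k], label = unname(agg[ord]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a BED3+ region file
#'
#' @param path BED file; columns chrom, start, end and optionally a 4th
#'   column used as \code{region_id}.
#' @param max_length maximum region length (default 350 bp).
#' @return region data.frame.
#' @export
read_regions_bed <- function(path, max_length = 350L) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  id <- if (ncol(tab) >= 4) as.character(tab[[4]]) else NULL
  region_set(tab[[1]], tab[[2]], tab[[3]], region_id = id,
             max_length = max_length)
}

#' Read labeled ground-truth bins
#'
#' Expects BED-like TSV with columns chrom, start, end, tf, cell, label.
#'
#' @param path file path.
#' @return data.frame of bins.
#' @export
read_bin_labels <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stop("expected 6 columns: chrom start end tf cell label")
  names(tab)[1:6] <- c("chrom", "start", "end", "tf", "cell", "label")
  tab
}

#' Write / read a label set as TSV
#'
#' @param labelset data.frame (region_id, tf, cell, label).
#' @param path output file.
#' @export
write_labelset <- function(labelset, path) {
  write.table(labelset, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labelset
#' @export
read_labelset <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
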