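# Cell-type-specific cooperating TF pairs: contingency tables over
# ubiquitous vs cell-specific enhancers, Fisher exact tests, and the
# L = log(p_cell / p_ubiq) cooperation score with its a_c >= 10 support rule.

#' Partition enhancers into ubiquitous and cell-specific sets
#'
#' The ubiquitous set U holds the n enhancers accessible in every cell type:
#' the accessibility threshold s is set so that exactly n enhancers have
#' min-across-cells mean signal >= s (ties broken by region id). The
#' cell-specific set S_c per cell is built by filtering out enhancers with
#' low global mean accessibility (below the \code{low_frac} quantile) and
#' ranking the rest by the relative deviation of the cell's mean from the
#' enhancer's global mean, keeping the top n.
#'
#' @param mean_atac regions x cells matrix of mean accessibility, with row
#'   names as region ids.
#' @param n number of enhancers per set; must satisfy
#'   \code{n <= nrow(mean_atac) / (1 + ncol(mean_atac))}.
#' @param low_frac quantile of global means below which enhancers are
#'   excluded from cell-specific ranking (default 0.25).
#' @return list with \code{U} (ids), \code{S} (named list of id vectors per
#'   cell), \code{s} (realized threshold) and \code{n}.
#' @export
partition_enhancers <- function(mean_atac, n, low_frac = 0.25) {
  mean_atac <- as.matrix(mean_atac)
  if (is.null(rownames(mean_atac))) stop("mean_atac needs region-id row names")
  n_reg <- nrow(mean_atac); n_cell <- ncol(mean_atac)
  if (n > n_reg / (1 + n_cell))
    stop("n infeasible: need n <= n_regions / (1 + n_cells)")

  ids <- rownames(mean_atac)
  min_across <- apply(mean_atac, 1, min)
  ord_u <- order(-min_across, ids)
  U <- ids[ord_u[seq_len(n)]]
  s <- min_across[ord_u[n]]

  global_mean <- rowMeans(mean_atac)
  keep <- global_mean >= quantile(global_mean, low_frac)
  S <- lapply(colnames(mean_atac), function(cell) {
    dev <- (mean_atac[keep, cell] - global_mean[keep]) / global_mean[keep]
    sub_ids <- ids[keep]
    sub_ids[order(-dev, sub_ids)][seq_len(n)]
  })
  names(S) <- colnames(mean_atac)
  list(U = U, S = S, s = unname(s), n = n)
}

#' Top-k bound enhancers per TF by total affinity
#'
#' Labels the k enhancers with the highest total binding affinity as bound
#' by each TF. Selection is deterministic and permutation-invariant: ties at
#' the k-boundary are broken by enhancer id.
#'
#' @param enhancer_ids character vector of enhancer ids.
#' @param tf_affinities matrix (enhancers x TFs) of total affinities, rows
#'   aligned with \code{enhancer_ids} (or carrying matching row names).
#' @param k number of bound enhancers per TF (k <= number of enhancers).
#' @return named list of id vectors, one per TF.
#' @export
bound_sets <- function(enhancer_ids, tf_affinities, k) {
  tf_affinities <- as.matrix(tf_affinities)
  if (!is.null(rownames(tf_affinities)))
    tf_affinities <- tf_affinities[enhancer_ids, , drop = FALSE]
  if (nrow(tf_affinities) != length(enhancer_ids))
    stop("affinity rows must align with enhancer_ids")
  if (k > length(enhancer_ids)) stop("k exceeds number of enhancers")
  out <- lapply(seq_len(ncol(tf_affinities)), function(j) {
    ord <- order(-tf_affinities[, j], enhancer_ids)
    sort(enhancer_ids[ord[seq_len(k)]])
  })
  names(out) <- colnames(tf_affinities)
  out
}

fisher_p <- function(a, b, c, d) {
  # degenerate margins give p = 1 by convention
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) return(1)
  fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
}

#' Cooperation score for a TF pair in one cell type
#'
#' Builds the 2x2 co-binding contingency table of two TFs over the
#' cell-specific enhancers S_c (counts a_c = co-bound, b_c / c_c = bound by
#' one only, d_c = bound by neither) and the analogous table over the
#' ubiquitous enhancers U, applies two-sided Fisher exact tests to each, and
#' scores cooperation as the log p-value ratio \eqn{L = \log(p_{ubiq} /
#' p_{cell})} (natural log): L is large when co-binding is significant among
#' the cell-specific enhancers but not among the ubiquitous ones. The pair
#' is flagged cooperating when L > 2 with adequate support (a_c >= 10
#' co-bound cell-specific enhancers).
#'
#' @param B1,B2 character vectors: enhancers bound by TF 1 / TF 2.
#' @param S_c character vector: cell-specific enhancer ids.
#' @param U character vector: ubiquitous enhancer ids.
#' @param tf1,tf2,cell optional names recorded in the output.
#' @return a one-row data.frame with counts, both p-values, L and the
#'   cooperating flag.
#' @export
cooperation_score <- function(B1, B2, S_c, U,
                              tf1 = "tf1", tf2 = "tf2", cell = "cell") {
  count_table <- function(set) {
    a <- length(intersect(intersect(B1, B2), set))
    b <- length(intersect(B1, set)) - a
    c_ <- length(intersect(B2, set)) - a
    d <- length(set) - (a + b + c_)
    c(a = a, b = b, c = c_, d = d)
  }
  tc <- count_table(S_c)
  tu <- count_table(U)
  p_cell <- fisher_p(tc["a"], tc["b"], tc["c"], tc["d"])
  p_ubiq <- fisher_p(tu["a"], tu["b"], tu["c"], tu["d"])
  L <- log(p_ubiq / p_cell)
  data.frame(tf1 = tf1, tf2 = tf2, cell = cell,
             a_c = unname(tc["a"]), b_c = unname(tc["b"]),
             c_c = unname(tc["c"]), d_c = unname(tc["d"]),
             p_cell = p_cell, p_ubiq = p_ubiq, L = L,
             cooperating = (L > 2) && (tc["a"] >= 10),
             stringsAsFactors = FALSE)
}

#' Cooperation table over all TF pairs and cell types
#'
#' @param partition output of \code{\link{partition_enhancers}}.
#' @param bsets output of \code{\link{bound_sets}} computed over the joint
#'   universe U plus all S_c.
#' @return data.frame with one row per (tf1, tf2, cell).
#' @export
cooperation_table <- function(partition, bsets) {
  tfs <- names(bsets)
  if (length(tfs) < 2) stop("need >= 2 TFs")
  pairs <- combn(tfs, 2)
  rows <- list()
  for (cell in names(partition$S)) {
    for (j in seq_len(ncol(pairs))) {
      rows[[length(rows) + 1L]] <- cooperation_score(
        bsets[[pairs[1, j]]], bsets[[pairs[2, j]]],
        partition$S[[cell]], partition$U,
        tf1 = pairs[1, j], tf2 = pairs[2, j], cell = cell)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Eight partner-derived features for one TF
#'
#' Selects the TF's four strongest cooperating partners (highest L among
#' records flagged cooperating, deduplicated across cells by their best L)
#' and emits, per enhancer, the partner's number of binding sites and its
#' maximum site score — two columns per partner, ordered by descending L and
#' zero-padded when fewer than four partners exist.
#'
#' @param tf TF name.
#' @param records cooperation table (see \code{\link{cooperation_table}}).
#' @param site_counts enhancers x TFs matrix of binding-site counts.
#' @param max_scores enhancers x TFs matrix of maximum site scores.
#' @return numeric matrix (enhancers x 8) with columns
#'   \code{partner<i>_nsites}, \code{partner<i>_maxscore}; the partner names
#'   are attached as attribute \code{partners}.
#' @export
partner_features <- function(tf, records, site_counts, max_scores) {
  site_counts <- as.matrix(site_counts)
  max_scores <- as.matrix(max_scores)
  stopifnot(identical(dim(site_counts), dim(max_scores)))
  rec <- records[records$cooperating &
                 (records$tf1 == tf | records$tf2 == tf), , drop = FALSE]
  partners <- character(0)
  if (nrow(rec) > 0) {
    rec$partner <- ifelse(rec$tf1 == tf, rec$tf2, rec$tf1)
    best <- vapply(split(rec$L, rec$partner), max, numeric(1))
    partners <- names(best)[order(-best, names(best))]
    partners <- head(partners, 4L)
  }
  n_enh <- nrow(site_counts)
  out <- matrix(0, nrow = n_enh, ncol = 8,
                dimnames = list(rownames(site_counts),
                                paste0("partner", rep(1:4, each = 2), "_",
                                       c("nsites", "maxscore"))))
  for (i in seq_along(partners)) {
    out[, 2 * i - 1] <- site_counts[, partners[i]]
    out[, 2 * i] <- max_scores[, partners[i]]
  }
  attr(out, "partners") <- partners
  out
}

#' Write a cooperation table as TSV
#' @param records cooperation table.
#' @param path output file.
#' @export
write_cooperation_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
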