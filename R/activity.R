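# TF activity: the contribution of motif affinity to enhancer activity,
# obtained by solving A x W = C for W, where A holds best-site motif scores
# per (enhancer, TF) and C holds enhancer-probability profiles per tissue.

#' Infer TF activities by (ridge-regularizable) least squares
#'
#' Solves \eqn{A W = C} in the least-squares sense column by column, where
#' \code{A} is the N_enh x N_TF affinity matrix (best binding-site score per
#' enhancer and TF, 0 when no site) and \code{C} the N_enh x N_tissue
#' enhancer-probability matrix. The solution is scaled by 10000 for
#' readability and z-normalized across all entries; the unnormalized
#' solution is kept in the \code{"raw"} attribute.
#'
#' @param A affinity matrix (rows: enhancers, cols: TFs), entries >= 0.
#' @param C enhancer-probability matrix (rows: enhancers, cols: tissues);
#'   row universe must match \code{A}.
#' @param lambda ridge penalty (default 0 = plain linear regression; the
#'   regularized reading is available through a positive value).
#' @return N_TF x N_tissue activity matrix (z-normalized), with attributes
#'   \code{raw} (pre-scaling least-squares solution) and \code{lambda}.
#' @examples
#' A <- matrix(runif(200), 50, 4)
#' W <- matrix(rnorm(8), 4, 2)
#' act <- fit_activity(A, A %*% W)
#' @export
fit_activity <- function(A, C, lambda = 0) {
  A <- as.matrix(A); C <- as.matrix(C)
  if (nrow(A) != nrow(C)) stop("row universes of A and C must match")
  if (!is.null(rownames(A)) && !is.null(rownames(C)) &&
      !identical(rownames(A), rownames(C)))
    stop("row universes of A and C must match (row names differ)")
  if (nrow(A) <= ncol(A)) stop("need more enhancers than TFs (N_enh > N_TF)")
  if (any(A < 0)) stop("affinity entries must be >= 0")

  AtA <- crossprod(A)
  r <- qr(AtA)$rank
  if (lambda > 0) {
    W <- solve(AtA + diag(lambda, ncol(A)), crossprod(A, C))
  } else if (r < ncol(A)) {
    warning("rank-deficient affinity matrix with lambda = 0; ",
            "returning minimum-norm solution")
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-10
    W <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) %*% C / sv$d[pos])
  } else {
    W <- solve(AtA, crossprod(A, C))
  }
  dimnames(W) <- list(colnames(A), colnames(C))

  scaled <- W * 10000
  mu <- mean(scaled)
  sigma <- max(sd(as.vector(scaled)), 1e-8)
  out <- (scaled - mu) / sigma
  attr(out, "raw") <- W
  attr(out, "lambda") <- lambda
  out
}

#' Correlation between a TF's activity profile and an enhancer's score profile
#'
#' Pearson correlation across tissues between the per-tissue activity of a TF
#' and the per-tissue enhancer-probability scores of a region; a feature that
#' links condition-specific TF activity to condition-specific enhancer usage.
#' Constant vectors are guarded to 0 instead of NaN.
#'
#' @param activity_row numeric vector of per-tissue activities (>= 3).
#' @param crup_row numeric vector of per-tissue enhancer scores, same
#'   tissue order.
#' @return Pearson correlation in [-1, 1].
#' @export
activity_crup_correlation <- function(activity_row, crup_row) {
  if (length(activity_row) != length(crup_row))
    stop("activity and enhancer-score profiles differ in length")
  if (length(activity_row) < 3) stop("need >= 3 tissues")
  if (sd(activity_row) == 0 || sd(crup_row) == 0) return(0)
  cor(activity_row, crup_row)
}

#' Read / write a dense TSV matrix with row and column headers
#' @param path file path.
#' @export
read_matrix_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' @rdname read_matrix_tsv
#' @param mat matrix to write.
#' @param key name for the row-id column (default "id").
#' @export
write_matrix_tsv <- function(mat, path, key = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- key
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
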