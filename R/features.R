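# End-to-end feature assembly: turns a (synthetic or loaded) world into the
# (region, TF, cell) feature table the models consume, wiring together the
# signal, motif, activity and cooperation modules.

#' Build the full feature table for a world
#'
#' Produces one row per (region, TF, cell) with the four feature classes:
#' \itemize{
#'   \item genomic: mean ReMap signal, conservation;
#'   \item motif: maximum PWM site score, number of sites, total-affinity
#'     p-score;
#'   \item cell type: quantile-normalized mean ATAC, differential ATAC,
#'     footprint, enhancer probability;
#'   \item cell-and-TF: z-scored log(1+TPM), expressed indicator, TF
#'     activity (A x W = C fit), activity-enhancer-score correlation, and
#'     the eight cooperation partner features.
#' }
#'
#' @param world a \code{tfb_world} (or the list from
#'   \code{\link{read_world}}).
#' @param coop_n,coop_k cooperation enhancer-selection sizes; default from
#'   the world's config.
#' @param activity_lambda ridge penalty for the TF-activity fit (default 0).
#' @return data.frame keyed by region_id, tf, cell (plus chrom metadata)
#'   with numeric feature columns.
#' @export
build_features <- function(world, coop_n = NULL, coop_k = NULL,
                           activity_lambda = 0) {
  cfg <- world$config
  if (is.null(coop_n)) coop_n <- if (!is.null(cfg$coop_n)) cfg$coop_n else 200L
  if (is.null(coop_k)) coop_k <- if (!is.null(cfg$coop_k)) cfg$coop_k else 40L
  regions <- world$regions
  tfs <- colnames(world$max_pwm)
  cells <- colnames(world$atac)
  ids <- regions$region_id

  atac_qn <- quantile_normalize(world$atac)
  global_other_mean <- function(m) {
    # delta vs mean of other cells, vectorized over regions
    tot <- rowSums(m)
    sapply(colnames(m), function(cell)
      m[, cell] - (tot - m[, cell]) / (ncol(m) - 1))
  }
  datac <- global_other_mean(atac_qn)

  expr_z <- normalize_expression(world$tpm)

  # TF activity from affinities vs enhancer probabilities
  W <- fit_activity(world$max_pwm, world$crup, lambda = activity_lambda)
  act_cor <- matrix(0, nrow = length(ids), ncol = length(tfs),
                    dimnames = list(ids, tfs))
  if (length(cells) >= 3)  # correlation feature needs >= 3 tissues
    for (t in tfs)
      act_cor[, t] <- apply(world$crup, 1, function(cr)
        activity_crup_correlation(W[t, ], cr))

  # cooperation partner features
  part <- partition_enhancers(world$atac, n = coop_n)
  universe <- unique(c(part$U, unlist(part$S)))
  bsets <- bound_sets(universe,
                      world$total_affinity[universe, , drop = FALSE],
                      k = coop_k)
  coop <- cooperation_table(part, bsets)
  pf <- lapply(tfs, function(tf)
    partner_features(tf, coop, world$n_sites, world$max_pwm))
  names(pf) <- tfs

  grid <- expand.grid(region_id = ids, tf = tfs, cell = cells,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ri <- match(grid$region_id, ids)
  ti <- match(grid$tf, tfs)
  ci <- match(grid$cell, cells)

  out <- data.frame(
    grid,
    chrom = regions$chrom[ri],
    remap_mean = unname(world$remap[ri]),
    phastcons_mean = unname(world$phastcons[ri]),
    max_score = world$max_pwm[cbind(ri, ti)],
    n_sites = world$n_sites[cbind(ri, ti)],
    affinity_pscore = world$affinity_pscore[cbind(ri, ti)],
    atac_mean = atac_qn[cbind(ri, ci)],
    delta_atac = datac[cbind(ri, ci)],
    footprint_mean = world$footprint[cbind(ri, ci)],
    crup_score = world$crup[cbind(ri, ci)],
    tpm_z = expr_z[cbind(ti, ci)],
    expressed = as.numeric(world$tpm[cbind(ti, ci)] > 0),
    tf_activity = W[cbind(ti, ci)],
    activity_crup_cor = act_cor[cbind(ri, ti)],
    stringsAsFactors = FALSE)
  pcols <- colnames(pf[[1]])
  for (col in pcols) out[[col]] <- 0
  for (t in tfs) {
    rows <- which(out$tf == t)
    out[rows, pcols] <- pf[[t]][ri[rows], , drop = FALSE]
  }
  attr(out, "cooperation") <- coop
  attr(out, "partition") <- part
  out
}

#' Join precomputed sequence embeddings onto a feature table
#'
#' @param features feature data.frame with a region_id column.
#' @param embeddings regions x dims matrix with region-id row names.
#' @return the feature table with embedding columns appended.
#' @export
add_embeddings <- function(features, embeddings) {
  stopifnot(!is.null(rownames(embeddings)))
  idx <- match(features$region_id, rownames(embeddings))
  if (any(is.na(idx))) stop("embeddings missing for some regions")
  cbind(features, as.data.frame(embeddings[idx, , drop = FALSE],
                                row.names = NULL))
}

#' Split a feature/label universe into training and test chromosomes
#'
#' By default mirrors the chromosome-holdout design: the configured test
#' chromosomes (for real data, chr1/chr8/chr20) are reserved for testing.
#'
#' @param features feature table with a chrom column.
#' @param test_chromosomes character vector of held-out chromosomes.
#' @return list with \code{train} and \code{test} feature tables.
#' @export
split_by_chromosome <- function(features,
                                test_chromosomes = c("chr1", "chr8", "chr20")) {
  is_test <- features$chrom %in% test_chromosomes
  list(train = features[!is_test, , drop = FALSE],
       test = features[is_test, , drop = FALSE])
}

#' Write / read a feature table as TSV
#' @param features feature data.frame.
#' @param path file path.
#' @export
write_features_tsv <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
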