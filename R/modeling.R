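# Training-table assembly and the four model families: general (cross-TF),
# TF-tuned (two-stage transfer: the general model's prediction becomes an
# input feature), TF-only, and the embedding-augmented variant, plus
# criss-cross tissue-by-chromosome ensembling.

#' Assemble a training table from features and labels
#'
#' Joins the feature table to the ternary label set on (region_id, tf,
#' cell), drops ambiguous (A) rows, maps B -> 1 and U -> 0, and restricts to
#' one TF when \code{scope = "tf"}. Under the general scope each region
#' contributes one row per (TF, cell) pair it is labeled in — the
#' region-replication scheme that lets a single model see the whole
#' training set. Missing numeric features are imputed as 0.
#'
#' @param features data.frame keyed by \code{region_id}, \code{tf},
#'   \code{cell} with numeric feature columns (an optional \code{chrom}
#'   column is kept as metadata for fold construction).
#' @param labels data.frame (region_id, tf, cell, label in \{B, A, U\}).
#' @param scope \code{"general"} or \code{"tf"}.
#' @param tf TF name, required when \code{scope = "tf"}.
#' @param extra_columns optional data.frame keyed by \code{region_id} with
#'   additional numeric columns (e.g. precomputed sequence embeddings),
#'   joined by region id.
#' @param require_positive error when no bound (B) rows survive; disable
#'   for held-out evaluation tables.
#' @return list of class \code{tfb_table}: \code{x} (numeric matrix),
#'   \code{y} (0/1), \code{meta} (region_id, tf, cell, chrom),
#'   \code{feature_names}.
#' @export
assemble_table <- function(features, labels, scope = c("general", "tf"),
                           tf = NULL, extra_columns = NULL,
                           require_positive = TRUE) {
  scope <- match.arg(scope)
  key <- c("region_id", "tf", "cell")
  stopifnot(all(key %in% names(features)), all(key %in% names(labels)))
  if (scope == "tf") {
    if (is.null(tf)) stop("tf must be given for tf scope")
    labels <- labels[labels$tf == tf, , drop = FALSE]
  }
  labels <- labels[labels$label != "A", , drop = FALSE]
  merged <- merge(features, labels, by = key, sort = FALSE)
  if (!is.null(extra_columns)) {
    stopifnot("region_id" %in% names(extra_columns))
    merged <- merge(merged, extra_columns, by = "region_id", sort = FALSE)
  }
  merged <- merged[order(merged$tf, merged$cell, merged$region_id), ,
                   drop = FALSE]
  y <- as.integer(merged$label == "B")
  if (require_positive && sum(y) == 0L)
    stop("empty positive class in assembled table")
  meta_cols <- intersect(c(key, "chrom"), names(merged))
  meta <- merged[, meta_cols, drop = FALSE]
  rownames(meta) <- NULL
  feat_cols <- setdiff(names(merged), c(meta_cols, "label"))
  x <- as.matrix(merged[, feat_cols, drop = FALSE])
  storage.mode(x) <- "double"
  x[is.na(x)] <- 0
  structure(list(x = x, y = y, meta = meta, feature_names = feat_cols),
            class = "tfb_table")
}

subset_table <- function(table, idx) {
  structure(list(x = table$x[idx, , drop = FALSE], y = table$y[idx],
                 meta = table$meta[idx, , drop = FALSE],
                 feature_names = table$feature_names),
            class = "tfb_table")
}

new_model_bundle <- function(booster, scope, variant, seed, params,
                             fold_spec = NULL) {
  structure(list(booster = booster, schema = booster$feature_names,
                 scope = scope, variant = variant, seed = seed,
                 params = params, fold_spec = fold_spec),
            class = "tfb_model")
}

#' Train the TF-agnostic general model
#'
#' Stage one of the transfer scheme: one booster over all (TF, cell) pairs,
#' with region replication, learning TF-agnostic binding structure.
#'
#' @param table a \code{tfb_table} from \code{\link{assemble_table}} with
#'   general scope.
#' @param params booster hyperparameters (\code{\link{gbt_params}}).
#' @param seed integer seed.
#' @return a \code{tfb_model} with variant \code{"general"}.
#' @export
train_general <- function(table, params = gbt_params(), seed = 1L) {
  booster <- gbt_train(table$x, table$y, params = params, seed = seed)
  new_model_bundle(booster, scope = "general", variant = "general",
                   seed = seed, params = params)
}

#' Train a TF-only model
#'
#' A booster trained solely on one TF's (region, cell) rows, without any
#' transfer feature.
#'
#' @param tf_table a TF-scoped \code{tfb_table}.
#' @inheritParams train_general
#' @param variant recorded variant tag: \code{"tf_only"} by default, or
#'   \code{"tf_transformer"} when the table carries embedding columns.
#' @return a \code{tfb_model}.
#' @export
train_tf_only <- function(tf_table, params = gbt_params(), seed = 1L,
                          variant = "tf_only") {
  tf <- unique(tf_table$meta$tf)
  stopifnot(length(tf) == 1L)
  booster <- gbt_train(tf_table$x, tf_table$y, params = params, seed = seed)
  new_model_bundle(booster, scope = paste0("tf:", tf), variant = variant,
                   seed = seed, params = params)
}

#' Train a TF-tuned model (stage-two transfer)
#'
#' Appends the general model's predicted binding probability as an
#' additional feature column (\code{general_score}) to the TF's rows, then
#' trains a booster on the augmented TF subset. The transfer feature lets
#' small per-TF training sets inherit cross-TF structure.
#'
#' @param tf_table a TF-scoped \code{tfb_table} whose columns contain the
#'   general model's schema.
#' @param general_model a \code{tfb_model} of variant \code{"general"}.
#' @inheritParams train_general
#' @return a \code{tfb_model} with variant \code{"tf_tuned"}; its schema
#'   includes \code{general_score}.
#' @export
train_tf_tuned <- function(tf_table, general_model, params = gbt_params(),
                           seed = 1L) {
  stopifnot(inherits(general_model, "tfb_model"))
  missing <- setdiff(general_model$schema, tf_table$feature_names)
  if (length(missing))
    stop("tf_table lacks general-model feature(s): ",
         paste(missing, collapse = ", "))
  tf <- unique(tf_table$meta$tf)
  stopifnot(length(tf) == 1L)
  gs <- predict(general_model, tf_table$x)
  x <- cbind(tf_table$x, general_score = gs)
  booster <- gbt_train(x, tf_table$y, params = params, seed = seed)
  bundle <- new_model_bundle(booster, scope = paste0("tf:", tf),
                             variant = "tf_tuned", seed = seed,
                             params = params)
  bundle$general_model <- general_model
  bundle
}

#' Criss-cross tissue-by-chromosome ensemble
#'
#' Splits the training tissues randomly into groups A/B and the training
#' chromosomes into groups 1/2, then trains four boosters on the
#' complementary blocks — (A,1) validated on (B,2), (A,2) on (B,1), (B,1)
#' on (A,2), (B,2) on (A,1) — each with early stopping once validation
#' AUPR fails to improve for \code{patience} rounds. The ensemble
#' prediction is the arithmetic mean of the four members, improving
#' robustness on unseen cell types.
#'
#' @param table a \code{tfb_table} whose \code{meta} has \code{cell} and
#'   \code{chrom}; needs >= 2 tissues and >= 2 chromosomes.
#' @param params booster hyperparameters.
#' @param split_seed seed for the random tissue/chromosome split and member
#'   training.
#' @param patience early-stopping patience in boosting rounds (default 50).
#' @return object of class \code{tfb_ensemble}: members, the splits, seed.
#' @export
train_criss_cross <- function(table, params = gbt_params(), split_seed = 1L,
                              patience = 50L) {
  tissues <- sort(unique(table$meta$cell))
  chroms <- sort(unique(table$meta$chrom))
  if (length(tissues) < 2 || length(chroms) < 2)
    stop("criss-cross needs >= 2 tissues and >= 2 chromosomes")
  set.seed(as.integer(split_seed))
  t_idx <- sample(length(tissues)) <= length(tissues) / 2
  c_idx <- sample(length(chroms)) <= length(chroms) / 2
  groups <- list(tissue = list(A = tissues[t_idx], B = tissues[!t_idx]),
                 chrom = list(`1` = chroms[c_idx], `2` = chroms[!c_idx]))

  pairings <- list(
    list(train = c("A", "1"), val = c("B", "2")),
    list(train = c("A", "2"), val = c("B", "1")),
    list(train = c("B", "1"), val = c("A", "2")),
    list(train = c("B", "2"), val = c("A", "1")))

  block_idx <- function(tg, cg) {
    which(table$meta$cell %in% groups$tissue[[tg]] &
          table$meta$chrom %in% groups$chrom[[cg]])
  }
  members <- vector("list", 4L)
  for (m in seq_along(pairings)) {
    pr <- pairings[[m]]
    tr <- block_idx(pr$train[1], pr$train[2])
    va <- block_idx(pr$val[1], pr$val[2])
    trn <- subset_table(table, tr)
    member_seed <- as.integer(split_seed) + m
    if (length(unique(table$y[va])) < 2L) {
      warning("validation block ", m, " has a single class; ",
              "member trained without early stopping")
      booster <- gbt_train(trn$x, trn$y, params = params, seed = member_seed)
    } else {
      booster <- gbt_train(trn$x, trn$y, params = params, seed = member_seed,
                           val = list(x = table$x[va, , drop = FALSE],
                                      y = table$y[va]),
                           early_stopping_rounds = patience)
    }
    members[[m]] <- new_model_bundle(
      booster, scope = "criss_cross", variant = "criss_cross_member",
      seed = member_seed, params = params,
      fold_spec = list(train = pr$train, val = pr$val))
  }
  structure(list(members = members, groups = groups,
                 split_seed = split_seed, patience = patience),
            class = "tfb_ensemble")
}

#' @export
print.tfb_ensemble <- function(x, ...) {
  cat("criss-cross ensemble of 4 members\n")
  cat("tissue groups: A = {", paste(x$groups$tissue$A, collapse = ", "),
      "}, B = {", paste(x$groups$tissue$B, collapse = ", "), "}\n")
  cat("chrom groups: 1 = {", paste(x$groups$chrom$`1`, collapse = ", "),
      "}, 2 = {", paste(x$groups$chrom$`2`, collapse = ", "), "}\n")
  invisible(x)
}

#' Predict from a model bundle
#'
#' @param object a \code{tfb_model}.
#' @param newdata data.frame or matrix carrying the model's schema; for
#'   TF-tuned models the \code{general_score} column is computed on the fly
#'   from the embedded general model when absent.
#' @param ... unused.
#' @return probabilities in [0, 1].
#' @export
predict.tfb_model <- function(object, newdata, ...) {
  if (object$variant == "tf_tuned" && !is.null(object$general_model)) {
    has_gs <- if (is.data.frame(newdata)) "general_score" %in% names(newdata)
              else "general_score" %in% colnames(newdata)
    if (!has_gs) {
      gs <- predict(object$general_model, newdata)
      newdata <- cbind(as.matrix(newdata), general_score = gs)
    }
  }
  predict(object$booster, newdata)
}

#' Predict from a criss-cross ensemble (mean of members)
#'
#' @param object a \code{tfb_ensemble}.
#' @param newdata feature rows.
#' @param ... unused.
#' @return probabilities in [0, 1]: the arithmetic mean of the four
#'   members' outputs.
#' @export
predict.tfb_ensemble <- function(object, newdata, ...) {
  preds <- lapply(object$members, predict, newdata = newdata)
  Reduce(`+`, preds) / length(preds)
}

#' Feature importance of a trained model
#'
#' Gain (total loss reduction contributed by splits on the feature — the
#' default, and the meaningful metric) or frequency (how often the feature
#' is split on, which can mislead by rewarding features used in many weak
#' splits).
#'
#' @param bundle a \code{tfb_model} or \code{tfb_gbt}.
#' @param metric \code{"gain"} or \code{"frequency"}.
#' @return data.frame (feature, importance) in decreasing order.
#' @export
feature_importance <- function(bundle, metric = c("gain", "frequency")) {
  metric <- match.arg(metric)
  booster <- if (inherits(bundle, "tfb_model")) bundle$booster else bundle
  if (!inherits(booster, "tfb_gbt")) stop("untrained or invalid bundle")
  imp <- if (metric == "gain") booster$importance_gain
         else booster$importance_frequency
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Save / load a model bundle as JSON (+ sidecar metadata)
#'
#' The booster's trees are serialized to JSON together with a metadata
#' record (schema, scope, variant, seed, params, fold spec), so artifacts
#' are plain text and portable.
#'
#' @param bundle a \code{tfb_model}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
save_model <- function(bundle, dir) {
  stopifnot(inherits(bundle, "tfb_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  booster <- bundle$booster
  jsonlite::write_json(
    list(trees = booster$trees, n_trees = booster$n_trees,
         base_score = booster$base_score,
         importance_gain = as.list(booster$importance_gain),
         importance_frequency = as.list(booster$importance_frequency)),
    file.path(dir, "booster.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(schema = bundle$schema, scope = bundle$scope,
         variant = bundle$variant, seed = bundle$seed,
         params = unclass(bundle$params), fold_spec = bundle$fold_spec),
    file.path(dir, "metadata.json"), digits = NA, auto_unbox = TRUE)
  if (!is.null(bundle$general_model))
    save_model(bundle$general_model, file.path(dir, "general_model"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  bj <- jsonlite::read_json(file.path(dir, "booster.json"),
                            simplifyVector = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  trees <- lapply(bj$trees, function(tr) {
    list(feature = vapply(tr$feature, as.integer, integer(1)),
         threshold = vapply(tr$threshold, as.numeric, numeric(1)),
         left = vapply(tr$left, as.integer, integer(1)),
         right = vapply(tr$right, as.integer, integer(1)),
         value = vapply(tr$value, as.numeric, numeric(1)),
         gain = vapply(tr$gain, as.numeric, numeric(1)),
         cover = vapply(tr$cover, as.numeric, numeric(1)))
  })
  params <- do.call(gbt_params, meta$params)
  booster <- structure(
    list(trees = trees, n_trees = as.integer(bj$n_trees),
         best_iteration = as.integer(bj$n_trees),
         best_score = NA_real_, eval_log = numeric(0),
         base_score = as.numeric(bj$base_score),
         importance_gain = unlist(bj$importance_gain),
         importance_frequency = unlist(bj$importance_frequency),
         feature_names = meta$schema, params = params, seed = meta$seed),
    class = "tfb_gbt")
  bundle <- new_model_bundle(booster, scope = meta$scope,
                             variant = meta$variant, seed = meta$seed,
                             params = params, fold_spec = meta$fold_spec)
  gdir <- file.path(dir, "general_model")
  if (dir.exists(gdir)) bundle$general_model <- load_model(gdir)
  bundle
}
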