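# Training-table assembly, the booster, transfer learning and criss-cross
# ensembling. Booster rounds are scaled down from the full-scale defaults
# to keep the suite fast.

test_that("assemble_table: replication, scoping, ambiguous exclusion", {
  w <- shared_world()
  f <- shared_features()
  n_pairs <- length(unique(paste(w$labels$tf, w$labels$cell)))
  tab <- assemble_table(f, w$labels, scope = "general")
  expect_lte(nrow(tab$x), nrow(w$regions) * n_pairs)
  # groupby oracle: every non-ambiguous (region, tf, cell) appears exactly once
  keep <- w$labels$label != "A"
  expect_equal(nrow(tab$x), sum(keep))
  expect_false(any(is.na(tab$x)))
  key_got <- sort(paste(tab$meta$region_id, tab$meta$tf, tab$meta$cell))
  key_want <- sort(paste(w$labels$region_id, w$labels$tf,
                         w$labels$cell)[keep])
  expect_equal(key_got, key_want)
  # tf scope restricts rows to that TF
  tf_tab <- assemble_table(f, w$labels, scope = "tf", tf = "TF2")
  expect_true(all(tf_tab$meta$tf == "TF2"))
  expect_equal(nrow(tf_tab$x),
               sum(keep & w$labels$tf == "TF2"))
  expect_error(assemble_table(f, w$labels, scope = "tf"), "tf must be given")
})

test_that("booster is seed-deterministic and outputs probabilities", {
  w <- shared_world()
  f <- shared_features()
  tab <- assemble_table(f, w$labels, scope = "general")
  m1 <- train_general(tab, params = test_params(40L), seed = 9L)
  m2 <- train_general(tab, params = test_params(40L), seed = 9L)
  p1 <- predict(m1, tab$x); p2 <- predict(m2, tab$x)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  m3 <- train_general(tab, params = test_params(40L), seed = 10L)
  expect_false(identical(p1, predict(m3, tab$x)))
  expect_error(gbt_train(matrix(1:10, 5), rep(1L, 5)), "both classes")
})

test_that("planted signal is learned far above prevalence; noise is not", {
  w <- shared_world()
  f <- shared_features()
  tab <- assemble_table(f, w$labels, scope = "general")
  m <- train_general(tab, params = test_params(60L), seed = 1L)
  train_aupr <- aupr(predict(m, tab$x), tab$y)
  expect_gt(train_aupr, 5 * mean(tab$y))
  # pure-noise features: held-out AUPR stays near prevalence
  set.seed(55)
  diffs <- replicate(5, {
    x <- matrix(rnorm(1500 * 6), 1500, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- rbinom(1500, 1, 0.1)
    tr <- sample(1500, 1000); te <- setdiff(seq_len(1500), tr)
    b <- gbt_train(x[tr, ], y[tr], params = test_params(30L), seed = 3L)
    aupr(predict(b, x[te, ]), y[te]) - mean(y[te])
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.05)
})

test_that("transfer: general_score dominates TF-tuned gains when informative", {
  w <- shared_world()
  f <- shared_features()
  gen_tab <- assemble_table(f, w$labels, scope = "general")
  gm <- train_general(gen_tab, params = test_params(60L), seed = 1L)
  tf_tab <- assemble_table(f, w$labels, scope = "tf", tf = "TF1")
  tt <- train_tf_tuned(tf_tab, gm, params = test_params(60L), seed = 2L)
  imp <- feature_importance(tt, metric = "gain")
  expect_equal(imp$feature[1], "general_score")
  # schema mismatch errors
  broken <- tf_tab
  broken$x <- broken$x[, -1, drop = FALSE]
  broken$feature_names <- colnames(broken$x)
  expect_error(train_tf_tuned(broken, gm, params = test_params(10L)),
               "lacks general-model feature")
})

test_that("an uninformative general model reduces TF-tuned to TF-only", {
  w <- shared_world()
  f <- shared_features()
  tf_tab <- assemble_table(f, w$labels, scope = "tf", tf = "TF1")
  # constant-output general model: a booster trained on a feature-free signal
  const_gm <- local({
    x <- tf_tab$x
    y <- tf_tab$y
    xz <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
    bundle <- train_general(structure(list(x = xz, y = y,
                                           meta = tf_tab$meta,
                                           feature_names = colnames(x)),
                                      class = "tfb_table"),
                            params = test_params(5L), seed = 1L)
    bundle
  })
  gs <- predict(const_gm, tf_tab$x)
  expect_lt(diff(range(gs)), 1e-9)
  tt <- train_tf_tuned(tf_tab, const_gm, params = test_params(40L), seed = 2L)
  to <- train_tf_only(tf_tab, params = test_params(40L), seed = 2L)
  # constant transfer feature is never split on
  imp <- feature_importance(tt)
  expect_equal(imp$importance[imp$feature == "general_score"], 0)
  a_tt <- aupr(predict(tt, tf_tab$x), tf_tab$y)
  a_to <- aupr(predict(to, tf_tab$x), tf_tab$y)
  expect_lt(abs(a_tt - a_to), 0.15)
})

test_that("criss-cross: pairings, block disjointness and the mean contract", {
  w <- shared_world()
  f <- shared_features()
  tab <- assemble_table(f, w$labels, scope = "tf", tf = "TF1")
  cc <- train_criss_cross(tab, params = test_params(50L), split_seed = 5L,
                          patience = 15L)
  expect_length(cc$members, 4)
  # the 4 train/val pairings are exactly the complementary block assignments
  specs <- lapply(cc$members, function(m) m$fold_spec)
  expect_setequal(vapply(specs, function(s) paste(s$train, collapse = ""),
                         character(1)),
                  c("A1", "A2", "B1", "B2"))
  for (s in specs) {
    expect_false(s$train[1] == s$val[1])
    expect_false(s$train[2] == s$val[2])
  }
  # no member sees its validation block's tissue or chromosome group
  for (m in cc$members) {
    tr_t <- cc$groups$tissue[[m$fold_spec$train[1]]]
    va_t <- cc$groups$tissue[[m$fold_spec$val[1]]]
    expect_length(intersect(tr_t, va_t), 0)
    tr_c <- cc$groups$chrom[[m$fold_spec$train[2]]]
    va_c <- cc$groups$chrom[[m$fold_spec$val[2]]]
    expect_length(intersect(tr_c, va_c), 0)
  }
  # ensemble = arithmetic mean of members, to 1e-12
  newx <- tab$x[1:50, , drop = FALSE]
  member_preds <- sapply(cc$members, function(m) predict(m, newx))
  expect_equal(predict(cc, newx), rowMeans(member_preds), tolerance = 1e-12)
})

test_that("predict contracts: empty input, missing columns, identical members", {
  w <- shared_world()
  f <- shared_features()
  tab <- assemble_table(f, w$labels, scope = "tf", tf = "TF1")
  m <- train_tf_only(tab, params = test_params(20L), seed = 1L)
  expect_length(predict(m, tab$x[0, , drop = FALSE]), 0)
  bad <- as.data.frame(tab$x[1:5, ])
  bad$atac_mean <- NULL
  expect_error(predict(m, bad), "atac_mean")
  fake_ens <- structure(list(members = list(m, m, m, m)),
                        class = "tfb_ensemble")
  expect_equal(predict(fake_ens, tab$x[1:20, ]),
               predict(m, tab$x[1:20, ]), tolerance = 1e-15)
  # scores bounded for random inputs
  set.seed(66)
  rnd <- matrix(rnorm(2000 * ncol(tab$x), sd = 5), 2000,
                dimnames = list(NULL, colnames(tab$x)))
  pr <- predict(m, rnd)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("feature importance: planted feature ranks first, constants at zero", {
  set.seed(57)
  n <- 1500
  x <- cbind(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n),
             flat = rep(1, n))
  y <- rbinom(n, 1, plogis(3 * x[, "signal"] - 2))
  b <- gbt_train(x, y, params = test_params(30L), seed = 1L)
  gain <- feature_importance(b, "gain")
  expect_equal(gain$feature[1], "signal")
  expect_equal(gain$importance[gain$feature == "flat"], 0)
  freq <- feature_importance(b, "frequency")
  expect_true(all(freq$importance >= 0))
  expect_error(feature_importance(list()), "untrained")
})

test_that("model bundles round-trip through JSON artifacts", {
  w <- shared_world()
  f <- shared_features()
  gen_tab <- assemble_table(f, w$labels, scope = "general")
  gm <- train_general(gen_tab, params = test_params(25L), seed = 1L)
  tf_tab <- assemble_table(f, w$labels, scope = "tf", tf = "TF1")
  tt <- train_tf_tuned(tf_tab, gm, params = test_params(25L), seed = 2L)
  dir <- tempfile()
  save_model(tt, dir)
  back <- load_model(dir)
  expect_equal(back$variant, "tf_tuned")
  expect_equal(back$schema, tt$schema)
  expect_equal(predict(back, tf_tab$x), predict(tt, tf_tab$x),
               tolerance = 1e-12)
})

test_that("default hyperparameters match the training configuration", {
  p <- gbt_params()
  expect_equal(p$nrounds, 500L)
  expect_equal(p$eta, 0.05)
  expect_equal(p$subsample, 0.8)
  expect_equal(p$colsample_bytree, 0.8)
  expect_equal(p$max_depth, 6L)
  expect_equal(p$min_child_weight, 1)
})
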