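# Enhancer partitioning, top-k bound sets, Fisher-based cooperation scores
# and partner features.

test_that("partition_enhancers: crafted matrices", {
  ids <- sprintf("e%02d", 1:30)
  m <- matrix(1, 30, 3, dimnames = list(ids, c("c1", "c2", "c3")))
  m[1:5, ] <- 10      # high everywhere -> ubiquitous
  m[6, 1] <- 50       # high only in c1
  part <- partition_enhancers(m, n = 5)
  expect_setequal(part$U, ids[1:5])
  expect_true("e06" %in% part$S$c1)
  expect_false("e06" %in% part$U)
  expect_error(partition_enhancers(m, n = 10), "infeasible")
})

test_that("partition_enhancers matches an independent sort-and-slice reference", {
  set.seed(41)
  ids <- sprintf("e%03d", 1:300)
  m <- matrix(rlnorm(300 * 4), 300, 4,
              dimnames = list(ids, paste0("c", 1:4)))
  n <- 50
  part <- partition_enhancers(m, n = n, low_frac = 0.25)
  # reference: U = top-n by min across cells
  u_want <- ids[order(-apply(m, 1, min), ids)][1:n]
  expect_equal(part$U, u_want)
  expect_equal(part$s, unname(sort(apply(m, 1, min), decreasing = TRUE)[n]))
  gm <- rowMeans(m)
  kept <- gm >= quantile(gm, 0.25)
  for (cell in colnames(m)) {
    rel <- (m[kept, cell] - gm[kept]) / gm[kept]
    s_want <- ids[kept][order(-rel, ids[kept])][1:n]
    expect_equal(part$S[[cell]], s_want)
  }
})

test_that("bound_sets selects top-k deterministically with id tie-breaks", {
  ids <- c("e1", "e2", "e3", "e4", "e5")
  aff <- matrix(c(5, 4, 3, 2, 1,
                  1, 1, 1, 1, 1), ncol = 2,
                dimnames = list(ids, c("TFa", "TFb")))
  bs <- bound_sets(ids, aff, k = 5)
  expect_setequal(bs$TFa, ids)
  bs2 <- bound_sets(ids, aff, k = 2)
  expect_equal(bs2$TFa, c("e1", "e2"))
  expect_equal(bs2$TFb, c("e1", "e2")) # all tied -> id order
  # permutation invariance under input reordering
  perm <- c(4, 2, 5, 1, 3)
  bs3 <- bound_sets(ids[perm], aff[perm, ], k = 2)
  expect_equal(bs3, bs2)
  expect_error(bound_sets(ids, aff, k = 9), "exceeds")
})

test_that("Fisher p matches the hypergeometric enumeration oracle", {
  expect_equal(fisher.test(matrix(c(8, 2, 2, 88), 2))$p.value,
               oracle_fisher(8, 2, 2, 88), tolerance = 1e-12)
  rec <- cooperation_score(B1 = paste0("e", 1:10), B2 = paste0("e", c(1:8, 90, 91)),
                           S_c = paste0("e", 1:100), U = paste0("u", 1:100))
  expect_equal(rec$p_cell, oracle_fisher(rec$a_c, rec$b_c, rec$c_c, rec$d_c),
               tolerance = 1e-12)
})

test_that("cooperation_score: symmetry, identical patterns give L = 0", {
  S_c <- paste0("s", 1:60)
  U <- paste0("u", 1:60)
  B1 <- c(paste0("s", 1:12), paste0("u", 1:12))
  B2 <- c(paste0("s", 5:16), paste0("u", 5:16))
  r12 <- cooperation_score(B1, B2, S_c, U)
  r21 <- cooperation_score(B2, B1, S_c, U)
  expect_equal(r12$L, r21$L, tolerance = 1e-12)
  expect_equal(r12$a_c, r21$a_c)
  # same co-binding structure in S_c and U -> p_cell = p_ubiq -> L = 0
  expect_equal(r12$L, 0, tolerance = 1e-12)
  # degenerate table: nothing bound -> both p = 1
  r0 <- cooperation_score(character(0), character(0), S_c, U)
  expect_equal(r0$p_cell, 1)
  expect_equal(r0$L, 0)
})

test_that("a planted cell-specific co-binding pattern is flagged cooperating", {
  set.seed(43)
  S_c <- paste0("s", 1:100)
  U <- paste0("u", 1:100)
  # co-bound in 15 cell-specific enhancers, independent in U
  B1 <- c(paste0("s", 1:15), sample(U, 15))
  B2 <- c(paste0("s", 1:15), sample(U, 15))
  rec <- cooperation_score(B1, B2, S_c, U)
  expect_gte(rec$a_c, 10)
  expect_gt(rec$L, 2)
  expect_true(rec$cooperating)
  # support rule: strong L but a_c < 10 is not flagged
  rec2 <- cooperation_score(paste0("s", 1:5), paste0("s", 1:5), S_c, U)
  expect_false(rec2$cooperating)
})

test_that("partner_features pads, orders by L, and picks top-4 of many", {
  ids <- paste0("e", 1:20)
  counts <- matrix(seq_len(20 * 7), 20, 7,
                   dimnames = list(ids, paste0("TF", 1:7)))
  scores <- counts / 10
  mk_rec <- function(partner, L) {
    data.frame(tf1 = "TF1", tf2 = partner, cell = "c1", a_c = 12,
               b_c = 1, c_c = 1, d_c = 86, p_cell = 1e-5, p_ubiq = 0.5,
               L = L, cooperating = TRUE, stringsAsFactors = FALSE)
  }
  # no partners -> all-zero 8 columns
  none <- partner_features("TF1", mk_rec("TF2", 5)[0, ], counts, scores)
  expect_equal(dim(none), c(20, 8))
  expect_true(all(none == 0))
  # six partners -> top 4 by L
  recs <- do.call(rbind, Map(mk_rec, paste0("TF", 2:7), c(3, 9, 4, 7, 2.5, 5)))
  pf <- partner_features("TF1", recs, counts, scores)
  expect_equal(attr(pf, "partners"), c("TF3", "TF5", "TF7", "TF4"))
  expect_equal(pf[, "partner1_nsites"], counts[, "TF3"])
  expect_equal(pf[, "partner2_maxscore"], scores[, "TF5"])
  # a non-cooperating record is ignored
  recs$cooperating[recs$tf2 == "TF3"] <- FALSE
  pf2 <- partner_features("TF1", recs, counts, scores)
  expect_equal(attr(pf2, "partners")[1], "TF5")
})

test_that("independent binding rarely produces cooperation flags", {
  set.seed(44)
  flagged <- 0; total <- 0
  for (rep in 1:3) {
    ids <- sprintf("e%03d", 1:500)
    m <- matrix(rlnorm(500 * 3), 500, 3,
                dimnames = list(ids, paste0("c", 1:3)))
    part <- partition_enhancers(m, n = 100)
    universe <- unique(c(part$U, unlist(part$S)))
    aff <- matrix(runif(length(universe) * 4), length(universe), 4,
                  dimnames = list(universe, paste0("TF", 1:4)))
    bsets <- bound_sets(universe, aff, k = 30)
    tab <- cooperation_table(part, bsets)
    flagged <- flagged + sum(tab$cooperating)
    total <- total + nrow(tab)
  }
  expect_lt(flagged / total, 0.05)
})
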