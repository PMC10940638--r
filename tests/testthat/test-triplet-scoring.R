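test_that("partial correlation equals the residual-regression oracle", {
  set.seed(17)
  for (i in 1:50) {
    n <- 50
    c0 <- rnorm(n)
    x <- 0.4 * c0 + rnorm(n)
    y <- -0.6 * c0 + rnorm(n)
    got <- partial_correlation(x, y, c0)
    rx <- resid(lm(x ~ c0)); ry <- resid(lm(y ~ c0))
    expect_equal(got$r, cor(rx, ry), tolerance = 1e-10)
  }
})

test_that("partial correlation collapses and degenerates as prescribed", {
  set.seed(23)
  n <- 30
  x <- rnorm(n); y <- rnorm(n)
  # covariate orthogonalized against x and y: formula collapses to r_xy
  c0 <- resid(lm(rnorm(n) ~ x + y))
  got <- partial_correlation(x, y, c0)
  expect_equal(got$r, cor(x, y), tolerance = 1e-10)
  # identity: x = y
  expect_equal(partial_correlation(x, x, c0)$r, 1, tolerance = 1e-12)
  expect_error(partial_correlation(x, y, rep(1, n)), "constant")
  expect_error(partial_correlation(x, y, x), "undefined")
  expect_error(partial_correlation(x, y[-1], c0[-1]), "equal length")
  expect_error(partial_correlation(x[1:3], y[1:3], c0[1:3]), "at least 4")
})

test_that("immune-gene ranking is signed, antisymmetric and null-calm", {
  set.seed(31)
  n <- 60
  lnc <- rnorm(n)
  m <- rbind(
    LNC = lnc,
    IMMtrack = lnc + rnorm(n, 0, 0.05),
    IMMa = rnorm(n), IMMb = rnorm(n), IMMc = rnorm(n)
  )
  colnames(m) <- sprintf("s%03d", seq_len(n))
  e <- as_expr(m, is_log2 = TRUE)
  purity <- runif(n, 0.3, 0.9)
  rk <- rank_immune_genes(e, "LNC", c("IMMtrack", "IMMa", "IMMb", "IMMc"),
                          purity)
  expect_identical(rk$gene_id[1], "IMMtrack")
  # sign flip of the lncRNA reverses the ranking exactly
  m2 <- m; m2["LNC", ] <- -m2["LNC", ]
  rk2 <- rank_immune_genes(as_expr(m2, is_log2 = TRUE), "LNC",
                           c("IMMtrack", "IMMa", "IMMb", "IMMc"), purity)
  expect_identical(rk2$gene_id, rev(rk$gene_id))
  expect_equal(rk2$score, -rev(rk$score), tolerance = 1e-12)
  # independent genes: scores hover near zero
  expect_lt(max(abs(rk$score[-1])), 3)
  expect_error(rank_immune_genes(e, "LNC", "IMMa"), "at least 2")
  expect_error(rank_immune_genes(e, "nope", c("IMMa", "IMMb")), "not found")
})

test_that("the S score follows its closed form, symmetry and linearity", {
  expect_identical(s_score(tibble::tibble(w = numeric(), p1 = numeric(),
                                          cor1 = numeric(), p2 = numeric(),
                                          cor2 = numeric())), 0)
  one <- tibble::tibble(w = 1, p1 = 0.01, cor1 = 0.5, p2 = 0.1,
                        cor2 = -0.4)
  expect_equal(s_score(one), 1, tolerance = 1e-12)
  # odd symmetry under sign negation
  set.seed(3)
  contrib <- tibble::tibble(w = runif(6, -1, 1), p1 = runif(6),
                            cor1 = rnorm(6), p2 = runif(6), cor2 = rnorm(6))
  flipped <- dplyr::mutate(contrib, cor1 = -cor1, cor2 = -cor2)
  expect_equal(s_score(flipped), -s_score(contrib), tolerance = 1e-12)
  # additive over disjoint contribution lists
  expect_equal(s_score(contrib),
               s_score(contrib[1:2, ]) + s_score(contrib[3:6, ]),
               tolerance = 1e-12)
  expect_error(s_score(dplyr::mutate(one, p1 = 0)), "floor")
  expect_error(s_score(dplyr::mutate(one, p2 = 1.5)), "<= 1")
})

make_scoring_fixture <- function(seed = 101) {
  coh <- simulate_cohort(small_sim_config(seed = seed))
  tum <- coh$meta$group == "tumor"
  lg <- log2_transform(filter_low_expressed(coh$expr))
  list(
    cohort = coh,
    expr_t = as_expr(expr_values(lg)[, tum, drop = FALSE], is_log2 = TRUE),
    purity = coh$meta$purity[tum]
  )
}

test_that("triplet scoring is deterministic and internally consistent", {
  fx <- make_scoring_fixture()
  run_once <- function() {
    sc <- suppressMessages(score_triplets(
      fx$expr_t, fx$cohort$catalog, fx$cohort$pathways, purity = fx$purity,
      B = 200, seed = 42))
    sc <- triplet_permutation_fdr(sc, B = 200, seed = 43)
    assemble_triplets(sc, fdr_cut = 0.05, cancer_type = "SIM")
  }
  t1 <- run_once()
  t2 <- run_once()
  expect_identical(t1, t2)
  expect_gt(nrow(t1), 0)
  # stored S equals the contribution sum recomputed from stored fields
  per_pair <- split(t1, paste(t1$lncRNA, t1$icp))
  for (pp in per_pair) {
    expect_equal(s_score(pp[, c("w", "p1", "cor1", "p2", "cor2")]),
                 pp$s[1], tolerance = 1e-9)
  }
})

test_that("planted pairs survive scoring while a failing pair is absent", {
  fx <- make_scoring_fixture()
  sc <- suppressMessages(score_triplets(
    fx$expr_t, fx$cohort$catalog, fx$cohort$pathways, purity = fx$purity,
    B = 500, seed = 7))
  sc <- triplet_permutation_fdr(sc, B = 500, seed = 8)
  trip <- assemble_triplets(sc, fdr_cut = 0.01, cancer_type = "SIM")
  truth <- fx$cohort$truth$planted
  found <- unique(paste(trip$lncRNA, trip$icp))
  expect_true(all(paste(truth$lncRNA, truth$icp) %in% found))
  # a pair that failed the FDR cut never reaches the triplet table
  failed <- sc$pairs[sc$pairs$fdr >= 0.01, ]
  if (nrow(failed) > 0) {
    expect_false(any(paste(failed$lncRNA, failed$icp) %in% found))
  }
})

test_that("duplicate candidate pair rows collapse to one deterministic record", {
  fx <- make_scoring_fixture()
  truth <- fx$cohort$truth$planted
  pairs <- tibble::tibble(lncRNA = rep(truth$lncRNA[1], 2),
                          icp = rep(truth$icp[1], 2))
  sc <- suppressMessages(score_triplets(
    fx$expr_t, fx$cohort$catalog, fx$cohort$pathways, purity = fx$purity,
    pairs = pairs, B = 100, seed = 5))
  expect_identical(nrow(sc$pairs), 1L)
})

test_that("missing purity falls back to plain correlation with a warning", {
  fx <- make_scoring_fixture()
  expect_warning(
    sc <- suppressMessages(score_triplets(
      fx$expr_t, fx$cohort$catalog, fx$cohort$pathways,
      purity = rep(NA_real_, ncol(expr_values(fx$expr_t))),
      B = 50, seed = 5)),
    "purity")
  expect_false(sc$purity_adjusted)
})
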