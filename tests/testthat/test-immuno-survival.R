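test_that("signature scores are marker means with linear-shift behavior", {
  m <- rbind(GZMA = c(2, 6), PRF1 = c(4, 2), OTHER = c(9, 9))
  colnames(m) <- c("s1", "s2")
  e <- as_expr(m, is_log2 = TRUE)
  # two markers (2, 4) -> 3
  sc <- signature_score(e, c("GZMA", "PRF1"), "CYT")
  expect_equal(sc$score, c(3, 4))
  # single marker: the gene's own row
  expect_equal(signature_score(e, "GZMA")$score, c(2, 6))
  # missing markers reported, all-missing is an error
  expect_message(signature_score(e, c("GZMA", "NOPE")), "NOPE")
  expect_error(suppressMessages(signature_score(e, "NOPE")), "no marker")
  # adding a constant to all markers shifts scores by that constant
  m2 <- m; m2[c("GZMA", "PRF1"), ] <- m2[c("GZMA", "PRF1"), ] + 1.5
  sc2 <- signature_score(as_expr(m2, is_log2 = TRUE), c("GZMA", "PRF1"))
  expect_equal(sc2$score, sc$score + 1.5, tolerance = 1e-12)
})

test_that("spearman handles monotone, reversed and tied data", {
  x <- c(1, 2, 3, 5, 8, 13)
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  # tied data: equals rank-then-Pearson with average ranks
  set.seed(2)
  xt <- sample(rep(1:4, length.out = 10))
  yt <- sample(rep(1:3, length.out = 10))
  got <- spearman(xt, yt)
  expect_equal(got$rho, cor(rank(xt), rank(yt)), tolerance = 1e-12)
  expect_error(spearman(rep(1, 6), x), "constant")
  expect_error(spearman(x[1:3], x[1:3]), "at least 4")
})

test_that("kruskal-wallis matches the rank-sum formula", {
  got <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(got$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(got$p_value, pchisq(27 / 7, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # all observations equal: no rank variation
  flat <- kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), 3))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
  # null: p roughly uniform across replicates
  set.seed(8)
  ps <- replicate(200, kruskal_wallis(rnorm(30), rep(1:3, 10))$p_value)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("log-rank test agrees with the risk-table oracle", {
  # identical groups: no separation
  t0 <- c(3, 5, 7, 9, 3, 5, 7, 9)
  e0 <- c(1, 1, 0, 1, 1, 1, 0, 1)
  g0 <- rep(c("a", "b"), each = 4)
  same <- logrank_test(t0, e0, g0)
  expect_equal(same$chi2, 0, tolerance = 1e-9)
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  # extreme separation
  sep <- logrank_test(c(1:6, 101:106), c(rep(1, 6), rep(0, 6)),
                      rep(c("a", "b"), each = 6))
  expect_gt(sep$chi2, 8)
  # 12-subject toy with censoring vs hand enumeration
  set.seed(9)
  tt <- c(2, 4, 4, 6, 7, 9, 3, 5, 8, 10, 11, 12)
  ee <- c(1, 1, 0, 1, 1, 0, 1, 1, 1, 0, 1, 1)
  gg <- rep(c("hi", "lo"), each = 6)
  got <- logrank_test(tt, ee, gg)
  want <- logrank_oracle(tt, ee, gg)
  expect_equal(got$chi2, want$chi2, tolerance = 1e-9)
  expect_equal(got$p_value, want$p, tolerance = 1e-9)
  # invariant under label swap
  swap <- logrank_test(tt, ee, rev(gg))
  expect_equal(swap$chi2, logrank_test(tt, ee, gg)$chi2, tolerance = 1e-9)
  expect_error(logrank_test(tt, ee, rep("a", 12)), "two")
})

test_that("the dual Cox/log-rank screen is calibrated and powered", {
  set.seed(30)
  n <- 300
  # planted proportional-hazards gene plus nulls
  x_risk <- rnorm(n)
  times <- rexp(n, rate = 0.1 * exp(1.2 * x_risk))
  cens <- rexp(n, rate = 0.02)
  os_t <- pmin(times, cens); os_e <- as.numeric(times <= cens)
  m <- rbind(RISK = x_risk,
             matrix(rnorm(20 * n), 20,
                    dimnames = list(sprintf("N%02d", 1:20), NULL)))
  colnames(m) <- sprintf("s%03d", seq_len(n))
  scr <- univariate_survival_screen(as_expr(m, is_log2 = TRUE), os_t, os_e)
  expect_true(scr$candidate[scr$gene_id == "RISK"])
  # null genes: candidate rate bounded by the joint type-I level
  expect_lte(mean(scr$candidate[-1]), 0.15)
  expect_error(univariate_survival_screen(as_expr(m, is_log2 = TRUE),
                                          os_t, rep(0, n)), "events")
})

test_that("risk scores are exact linear combinations with a median split", {
  m <- rbind(A = c(1, 0, 2), B = c(2, 0, 4), C = c(3, 0, 6))
  colnames(m) <- c("s1", "s2", "s3")
  e <- as_expr(m, is_log2 = TRUE)
  rm_ <- suppressWarnings(risk_score(e, c(A = 1, B = 1, C = 1)))
  expect_equal(rm_$samples$risk, c(6, 0, 12))
  expect_identical(rm_$samples$group, c("low", "low", "high")) # ties to low
  # zero coefficients: degenerate split is flagged
  expect_warning(r0 <- risk_score(e, c(A = 0, B = 0, C = 0)), "degenerate")
  expect_true(r0$degenerate)
  expect_error(risk_score(e, c(ZZ = 1)), "absent")
})

test_that("a fitted triplet risk model separates planted survival groups", {
  coh <- simulate_cohort(small_sim_config(seed = 404))
  tum <- coh$meta$group == "tumor"
  lg <- log2_transform(filter_low_expressed(coh$expr))
  et <- as_expr(expr_values(lg)[, tum, drop = FALSE], is_log2 = TRUE)
  rm_ <- fit_risk_model(et, coh$meta$os_time[tum], coh$meta$os_event[tum],
                        coh$truth$survival$genes)
  expect_identical(nrow(rm_$betas), 3L)
  expect_lt(rm_$logrank$p_value, 0.05)
  # tidiers expose betas and the test summary
  td <- tidy(rm_)
  expect_identical(td$term, coh$truth$survival$genes)
  gl <- glance(rm_)
  expect_identical(gl$logrank_p, rm_$logrank$p_value)
})
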