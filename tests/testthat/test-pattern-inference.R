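test_that("linear-Gaussian node fits agree with lm and its MLE log-likelihood", {
  set.seed(5)
  n <- 100
  x <- rnorm(n)
  y <- 2 * x + rnorm(n, 0, 0.01)
  fit <- fit_linear_gaussian(y, cbind(L = x))
  ref <- lm(y ~ x)
  expect_equal(unname(fit$coefficients["L"]), unname(coef(ref)[2]),
               tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["L"]), 2, tolerance = 0.01)
  # stats::logLik.lm uses the same MLE variance convention
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-9)
  expect_identical(fit$k, 3L)
  # marginal fit: mean/variance MLE, k = 2
  f0 <- fit_linear_gaussian(y)
  expect_equal(unname(f0$coefficients[1]), mean(y), tolerance = 1e-12)
  expect_equal(f0$sigma2, mean((y - mean(y))^2), tolerance = 1e-12)
  expect_identical(f0$k, 2L)
  # independent parent: slope near zero
  f1 <- fit_linear_gaussian(rnorm(n), cbind(z = rnorm(n)))
  expect_lt(abs(f1$coefficients["z"]), 0.3)
  expect_error(fit_linear_gaussian(y, cbind(a = x, b = 2 * x)), "collinear")
  expect_error(fit_linear_gaussian(y[1:3], cbind(a = x[1:3])), "too few")
})

test_that("each generating mechanism maximizes its own pattern likelihood", {
  for (pat in c("COO", "LGI", "LIG", "INDEP")) {
    tri <- simulate_triplet(pat, 500, a = 0.8, b = 0.8, sigma = 0.5,
                            seed = 99)
    ll <- vapply(c("INDEP", "COO", "LGI", "LIG"), function(p) {
      pattern_loglik(scale(tri$L)[, 1], scale(tri$C)[, 1],
                     scale(tri$M)[, 1], p)$loglik
    }, numeric(1))
    expect_identical(names(which.max(ll)), pat)
  }
  tri <- simulate_triplet("COO", 100, seed = 1)
  ks <- vapply(c("INDEP", "COO", "LGI", "LIG"), function(p) {
    pattern_loglik(tri$L, tri$C, tri$M, p)$k
  }, integer(1))
  expect_true(all(ks == 8L))
  expect_error(pattern_loglik(tri$L, tri$C, tri$M, "XXX"), "unknown")
  expect_error(pattern_loglik(tri$L[1:5], tri$C[1:5], tri$M[1:5], "COO"),
               "at least 8")
  expect_error(pattern_loglik(tri$L, tri$C[-1], tri$M, "COO"), "aligned")
})

test_that("Akaike weights follow the closed form", {
  expect_equal(akaike_weights(c(5, 5)), c(0.5, 0.5))
  w <- akaike_weights(c(10, 12))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  w2 <- akaike_weights(c(0, 150, 200))
  expect_gt(w2[1], 0.999999)
  expect_error(akaike_weights(c(1, Inf)), "finite")
  expect_error(akaike_weights(3), "at least 2")
})

test_that("pattern selection satisfies its AIC/weight invariants", {
  set.seed(61)
  for (i in 1:20) {
    pat <- sample(c("INDEP", "COO", "LGI", "LIG"), 1)
    tri <- simulate_triplet(pat, 150, seed = 600 + i)
    call <- select_pattern(tri$L, tri$C, tri$M)
    f <- call$fits
    expect_equal(sum(f$weight), 1, tolerance = 1e-9)
    expect_equal(f$aic, -2 * f$loglik + 2 * f$k, tolerance = 1e-9)
    expect_identical(f$pattern[which.min(f$aic)],
                     f$pattern[which.max(f$weight)])
    expect_identical(call$best, f$pattern[which.min(f$aic)])
    expect_equal(f$delta, f$aic - min(f$aic), tolerance = 1e-12)
    # equal k for all patterns: AIC ordering must equal loglik ordering
    expect_identical(order(f$aic), order(-f$loglik))
  }
  # n = 8 pure noise still yields a call (contract, not accuracy)
  set.seed(3)
  call <- select_pattern(rnorm(8), rnorm(8), rnorm(8))
  expect_true(call$best %in% c("INDEP", "COO", "LGI", "LIG"))
  expect_type(call$ambiguous, "logical")
})

test_that("pattern recovery is near-perfect at the reference strength", {
  for (pat in c("COO", "LIG")) { # shared-skeleton pair
    hits <- vapply(1:30, function(s) {
      tri <- simulate_triplet(pat, 500, a = 0.8, b = 0.8, sigma = 0.5,
                              seed = 3000 + s)
      select_pattern(tri$L, tri$C, tri$M)$best == pat
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  }
})

test_that("lncRNAs classify as common, specific or intermediate by cancer count", {
  tab <- tibble::tibble(
    lncRNA = c(rep("L5", 5), rep("L2", 2), rep("L3", 3)),
    cancer_type = c(paste0("ca", 1:5), paste0("ca", 1:2), paste0("ca", 1:3))
  )
  cl <- classify_lncRNAs(tab)
  expect_identical(cl$class[cl$lncRNA == "L5"], "common")
  expect_identical(cl$class[cl$lncRNA == "L2"], "specific")
  expect_identical(cl$class[cl$lncRNA == "L3"], "intermediate")
  # list-of-tables input binds
  cl2 <- classify_lncRNAs(split(tab, tab$cancer_type))
  expect_identical(dplyr::arrange(cl2, lncRNA), dplyr::arrange(cl, lncRNA))
})

test_that("pattern-variable pairs need >=5 cancers, >=2 patterns, distinct genes", {
  base <- tibble::tibble(
    lncRNA = "L1", icp = "C1",
    cancer_type = paste0("ca", 1:6),
    immune_gene = paste0("M", 1:6),
    pattern = "COO"
  )
  expect_identical(nrow(pattern_variable_pairs(base)), 0L) # single pattern
  two <- base; two$pattern[4:6] <- "LGI"
  pv <- pattern_variable_pairs(two)
  expect_identical(nrow(pv), 1L)
  expect_identical(pv$patterns, "COO+LGI")
  few <- two[1:4, ] # below the cancer-count threshold
  expect_identical(nrow(pattern_variable_pairs(few)), 0L)
  # two patterns but always the same immune gene: excluded
  same_gene <- two; same_gene$immune_gene <- "M1"
  expect_identical(nrow(pattern_variable_pairs(same_gene)), 0L)
})

test_that("call_patterns emits one call per (pair, immune gene) contribution", {
  tri <- simulate_triplet("LGI", 60, seed = 77)
  m <- rbind(L1 = tri$L, C1 = tri$C, M1 = tri$M, M2 = rnorm(60))
  colnames(m) <- sprintf("s%02d", 1:60)
  trips <- tibble::tibble(cancer_type = "ca1", lncRNA = "L1",
                          immune_gene = c("M1", "M2"), icp = "C1")
  calls <- call_patterns(as_expr(m, is_log2 = TRUE), trips)
  expect_identical(nrow(calls), 2L)
  expect_identical(calls$pattern[calls$immune_gene == "M1"], "LGI")
  expect_equal(calls$w_indep + calls$w_coo + calls$w_lgi + calls$w_lig,
               rep(1, 2), tolerance = 1e-9)
})
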