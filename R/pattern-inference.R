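#' Regulatory pattern selection among four linear-Gaussian DAGs
#'
#' Each triplet (lncRNA L, ICP C, immune gene M) is fit under four fixed
#' directed acyclic graphs, each factorizing the joint density into
#' node-wise linear-Gaussian conditionals:
#'
#' * `INDEP`: P(L) P(C|L) P(M|L) — the lncRNA regulates both independently;
#' * `COO`:   P(L) P(M) P(C|L,M) — lncRNA and immune gene co-regulate the ICP;
#' * `LGI`:   P(L) P(M|L) P(C|M) — chain lncRNA -> immune gene -> ICP;
#' * `LIG`:   P(L) P(C|L) P(M|C) — chain lncRNA -> ICP -> immune gene.
#'
#' Maximum-likelihood fits give each pattern an AIC = -2 logL + 2K and
#' Akaike weights `w_j = exp(-delta_j/2) / sum exp(-delta/2)`; the pattern
#' with the lowest AIC (largest weight) is selected.
#'
#' @name pattern_inference
NULL

pattern_levels <- c("INDEP", "COO", "LGI", "LIG")

#' Linear-Gaussian maximum-likelihood fit of one node
#'
#' Fits `child ~ parents` by least squares with the MLE variance
#' (RSS / n, not RSS / (n - p)) and returns the Gaussian log-likelihood.
#' With zero parents this is the marginal Gaussian MLE. The parameter
#' count k includes the intercept, one slope per parent, and the variance.
#'
#' @param child Numeric response vector.
#' @param parents Numeric matrix (n x p) of parent values, or `NULL` for a
#'   marginal fit.
#' @return List with `coefficients`, `sigma2` (MLE residual variance),
#'   `loglik`, `k`.
#' @export
fit_linear_gaussian <- function(child, parents = NULL) {
  n <- length(child)
  p <- if (is.null(parents)) 0L else ncol(as.matrix(parents))
  if (n <= p + 2L) abort("too few observations for the number of parents")
  Xd <- cbind(`(Intercept)` = rep(1, n), parents)
  if (qr(Xd)$rank < ncol(Xd)) abort("collinear parents; fit is not identifiable")
  fit <- stats::lm.fit(Xd, child)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  if (sigma2 <= 0) sigma2 <- .Machine$double.eps
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  list(coefficients = fit$coefficients, sigma2 = sigma2,
       loglik = loglik, k = p + 2L)
}

#' Log-likelihood of a triplet under one regulatory pattern
#'
#' Sums the node-wise linear-Gaussian log-likelihoods of the pattern's
#' factorization. All four patterns have K = 8 free parameters under this
#' parameterization; K is nevertheless accumulated from the node fits.
#'
#' @param L,C,M Aligned numeric vectors: lncRNA, ICP and immune-gene
#'   expression (n >= 8).
#' @param pattern One of `"INDEP"`, `"COO"`, `"LGI"`, `"LIG"`.
#' @return List with `loglik` and `k`.
#' @export
pattern_loglik <- function(L, C, M, pattern) {
  if (length(unique(c(length(L), length(C), length(M)))) != 1L) {
    abort("L, C, M must be aligned")
  }
  if (length(L) < 8L) abort("need at least 8 observations")
  fits <- switch(pattern,
    INDEP = list(fit_linear_gaussian(L),
                 fit_linear_gaussian(C, cbind(L = L)),
                 fit_linear_gaussian(M, cbind(L = L))),
    COO = list(fit_linear_gaussian(L),
               fit_linear_gaussian(M),
               fit_linear_gaussian(C, cbind(L = L, M = M))),
    LGI = list(fit_linear_gaussian(L),
               fit_linear_gaussian(M, cbind(L = L)),
               fit_linear_gaussian(C, cbind(M = M))),
    LIG = list(fit_linear_gaussian(L),
               fit_linear_gaussian(C, cbind(L = L)),
               fit_linear_gaussian(M, cbind(C = C))),
    abort(paste0("unknown pattern: ", pattern))
  )
  list(loglik = sum(vapply(fits, `[[`, numeric(1), "loglik")),
       k = sum(vapply(fits, `[[`, integer(1), "k")))
}

#' Akaike weights from AIC values
#'
#' `w_j = exp(-delta_j / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_j = AIC_j - min(AIC)`; the minimum is subtracted before
#' exponentiation for numerical stability.
#'
#' @param aics Numeric vector (length >= 2) of finite AIC values.
#' @return Weights summing to 1, in the input order.
#' @export
akaike_weights <- function(aics) {
  if (length(aics) < 2L) abort("need at least 2 AIC values")
  if (any(!is.finite(aics))) abort("non-finite AIC value")
  delta <- aics - min(aics)
  e <- exp(-delta / 2)
  e / sum(e)
}

#' Select the best regulatory pattern for one triplet
#'
#' Fits all four patterns, computes AIC, delta-AIC and Akaike weights, and
#' selects the minimum-AIC pattern. Exact AIC ties are broken by the fixed
#' preference order INDEP > COO > LGI > LIG and force the ambiguity flag.
#' The call is flagged ambiguous whenever the top weight falls below
#' `ambiguity_threshold`.
#'
#' @inheritParams pattern_loglik
#' @param standardize Z-score each vector before fitting (default TRUE),
#'   making log-likelihoods comparable across triplets.
#' @param ambiguity_threshold Minimum top weight for an unambiguous call
#'   (default 0.5).
#' @return An `icp_pattern_call`: list with `fits` (tibble: pattern,
#'   loglik, k, aic, delta, weight), `best`, `ambiguous`.
#' @export
select_pattern <- function(L, C, M, standardize = TRUE,
                           ambiguity_threshold = 0.5) {
  if (standardize) {
    L <- as.numeric(scale(L)); C <- as.numeric(scale(C)); M <- as.numeric(scale(M))
  }
  fits <- lapply(pattern_levels, function(p) pattern_loglik(L, C, M, p))
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  k <- vapply(fits, `[[`, integer(1), "k")
  aic <- -2 * ll + 2 * k
  delta <- aic - min(aic)
  weight <- akaike_weights(aic)
  tied <- sum(aic == min(aic)) > 1L
  best <- pattern_levels[which(aic == min(aic))[1]]
  ambiguous <- tied || max(weight) < ambiguity_threshold
  structure(list(
    fits = tibble::tibble(pattern = pattern_levels, loglik = ll, k = k,
                          aic = aic, delta = delta, weight = weight),
    best = best, ambiguous = ambiguous
  ), class = "icp_pattern_call")
}

#' @export
print.icp_pattern_call <- function(x, ...) {
  cat("Regulatory pattern call: best =", x$best,
      if (x$ambiguous) "(ambiguous)" else "", "\n")
  print(x$fits)
  invisible(x)
}

#' Pattern calls for every triplet contribution
#'
#' Runs [select_pattern()] on (lncRNA, immune gene, ICP) expression for
#' each row of an assembled triplet table; a pair with m mediating immune
#' genes yields m calls.
#'
#' @param expr Log2 expression table (tumor samples).
#' @param triplets Output of [assemble_triplets()] (needs `lncRNA`,
#'   `immune_gene`, `icp`; `cancer_type` is carried through).
#' @inheritParams select_pattern
#' @return Tibble: `cancer_type`, `lncRNA`, `immune_gene`, `icp`,
#'   `pattern`, per-pattern AIC and weight columns, `ambiguous`.
#' @export
call_patterns <- function(expr, triplets, standardize = TRUE,
                          ambiguity_threshold = 0.5) {
  X <- expr_values(expr)
  if (!"cancer_type" %in% names(triplets)) triplets$cancer_type <- "NA"
  trip <- dplyr::distinct(triplets, .data$cancer_type, .data$lncRNA,
                          .data$immune_gene, .data$icp)
  rows <- lapply(seq_len(nrow(trip)), function(i) {
    call <- select_pattern(X[trip$lncRNA[i], ], X[trip$icp[i], ],
                           X[trip$immune_gene[i], ],
                           standardize = standardize,
                           ambiguity_threshold = ambiguity_threshold)
    f <- call$fits
    tibble::tibble(
      cancer_type = trip$cancer_type[i], lncRNA = trip$lncRNA[i],
      immune_gene = trip$immune_gene[i], icp = trip$icp[i],
      pattern = call$best,
      aic_indep = f$aic[1], aic_coo = f$aic[2],
      aic_lgi = f$aic[3], aic_lig = f$aic[4],
      w_indep = f$weight[1], w_coo = f$weight[2],
      w_lgi = f$weight[3], w_lig = f$weight[4],
      ambiguous = call$ambiguous
    )
  })
  dplyr::bind_rows(rows)
}

#' Classify lncRNAs as common, specific or intermediate across cancers
#'
#' A lncRNA found in triplets of five or more cancer types is "common",
#' in at most two is "specific", otherwise "intermediate".
#'
#' @param triplets A triplet or call table with `lncRNA` and `cancer_type`
#'   columns, or a list of per-cancer tables (bound together).
#' @param common_min Minimum cancer count for "common" (default 5).
#' @param specific_max Maximum cancer count for "specific" (default 2).
#' @return Tibble `lncRNA`, `n_cancers`, `class`.
#' @export
classify_lncRNAs <- function(triplets, common_min = 5L, specific_max = 2L) {
  if (is.list(triplets) && !is.data.frame(triplets)) {
    triplets <- dplyr::bind_rows(triplets)
  }
  out <- dplyr::summarise(dplyr::group_by(triplets, .data$lncRNA),
                          n_cancers = dplyr::n_distinct(.data$cancer_type),
                          .groups = "drop")
  out$class <- dplyr::case_when(
    out$n_cancers >= common_min ~ "common",
    out$n_cancers <= specific_max ~ "specific",
    TRUE ~ "intermediate"
  )
  out
}

#' Pattern-variable (lncRNA, ICP) pairs across cancers
#'
#' Pairs present in at least `min_cancers` cancer types whose calls span at
#' least two distinct patterns attributable to different immune genes.
#'
#' @param calls Pattern-call table from [call_patterns()] across cancers.
#' @param min_cancers Minimum number of cancers (default 5).
#' @return Tibble `lncRNA`, `icp`, `n_cancers`, `n_patterns`, `patterns`
#'   (collapsed string), `variable` (logical); only variable pairs are
#'   returned.
#' @export
pattern_variable_pairs <- function(calls, min_cancers = 5L) {
  by_pair <- dplyr::group_by(calls, .data$lncRNA, .data$icp)
  summ <- dplyr::summarise(
    by_pair,
    n_cancers = dplyr::n_distinct(.data$cancer_type),
    n_patterns = dplyr::n_distinct(.data$pattern),
    patterns = paste(sort(unique(.data$pattern)), collapse = "+"),
    multi_gene_patterns = {
      # two calls with different pattern AND different immune gene
      pt <- .data$pattern; g <- .data$immune_gene
      any(outer(pt, pt, "!=") & outer(g, g, "!="))
    },
    .groups = "drop"
  )
  summ$variable <- summ$n_cancers >= min_cancers & summ$n_patterns >= 2L &
    summ$multi_gene_patterns
  dplyr::select(dplyr::filter(summ, .data$variable), -"multi_gene_patterns")
}
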