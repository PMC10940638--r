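#' Immune-activity scores and survival analysis
#'
#' Antitumor immune activity is summarized by marker-mean signature scores
#' (MHC presentation, cytolytic activity) and per-sample ssGSEA; lncRNAs
#' are related to these scores by Spearman correlation and Kruskal-Wallis
#' tests. Prognostic triplets are screened by a dual univariate Cox /
#' log-rank filter and summarized by a multivariate-Cox risk score with a
#' median split.
#'
#' @name immuno_survival
NULL

# Default marker reconstructions for cytolytic activity (geometric-mean
# convention simplified to the arithmetic mean on the log2 scale) and MHC
# class-I antigen presentation. Shipped as editable data, not hard-coded
# truth: replace with curated lists where available.
#' Default immune-activity marker sets (synthetic reconstructions)
#'
#' `CYT`: cytolytic effector markers; `MHC`: MHC class-I presentation
#' machinery. These are conventional reconstructions for demonstration and
#' testing; supply curated lists for real analyses.
#' @return Named list of character vectors.
#' @export
default_activity_markers <- function() {
  list(
    CYT = c("GZMA", "PRF1"),
    MHC = c("HLA-A", "HLA-B", "HLA-C", "B2M", "TAP1", "TAP2")
  )
}

#' Marker-mean signature score
#'
#' Per-sample arithmetic mean of the marker rows (log2 scale). Markers
#' absent from the matrix are reported with a message; at least one must be
#' present.
#'
#' @param expr Log2 expression table.
#' @param markers Character vector of marker gene IDs.
#' @param signature_name Label attached to the output.
#' @return Tibble `sample_id`, `score`, `signature`.
#' @export
signature_score <- function(expr, markers, signature_name = "signature") {
  X <- expr_values(expr)
  present <- intersect(markers, rownames(X))
  if (length(present) == 0L) abort("no marker gene present in the matrix")
  missing <- setdiff(markers, present)
  if (length(missing) > 0L) {
    inform(paste0("markers absent from matrix: ", paste(missing, collapse = ", ")))
  }
  sc <- colMeans(X[present, , drop = FALSE])
  tibble::tibble(sample_id = colnames(X), score = as.numeric(sc),
                 signature = signature_name)
}

#' Spearman rank correlation
#'
#' Average ranks for ties; two-sided p-value via the t approximation.
#'
#' @param x,y Numeric vectors (n >= 4), neither constant.
#' @return One-row tibble `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) < 4L) abort("need at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Kruskal-Wallis rank test
#'
#' @param values Numeric observations.
#' @param groups Group labels (>= 2 groups).
#' @return One-row tibble `statistic` (tie-corrected H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) abort("need at least 2 groups")
  if (sd(values) == 0) {
    # no rank variation at all: H = 0 by convention
    return(tibble::tibble(statistic = 0, df = nlevels(groups) - 1L,
                          p_value = 1))
  }
  kt <- kruskal.test(values, groups)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p_value = kt$p.value)
}

#' Two-group log-rank test
#'
#' @param times Follow-up times.
#' @param events Event indicator (1 = event, 0 = censored).
#' @param groups Two-level group labels, each level non-empty.
#' @return One-row tibble `chi2`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L || any(table(groups) == 0L)) {
    abort("log-rank test needs two non-empty groups")
  }
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  chi2 <- sd_$chisq
  tibble::tibble(chi2 = chi2, df = 1L,
                 p_value = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Dual Cox / log-rank univariate survival screen
#'
#' Per gene: the score-test p-value of a univariate Cox regression on the
#' continuous expression, and the log-rank p-value of the median-split
#' (exact-median samples to the low group). A gene is a candidate when both
#' p-values fall below `alpha`.
#'
#' @param expr Log2 expression table (tumor samples).
#' @param os_time,os_event Survival time and event indicator aligned to the
#'   samples.
#' @param genes Genes to screen (default all rows).
#' @param alpha Per-test significance level (default 0.05).
#' @return Tibble `gene_id`, `cox_p`, `logrank_p`, `candidate`.
#' @export
univariate_survival_screen <- function(expr, os_time, os_event,
                                       genes = NULL, alpha = 0.05) {
  X <- expr_values(expr)
  genes <- genes %||% rownames(X)
  ok <- is.finite(os_time) & !is.na(os_event)
  if (sum(ok) < 10L) abort("need at least 10 samples with survival data")
  if (sum(os_event[ok]) == 0L) abort("no events observed")
  tt <- os_time[ok]; ee <- os_event[ok]
  srv <- survival::Surv(tt, ee)
  rows <- lapply(genes, function(g) {
    x <- X[g, ok]
    if (sd(x) == 0) {
      return(tibble::tibble(gene_id = g, cox_p = NA_real_,
                            logrank_p = NA_real_, candidate = FALSE))
    }
    fit <- survival::coxph(srv ~ x)
    cox_p <- summary(fit)$sctest["pvalue"]
    grp <- ifelse(x > median(x), "high", "low")
    lr_p <- if (length(unique(grp)) == 2L) {
      logrank_test(tt, ee, grp)$p_value
    } else NA_real_
    tibble::tibble(gene_id = g, cox_p = unname(cox_p), logrank_p = lr_p,
                   candidate = !is.na(cox_p) & !is.na(lr_p) &
                     cox_p < alpha & lr_p < alpha)
  })
  dplyr::bind_rows(rows)
}

#' Multivariate Cox risk model for a triplet
#'
#' Fits a multivariate proportional-hazards model (Breslow ties) on the
#' triplet genes and assigns each sample the linear risk score
#' `Risk = sum_j beta_j * exp_j`. Samples are split into high/low risk at
#' the median (exact-median samples go to the low group) and compared by
#' log-rank.
#'
#' @param expr Log2 expression table (tumor samples).
#' @param os_time,os_event Survival data aligned to the samples.
#' @param genes The triplet's gene IDs (typically lncRNA, immune gene,
#'   ICP).
#' @return An `icp_risk_model`: list with `betas` (tibble gene, beta),
#'   `samples` (sample_id, risk, group), `logrank` (chi2, p), `degenerate`
#'   flag, and the underlying `coxph` fit.
#' @export
fit_risk_model <- function(expr, os_time, os_event, genes) {
  X <- expr_values(expr)
  missing <- setdiff(genes, rownames(X))
  if (length(missing) > 0L) {
    abort(paste0("gene(s) absent from expression: ",
                 paste(missing, collapse = ", ")))
  }
  M <- t(X[genes, , drop = FALSE])
  df <- data.frame(M, check.names = FALSE)
  fit <- survival::coxph(survival::Surv(os_time, os_event) ~ .,
                         data = df, ties = "breslow")
  betas <- stats::coef(fit)
  risk_score(expr, setNames(as.numeric(betas), genes),
             os_time = os_time, os_event = os_event, fit = fit)
}

#' Risk scores and median split from fixed coefficients
#'
#' @param expr Log2 expression table.
#' @param betas Named numeric vector of Cox coefficients (names are gene
#'   IDs present in `expr`).
#' @param os_time,os_event Optional survival data for the log-rank
#'   comparison of the two risk groups.
#' @param fit Optional fitted `coxph` object to store.
#' @return An `icp_risk_model` (see [fit_risk_model()]).
#' @export
risk_score <- function(expr, betas, os_time = NULL, os_event = NULL,
                       fit = NULL) {
  X <- expr_values(expr)
  genes <- names(betas)
  missing <- setdiff(genes, rownames(X))
  if (length(missing) > 0L) {
    abort(paste0("gene(s) absent from expression: ",
                 paste(missing, collapse = ", ")))
  }
  risk <- as.numeric(crossprod(X[genes, , drop = FALSE], betas))
  med <- median(risk)
  group <- ifelse(risk > med, "high", "low")
  degenerate <- length(unique(group)) < 2L
  if (degenerate) warn("degenerate risk split: all samples in one group")
  lr <- NULL
  if (!is.null(os_time) && !degenerate) {
    lr <- logrank_test(os_time, os_event, group)
  }
  structure(list(
    betas = tibble::tibble(gene = genes, beta = as.numeric(betas)),
    samples = tibble::tibble(sample_id = colnames(X), risk = risk,
                             group = group,
                             os_time = os_time %||% NA_real_,
                             os_event = os_event %||% NA_real_),
    logrank = lr, degenerate = degenerate, fit = fit
  ), class = "icp_risk_model")
}

#' @export
print.icp_risk_model <- function(x, ...) {
  cat("Cox risk model over", nrow(x$betas), "genes;",
      sum(x$samples$group == "high"), "high /",
      sum(x$samples$group == "low"), "low risk samples\n")
  if (!is.null(x$logrank)) {
    cat(sprintf("log-rank chi2 = %.3f, p = %.3g\n",
                x$logrank$chi2, x$logrank$p_value))
  }
  invisible(x)
}
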