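#' Two-group differential expression with permutation calibration
#'
#' The base test is a two-group linear-model t-statistic with empirical-Bayes
#' variance moderation (the limma approach); raw p-values are then calibrated
#' against B sample-label permutations, so the evidence scale is comparable
#' across cohorts of very different size, and finally corrected by
#' Benjamini-Hochberg. Genes with FDR below the cutoff (default 0.01) enter
#' the downstream network stage.
#'
#' @name diffexpr
NULL

# Vectorized two-group t statistics on a log2 matrix. Returns one row per
# gene. Moderation shrinks per-gene variances toward a common prior via
# limma::squeezeVar; with moderation = FALSE the statistic is the classical
# equal-variance two-sample t.
de_stats <- function(X, grp, moderation = TRUE, var_floor = 1e-8) {
  tum <- grp == "tumor"
  n1 <- sum(tum); n0 <- sum(!tum)
  if (n1 < 2L || n0 < 2L) abort("each group needs at least 2 samples")
  m1 <- rowMeans(X[, tum, drop = FALSE])
  m0 <- rowMeans(X[, !tum, drop = FALSE])
  ss1 <- rowSums((X[, tum, drop = FALSE] - m1)^2)
  ss0 <- rowSums((X[, !tum, drop = FALSE] - m0)^2)
  df <- n1 + n0 - 2L
  s2 <- (ss1 + ss0) / df
  if (any(s2 < var_floor)) {
    warn(paste0(sum(s2 < var_floor),
                " gene(s) with (near-)zero pooled variance: variance floored"))
    s2 <- pmax(s2, var_floor)
  }
  if (moderation) {
    sq <- limma::squeezeVar(s2, df = df)
    s2post <- sq$var.post
    df_tot <- df + sq$df.prior
  } else {
    s2post <- s2
    df_tot <- df
  }
  se <- sqrt(s2post * (1 / n1 + 1 / n0))
  tstat <- (m1 - m0) / se
  if (!is.finite(df_tot)) df_tot <- .Machine$double.xmax
  p <- 2 * pt(abs(tstat), df = df_tot, lower.tail = FALSE)
  list(log_fc = m1 - m0, t = tstat, p = p)
}

#' Moderated two-group differential expression
#'
#' @param expr A log2-scale expression table (see [as_expr()]).
#' @param meta Sample metadata with `group` in `{tumor, normal}`.
#' @param moderation Apply empirical-Bayes variance moderation (default
#'   TRUE). `FALSE` gives the classical two-sample t.
#' @param var_floor Lower bound on the pooled variance.
#' @return A tibble with columns `gene_id`, `log_fc` (tumor minus normal on
#'   the log2 scale), `t_stat`, `p_raw`; `p_perm` and `fdr` are filled by
#'   [permutation_adjust()].
#' @export
differential_expression <- function(expr, meta, moderation = TRUE,
                                    var_floor = 1e-8) {
  if (!is_log2(expr)) abort("run log2_transform() before differential expression")
  al <- align_samples(expr, meta)
  X <- expr_values(al$expr)
  st <- de_stats(X, al$meta$group, moderation = moderation, var_floor = var_floor)
  tibble::tibble(gene_id = rownames(X), log_fc = unname(st$log_fc),
                 t_stat = unname(st$t), p_raw = unname(st$p),
                 p_perm = NA_real_, fdr = NA_real_)
}

#' Permutation-calibrated p-values
#'
#' Sample labels are randomly re-assigned B times (group sizes preserved);
#' the whole differential-expression test is re-run on each relabeling, and
#' each gene's calibrated p-value is the fraction of permutations whose
#' p-value is at most the observed one, with a +1 pseudocount so p_perm is
#' never zero: `p_perm = (1 + #\{p_b <= p_obs\}) / (B + 1)`. One label
#' shuffle re-scores all genes, so permutations are shared across genes.
#'
#' @param expr Log2 expression table used for the observed test.
#' @param meta Matching metadata.
#' @param observed Result of [differential_expression()] on the same data.
#' @param B Number of permutations (default 1000).
#' @param seed Mandatory RNG seed.
#' @inheritParams differential_expression
#' @return `observed` with `p_perm` and `fdr` (BH over p_perm) filled in.
#' @export
permutation_adjust <- function(expr, meta, observed, B = 1000L, seed,
                               moderation = TRUE, var_floor = 1e-8) {
  check_seed(seed)
  if (B < 1L) abort("B must be >= 1")
  al <- align_samples(expr, meta)
  X <- expr_values(al$expr)
  if (!identical(rownames(X), observed$gene_id)) {
    abort("`observed` must come from differential_expression on the same matrix")
  }
  grp <- al$meta$group
  count <- numeric(nrow(X))
  set.seed(seed)
  for (b in seq_len(B)) {
    st <- de_stats(X, sample(grp), moderation = moderation,
                   var_floor = var_floor)
    count <- count + (st$p <= observed$p_raw)
  }
  observed$p_perm <- unname((1 + count) / (B + 1))
  observed$fdr <- bh_fdr(observed$p_perm)
  observed
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvals Numeric p-values in \[0,1\]; NA/NaN is an error.
#' @return Monotone BH q-values, order-preserving.
#' @export
bh_fdr <- function(pvals) {
  if (anyNA(pvals)) abort("NA/NaN p-values are not allowed in bh_fdr")
  if (any(pvals < 0 | pvals > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Select differentially expressed genes at an FDR cutoff
#'
#' @param results Differential-expression tibble with `fdr` populated.
#' @param catalog Optional gene catalog; when given, the output carries a
#'   `role` column and only cataloged genes are returned.
#' @param fdr_cut Strict upper bound on FDR (default 0.01).
#' @return Tibble of selected genes (`gene_id`, optional `role`, `fdr`).
#' @export
select_de_genes <- function(results, catalog = NULL, fdr_cut = 0.01) {
  if (anyNA(results$fdr)) abort("fdr not populated; run permutation_adjust()")
  out <- dplyr::filter(results, .data$fdr < fdr_cut)
  if (!is.null(catalog)) {
    out <- dplyr::inner_join(out, catalog, by = "gene_id")
    out <- dplyr::relocate(out, "role", .after = "gene_id")
  }
  out
}
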