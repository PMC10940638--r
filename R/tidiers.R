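# broom-style tidiers for the package's fitted objects.

#' @export
tidy.icp_pattern_call <- function(x, ...) x$fits

#' @export
glance.icp_pattern_call <- function(x, ...) {
  tibble::tibble(best = x$best, ambiguous = x$ambiguous,
                 top_weight = max(x$fits$weight),
                 min_aic = min(x$fits$aic))
}

#' @export
tidy.icp_risk_model <- function(x, ...) {
  tibble::tibble(term = x$betas$gene, estimate = x$betas$beta)
}

#' @export
glance.icp_risk_model <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$samples),
    n_events = sum(x$samples$os_event, na.rm = TRUE),
    logrank_chi2 = if (!is.null(x$logrank)) x$logrank$chi2 else NA_real_,
    logrank_p = if (!is.null(x$logrank)) x$logrank$p_value else NA_real_,
    degenerate = x$degenerate
  )
}

#' @export
tidy.icp_triplet_scores <- function(x, ...) x$pairs

#' @export
glance.icp_triplet_scores <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_lncRNA = length(unique(x$pairs$lncRNA)),
    n_icp = length(unique(x$pairs$icp)),
    n_significant = if ("fdr" %in% names(x$pairs))
      sum(x$pairs$fdr < 0.01) else NA_integer_,
    purity_adjusted = x$purity_adjusted %||% NA
  )
}
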