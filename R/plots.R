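#' Visualisations
#'
#' ggplot2 views of the main result types: a volcano plot of the
#' calibrated differential expression, pattern proportion bars, PageRank
#' influence, Akaike-weight bars for a single call and Kaplan-Meier curves
#' for a risk model.
#'
#' @name plots
NULL

#' Volcano plot of calibrated differential expression
#'
#' @param de Result of [permutation_adjust()].
#' @param fdr_cut Highlight genes below this FDR (default 0.01).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, fdr_cut = 0.01) {
  de <- dplyr::mutate(de, selected = .data$fdr < fdr_cut)
  ggplot2::ggplot(de, ggplot2::aes(.data$log_fc, -log10(.data$p_perm),
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "log2 fold change (tumor - normal)",
                  y = "-log10 permutation p",
                  colour = paste0("FDR < ", fdr_cut)) +
    ggplot2::theme_minimal()
}

#' Stacked bars of regulatory pattern proportions per cancer
#'
#' @param calls Pattern-call table (needs `cancer_type`, `pattern`).
#' @return A ggplot object.
#' @export
plot_pattern_proportions <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(.data$cancer_type,
                                      fill = .data$pattern)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::labs(x = NULL, y = "proportion of calls", fill = "pattern") +
    ggplot2::theme_minimal()
}

#' Propagation influence of the top genes
#'
#' @param prop Result of [personalized_pagerank()].
#' @param top_n Genes shown (default 20).
#' @return A ggplot object.
#' @export
plot_influence <- function(prop, top_n = 20L) {
  top <- head(dplyr::arrange(prop, dplyr::desc(.data$influence)), top_n)
  top$gene_id <- factor(top$gene_id, rev(top$gene_id))
  p <- ggplot2::ggplot(top, ggplot2::aes(.data$influence, .data$gene_id))
  if ("role" %in% names(top)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$role))
  } else {
    p <- p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = "PageRank influence", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.icp_pattern_call <- function(object, ...) {
  f <- object$fits
  ggplot2::ggplot(f, ggplot2::aes(.data$pattern, .data$weight)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(y = "Akaike weight",
                  title = paste0("best pattern: ", object$best,
                                 if (object$ambiguous) " (ambiguous)" else "")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.icp_risk_model <- function(object, ...) {
  s <- object$samples
  if (all(is.na(s$os_time))) abort("risk model carries no survival data")
  sf <- survival::survfit(survival::Surv(os_time, os_event) ~ group,
                          data = s)
  km <- tibble::tibble(
    time = sf$time, surv = sf$surv,
    group = rep(sub("group=", "", names(sf$strata)), sf$strata)
  )
  km <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1, group = unique(km$group)), km)
  lab <- if (!is.null(object$logrank)) {
    sprintf("log-rank p = %.3g", object$logrank$p_value)
  } else NULL
  ggplot2::ggplot(km, ggplot2::aes(.data$time, .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "survival probability",
                  colour = "risk group", subtitle = lab) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
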