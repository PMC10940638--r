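#' Preranked gene-set enrichment
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment of a gene set in a
#' ranked gene list (max-deviation convention), with a gene-label
#' permutation p-value.
#'
#' @name gsea
NULL

# Core running-sum walk. `score_sorted` are ranking scores in list order
# (descending), `inset` a logical membership vector in the same order.
# Returns the signed ES at the maximum absolute deviation, its position and
# the full deviation profile.
es_walk <- function(score_sorted, inset, weight_exponent = 1) {
  n <- length(score_sorted)
  nh <- sum(inset)
  w <- abs(score_sorted)^weight_exponent
  wh <- w * inset
  tot <- sum(wh)
  if (tot == 0) { # all in-set ranking scores are zero: fall back to equal steps
    wh <- as.numeric(inset)
    tot <- nh
  }
  p_hit <- cumsum(wh) / tot
  p_miss <- cumsum(1 - inset) / (n - nh)
  dev <- unname(p_hit - p_miss)
  # first position attaining the maximum deviation, with a small tolerance
  # so exact rational ties are broken deterministically
  pos <- which(abs(dev) >= max(abs(dev)) - 1e-12)[1]
  list(es = dev[pos], pos = pos, dev = dev)
}

#' Preranked GSEA for one gene set
#'
#' @param scores Named numeric vector of ranking scores (no duplicate
#'   names). Genes are walked in decreasing score order, ties broken by
#'   gene name so results are deterministic.
#' @param gene_set Character vector of member genes.
#' @param weight_exponent Exponent on |score| in the hit increments
#'   (default 1; 0 gives the classic unweighted KS statistic).
#' @param B Number of gene-label permutations for the p-value (default
#'   1000).
#' @param seed RNG seed for the permutations.
#' @return A list with `es` (in \[-1,1\]), `p_value` (two-sided on |ES|,
#'   floored at 1/(B+1)), `leading_edge` (set members at or before the ES
#'   extremum for positive ES, at or after it for negative ES) and
#'   `n_set` (members in the universe).
#' @export
gsea_preranked <- function(scores, gene_set, weight_exponent = 1,
                           B = 1000L, seed = 1L) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    abort("`scores` must be uniquely named by gene")
  }
  genes <- names(scores)
  members <- intersect(gene_set, genes)
  if (length(members) == 0L) abort("gene set does not intersect the ranked universe")
  if (length(members) == length(genes)) {
    abort("gene set equals the ranked universe; the complement is empty")
  }
  ord <- order(-scores, genes)
  s <- scores[ord]
  inset <- genes[ord] %in% members
  obs <- es_walk(s, inset, weight_exponent)
  n <- length(s); nh <- sum(inset)
  set.seed(seed)
  count <- 0L
  for (b in seq_len(B)) {
    ib <- logical(n)
    ib[sample.int(n, nh)] <- TRUE
    count <- count + (abs(es_walk(s, ib, weight_exponent)$es) >= abs(obs$es))
  }
  le_idx <- if (obs$es >= 0) seq_len(obs$pos) else obs$pos:n
  leading <- genes[ord][le_idx]
  leading <- leading[leading %in% members]
  list(es = obs$es, p_value = (1 + count) / (B + 1),
       leading_edge = leading, n_set = nh)
}

# Run GSEA for a whole pathway collection against one ranking. Pathways
# with empty intersection or covering the full universe are skipped.
# Returns a tibble with one row per scored pathway plus the permutation
# |ES| critical value at `p_cut` (reused as the enrichment rule inside
# sample-label permutation re-runs, where an inner gene-label permutation
# per pathway would be prohibitive and the gene-label null does not depend
# on the sample relabeling).
gsea_collection <- function(scores, pathways, weight_exponent = 1,
                            B = 1000L, seed = 1L, p_cut = 0.05) {
  genes <- names(scores)
  rows <- vector("list", length(pathways))
  set.seed(seed)
  ord <- order(-scores, genes)
  s <- scores[ord]
  g_ord <- genes[ord]
  n <- length(s)
  for (i in seq_along(pathways)) {
    members <- intersect(pathways[[i]], genes)
    nh <- length(members)
    if (nh == 0L || nh == n) next
    inset <- g_ord %in% members
    obs <- es_walk(s, inset, weight_exponent)
    null_abs <- numeric(B)
    for (b in seq_len(B)) {
      ib <- logical(n)
      ib[sample.int(n, nh)] <- TRUE
      null_abs[b] <- abs(es_walk(s, ib, weight_exponent)$es)
    }
    p <- (1 + sum(null_abs >= abs(obs$es))) / (B + 1)
    crit <- quantile(null_abs, probs = 1 - p_cut, type = 1, names = FALSE)
    le_idx <- if (obs$es >= 0) seq_len(obs$pos) else obs$pos:n
    leading <- g_ord[le_idx]
    leading <- leading[leading %in% members]
    rows[[i]] <- tibble::tibble(
      pathway = names(pathways)[i], es = obs$es, p_value = p,
      n_set = nh, es_crit = crit, leading_edge = list(leading)
    )
  }
  dplyr::bind_rows(rows)
}

#' Single-sample GSEA scores
#'
#' For each sample, genes are ranked by expression and a rank-weighted KS
#' statistic is integrated over the full list: the cumulative, weight^
#' `exponent`-weighted in-set ECDF minus the unweighted out-of-set ECDF,
#' summed over all positions. Raw scores are normalized by the score range
#' across the samples of the run. Being rank-based, the score is invariant
#' to any monotone transform of a sample's values.
#'
#' @param expr Expression table (any scale; only within-sample ranks are
#'   used).
#' @param gene_set Character vector of member genes; must intersect but not
#'   equal the gene universe.
#' @param exponent Rank weight exponent (default 0.25).
#' @param normalize Divide by the max-min score range of the run (default
#'   TRUE).
#' @return Tibble `sample_id`, `score`.
#' @export
ssgsea <- function(expr, gene_set, exponent = 0.25, normalize = TRUE) {
  X <- expr_values(expr)
  genes <- rownames(X)
  members <- intersect(gene_set, genes)
  if (length(members) == 0L) abort("gene set does not intersect the expression genes")
  if (length(members) == length(genes)) abort("gene set equals the gene universe")
  n <- length(genes)
  raw <- vapply(seq_len(ncol(X)), function(j) {
    r <- rank(X[, j], ties.method = "average")
    ord <- order(-r, genes)
    inset <- genes[ord] %in% members
    w <- r[ord]^exponent * inset
    p_hit <- cumsum(w) / sum(w)
    p_miss <- cumsum(1 - inset) / (n - length(members))
    sum(p_hit - p_miss)
  }, numeric(1))
  score <- raw
  if (normalize) {
    rng <- diff(range(raw))
    if (rng > 0) score <- raw / rng
  }
  tibble::tibble(sample_id = colnames(X), score = score)
}
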