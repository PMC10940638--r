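#' Triplet scoring: purity-adjusted partial correlation, enrichment, S score
#'
#' Candidate (lncRNA, ICP) pairs are scored through the immune genes they
#' may regulate. Associations are measured by first-order partial
#' correlation with tumor purity as the covariate, immune genes are ranked
#' per lncRNA by signed -log10 partial-correlation p, pathways enriched in
#' that ranking contribute their leading-edge genes, and each pair's S
#' score sums the signed evidence of those genes weighted by pathway
#' enrichment. Significance comes from sample-label permutations of the
#' lncRNA/ICP profiles with BH correction across pairs.
#'
#' @name triplet_scoring
NULL

#' First-order partial correlation with a single covariate
#'
#' `pcor(x, y | c) = (r_xy - r_xc * r_yc) / sqrt((1 - r_xc^2) (1 - r_yc^2))`,
#' with a two-sided p-value from the t distribution on n - 3 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 4).
#' @param covariate Numeric covariate (tumor purity), non-constant.
#' @return One-row tibble: `r` (the partial correlation), `r_xy`, `r_xc`,
#'   `r_yc` (the raw Pearson components), `p_value`, `n`.
#' @export
partial_correlation <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n) abort("inputs must have equal length")
  if (n < 4L) abort("need at least 4 observations")
  if (sd(covariate) == 0) abort("covariate is constant; partial correlation undefined")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input vector")
  r_xy <- cor(x, y); r_xc <- cor(x, covariate); r_yc <- cor(y, covariate)
  if (abs(r_xc) >= 1 - 1e-12 || abs(r_yc) >= 1 - 1e-12) {
    which_bad <- if (abs(r_xc) >= 1 - 1e-12) "x" else "y"
    abort(paste0("|cor(", which_bad,
                 ", covariate)| = 1; partial correlation undefined"))
  }
  r <- (r_xy - r_xc * r_yc) / (sqrt(1 - r_xc^2) * sqrt(1 - r_yc^2))
  r <- max(-1, min(1, r))
  df <- n - 3L
  p <- if (abs(r) >= 1) 0 else 2 * pt(abs(r) * sqrt(df / (1 - r^2)), df,
                                      lower.tail = FALSE)
  tibble::tibble(r = r, r_xy = r_xy, r_xc = r_xc, r_yc = r_yc,
                 p_value = p, n = n)
}

# Vectorized partial correlations of every row of Za with every row of Zb
# given the covariate (all inputs pre-z-scored rows / vector). With zc =
# NULL a plain Pearson correlation is returned (df = n - 2). Degenerate
# denominators yield NA.
pcor_rows <- function(Za, Zb, zc, n) {
  clamp <- function(m) { m[m > 1] <- 1; m[m < -1] <- -1; m }
  r_ab <- tcrossprod(Za, Zb) / (n - 1)
  if (is.null(zc)) {
    r <- clamp(r_ab)
    df <- n - 2L
  } else {
    r_ac <- as.numeric(Za %*% zc) / (n - 1)
    r_bc <- as.numeric(Zb %*% zc) / (n - 1)
    den <- outer(sqrt(pmax(0, 1 - r_ac^2)), sqrt(pmax(0, 1 - r_bc^2)))
    r <- (r_ab - outer(r_ac, r_bc)) / den
    r[den < 1e-12] <- NA_real_
    r <- clamp(r)
    df <- n - 3L
  }
  tt <- abs(r) * sqrt(df / pmax(1e-300, 1 - r^2))
  p <- 2 * pt(tt, df, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  list(r = r, p = p, df = df)
}

#' Rank immune genes by association with a lncRNA
#'
#' Immune genes are scored by `sign(cor) * (-log10 p)` of their
#' purity-adjusted partial correlation with the lncRNA and returned in
#' decreasing score order (ties broken by gene ID).
#'
#' @param expr Log2 expression table containing the lncRNA and the immune
#'   genes (tumor samples).
#' @param lnc_gene The lncRNA gene ID.
#' @param immune_genes Character vector (>= 2) of immune gene IDs.
#' @param purity Tumor purity per sample, aligned to the expression
#'   columns; `NULL` falls back to plain Pearson correlation.
#' @param p_floor Lower bound applied to p-values before -log10 (default
#'   1/1001, the granularity of a 1000-permutation test).
#' @return Tibble `gene_id`, `r`, `p_value`, `score`, ordered by
#'   decreasing score.
#' @export
rank_immune_genes <- function(expr, lnc_gene, immune_genes, purity = NULL,
                              p_floor = 1 / 1001) {
  X <- expr_values(expr)
  if (!lnc_gene %in% rownames(X)) abort("lncRNA not found in expression")
  immune_genes <- intersect(immune_genes, rownames(X))
  if (length(immune_genes) < 2L) abort("need at least 2 immune genes present")
  n <- ncol(X)
  Zl <- zscore_rows(X[lnc_gene, , drop = FALSE])
  Zm <- zscore_rows(X[immune_genes, , drop = FALSE])
  zc <- if (is.null(purity)) NULL else as.numeric(scale(purity))
  pc <- pcor_rows(Zl, Zm, zc, n)
  p <- floor_p(as.numeric(pc$p), 1 / p_floor - 1)
  out <- tibble::tibble(
    gene_id = immune_genes, r = as.numeric(pc$r), p_value = p,
    score = sign(as.numeric(pc$r)) * (-log10(p))
  )
  dplyr::arrange(out, dplyr::desc(.data$score), .data$gene_id)
}

#' S score of a (lncRNA, ICP) pair
#'
#' `S = sum_i w_i * ((-log10 P1_i) * sign(cor1_i) + (-log10 P2_i) *
#' sign(cor2_i))` over the pair's mediating immune genes, where `w_i` is
#' the pathway enrichment score of immune gene i, `P1_i`/`cor1_i` come
#' from the lncRNA-immune partial correlation and `P2_i`/`cor2_i` from the
#' ICP-immune partial correlation.
#'
#' @param contributions Data frame with columns `w`, `p1`, `cor1`, `p2`,
#'   `cor2`; zero rows give S = 0.
#' @return The S score (a single real number).
#' @export
s_score <- function(contributions) {
  if (nrow(contributions) == 0L) return(0)
  req <- c("w", "p1", "cor1", "p2", "cor2")
  if (!all(req %in% names(contributions))) {
    abort(paste0("contributions need columns: ", paste(req, collapse = ", ")))
  }
  with(contributions, {
    if (any(p1 <= 0) || any(p2 <= 0)) {
      abort("p-values must be > 0; floor them upstream at 1/(B+1)")
    }
    if (any(p1 > 1) || any(p2 > 1)) abort("p-values must be <= 1")
    sum(w * ((-log10(p1)) * sign(cor1) + (-log10(p2)) * sign(cor2)))
  })
}

# Re-derive retained immune genes and weights for one ranking, reusing
# per-pathway |ES| critical values (used inside permutation re-runs).
build_weights <- function(scores, pathways, crit_row, weight_exponent) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  g_ord <- names(scores)[ord]
  n <- length(s)
  w_out <- numeric(0)
  for (i in seq_along(pathways)) {
    crit <- crit_row[[i]]
    if (is.na(crit)) next
    inset <- g_ord %in% pathways[[i]]
    nh <- sum(inset)
    if (nh == 0L || nh == n) next
    walk <- es_walk(s, inset, weight_exponent)
    if (abs(walk$es) < crit) next
    le_idx <- if (walk$es >= 0) seq_len(walk$pos) else walk$pos:n
    le <- g_ord[le_idx][inset[le_idx]]
    # per-gene weight: ES of the largest-|ES| enriched pathway containing it
    for (g in le) {
      if (!(g %in% names(w_out)) || abs(walk$es) > abs(w_out[[g]])) {
        w_out[[g]] <- walk$es
      }
    }
  }
  w_out
}

#' Score all (lncRNA, ICP) pairs through their immune mediators
#'
#' The observed stage of triplet scoring. Candidate pairs must first pass
#' the PCC(ij) screen: the purity-adjusted partial correlation between the
#' lncRNA and the ICP gene itself must be significant at BH FDR below
#' `pair_fdr`, which removes pairs associated only through tumor purity. Immune genes
#' are then ranked per pair by combined signed evidence — the
#' lncRNA-immune term plus the ICP-immune term, each
#' `sign(cor) * (-log10 p)` of the purity-adjusted partial correlation —
#' and preranked GSEA against the immune pathway collection retains the
#' leading-edge genes of pathways enriched at `gsea_p_cut`, weighted by
#' the largest-|ES| enriched pathway containing them. The pair's S score
#' sums the weighted evidence of the retained genes. Pairs with no
#' retained immune genes are dropped with a message. Follow with
#' [triplet_permutation_fdr()] and [assemble_triplets()].
#'
#' @param expr Log2 expression table of tumor samples.
#' @param catalog Gene catalog (roles).
#' @param pathways Named list of immune pathway gene sets.
#' @param purity Tumor purity aligned to the samples; `NULL` uses plain
#'   Pearson correlations and flags the result.
#' @param lnc_genes,immune_genes,icp_genes Candidate genes per role;
#'   defaults to all cataloged genes of the role present in `expr`.
#' @param pairs Optional tibble (`lncRNA`, `icp`) restricting which pairs
#'   are scored (e.g. pairs supported by a co-expression edge); defaults
#'   to all lncRNA x ICP combinations.
#' @param B Permutations for the GSEA p-values and the p-value floor.
#' @param seed Mandatory RNG seed.
#' @param gsea_p_cut Pathway enrichment significance cutoff (default 0.05).
#' @param pair_fdr BH FDR cutoff on the lncRNA-ICP partial-correlation
#'   p-values for pair candidacy (default 0.01).
#' @param weight_exponent GSEA weight exponent (default 1).
#' @return An `icp_triplet_scores` object: list with the pair table
#'   (`pairs`, including `r_lc`/`p_lc` from the PCC(ij) screen), per-pair
#'   enrichment results (`enrichment`), the retained weight matrix and
#'   the state needed for permutation testing.
#' @export
score_triplets <- function(expr, catalog, pathways, purity = NULL,
                           lnc_genes = NULL, immune_genes = NULL,
                           icp_genes = NULL, pairs = NULL, B = 1000L, seed,
                           gsea_p_cut = 0.05, pair_fdr = 0.01,
                           weight_exponent = 1) {
  check_seed(seed)
  X <- expr_values(expr)
  in_expr <- function(g) intersect(g, rownames(X))
  if (!is.null(pairs)) {
    lnc_genes <- lnc_genes %||% unique(pairs$lncRNA)
    icp_genes <- icp_genes %||% unique(pairs$icp)
  }
  lnc_genes <- in_expr(lnc_genes %||% catalog$gene_id[catalog$role == "lncRNA"])
  immune_genes <- in_expr(immune_genes %||% catalog$gene_id[catalog$role == "immune"])
  icp_genes <- in_expr(icp_genes %||% catalog$gene_id[catalog$role == "ICP"])
  if (length(lnc_genes) == 0L || length(icp_genes) == 0L) {
    abort("need at least one candidate lncRNA and one ICP gene")
  }
  if (length(immune_genes) < 2L) abort("need at least 2 immune genes")
  n <- ncol(X)
  drop_constant <- function(g) {
    keep <- apply(X[g, , drop = FALSE], 1L, sd) > 0
    if (!all(keep)) warn(paste0("constant gene(s) dropped: ",
                                paste(g[!keep], collapse = ", ")))
    g[keep]
  }
  lnc_genes <- drop_constant(lnc_genes)
  immune_genes <- drop_constant(immune_genes)
  icp_genes <- drop_constant(icp_genes)

  purity_adjusted <- !is.null(purity) && !all(is.na(purity)) &&
    sd(purity, na.rm = TRUE) > 0
  if (!is.null(purity) && !purity_adjusted) {
    warn("purity missing or constant: falling back to plain Pearson correlation")
  }
  zc <- if (purity_adjusted) as.numeric(scale(purity)) else NULL

  Zl <- zscore_rows(X[lnc_genes, , drop = FALSE])
  Zm <- zscore_rows(X[immune_genes, , drop = FALSE])
  Zi <- zscore_rows(X[icp_genes, , drop = FALSE])

  pc1 <- pcor_rows(Zl, Zm, zc, n)   # lncRNA x immune
  pc2 <- pcor_rows(Zi, Zm, zc, n)   # ICP x immune
  p1 <- floor_p(pc1$p, B); p2 <- floor_p(pc2$p, B)
  term1 <- sign(pc1$r) * (-log10(p1)); term1[is.na(term1)] <- 0
  term2 <- sign(pc2$r) * (-log10(p2)); term2[is.na(term2)] <- 0

  # pair candidacy: the lncRNA-ICP partial correlation itself must be
  # significant at BH FDR < pair_fdr over the candidate universe (this is
  # the PCC(ij) screen; it removes pairs associated only through purity)
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(lncRNA = lnc_genes, icp = icp_genes)
  } else {
    pairs <- dplyr::distinct(tibble::as_tibble(pairs[, c("lncRNA", "icp")]))
    pairs <- dplyr::filter(pairs, .data$lncRNA %in% lnc_genes,
                           .data$icp %in% icp_genes)
  }
  pc_lc <- pcor_rows(Zl, Zi, zc, n)
  li <- match(pairs$lncRNA, lnc_genes)
  ii <- match(pairs$icp, icp_genes)
  pairs$r_lc <- pc_lc$r[cbind(li, ii)]
  pairs$p_lc <- pc_lc$p[cbind(li, ii)]
  pairs <- dplyr::filter(pairs, !is.na(.data$p_lc))
  pairs$fdr_lc <- bh_fdr(pairs$p_lc)
  n_cand <- sum(pairs$fdr_lc < pair_fdr)
  if (n_cand < nrow(pairs)) {
    inform(paste0(nrow(pairs) - n_cand,
                  " pair(s) failed the lncRNA-ICP partial-correlation screen"))
  }
  pairs <- dplyr::filter(pairs, .data$fdr_lc < pair_fdr)
  li <- match(pairs$lncRNA, lnc_genes)
  ii <- match(pairs$icp, icp_genes)

  # per-pair enrichment: immune genes ranked by combined signed evidence
  # from the lncRNA and the ICP sides
  enr_rows <- vector("list", nrow(pairs))
  crit <- matrix(NA_real_, nrow(pairs), length(pathways),
                 dimnames = list(NULL, names(pathways)))
  wmat <- matrix(0, nrow(pairs), length(immune_genes),
                 dimnames = list(NULL, immune_genes))
  for (k in seq_len(nrow(pairs))) {
    scores <- setNames(term1[li[k], ] + term2[ii[k], ], immune_genes)
    enr <- gsea_collection(scores, pathways, weight_exponent, B = B,
                           seed = stage_seed(seed, 50L) + k,
                           p_cut = gsea_p_cut)
    if (nrow(enr) > 0L) {
      crit[k, enr$pathway] <- enr$es_crit
      enr$lncRNA <- pairs$lncRNA[k]
      enr$icp <- pairs$icp[k]
      enr_rows[[k]] <- enr
      sig <- enr[enr$p_value < gsea_p_cut, , drop = FALSE]
      if (nrow(sig) > 0L) {
        for (i in order(abs(sig$es))) { # ascending: larger |ES| overwrites
          wmat[k, sig$leading_edge[[i]]] <- sig$es[i]
        }
      }
    }
  }
  enrichment <- dplyr::bind_rows(enr_rows)
  retained <- rowSums(wmat != 0)
  if (any(retained == 0)) {
    inform(paste0(sum(retained == 0),
                  " pair(s) with no enriched immune genes dropped"))
  }
  evid <- term1[li, , drop = FALSE] + term2[ii, , drop = FALSE]
  pairs$s <- rowSums(wmat * evid)
  pairs$n_immune <- as.integer(retained)
  keep <- retained > 0L
  pairs <- pairs[keep, , drop = FALSE]
  wmat <- wmat[keep, , drop = FALSE]
  crit <- crit[keep, , drop = FALSE]
  structure(list(
    pairs = pairs, enrichment = enrichment, wmat = wmat, crit = crit,
    term1 = term1, term2 = term2, pc1 = pc1, pc2 = pc2, p1 = p1, p2 = p2,
    Zl = Zl, Zm = Zm, Zi = Zi, zc = zc, n = n,
    lnc_genes = lnc_genes, immune_genes = immune_genes,
    icp_genes = icp_genes, pathways = pathways,
    purity_adjusted = purity_adjusted,
    params = list(B = B, seed = seed, gsea_p_cut = gsea_p_cut,
                  weight_exponent = weight_exponent,
                  pair_fdr = pair_fdr)
  ), class = "icp_triplet_scores")
}

#' Permutation significance and FDR for pair S scores
#'
#' Sample labels of the lncRNA and ICP profiles are shuffled jointly B
#' times (immune genes and purity stay in place), the S pipeline is re-run
#' on each shuffle, and each pair's p-value is
#' `(1 + #\{|S_b| >= |S_obs|\}) / (B + 1)`, BH-corrected across pairs.
#'
#' @param scores An `icp_triplet_scores` object.
#' @param B Number of label permutations (default 1000).
#' @param seed Mandatory RNG seed.
#' @param mode `"full"` re-runs ranking, enrichment (against the observed
#'   gene-label critical values) and leading-edge weighting on every
#'   shuffle; `"fixed_weights"` keeps the observed immune-gene weights and
#'   re-computes only the partial-correlation evidence.
#' @return The object with `p_perm` and `fdr` columns added to `$pairs`.
#' @export
triplet_permutation_fdr <- function(scores, B = 1000L, seed,
                                    mode = c("fixed_weights", "full")) {
  check_seed(seed)
  mode <- match.arg(mode)
  if (B < 1L) abort("B must be >= 1")
  st <- scores
  n <- st$n
  pairs <- st$pairs
  if (nrow(pairs) == 0L) {
    pairs$p_perm <- numeric(0)
    pairs$fdr <- numeric(0)
    st$pairs <- pairs
    return(st)
  }
  li <- match(pairs$lncRNA, st$lnc_genes)
  ii <- match(pairs$icp, st$icp_genes)
  s_obs <- abs(pairs$s)
  count <- numeric(nrow(pairs))
  wexp <- st$params$weight_exponent
  set.seed(seed)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    pc1b <- pcor_rows(st$Zl[, perm, drop = FALSE], st$Zm, st$zc, n)
    pc2b <- pcor_rows(st$Zi[, perm, drop = FALSE], st$Zm, st$zc, n)
    t1b <- sign(pc1b$r) * (-log10(floor_p(pc1b$p, B)))
    t2b <- sign(pc2b$r) * (-log10(floor_p(pc2b$p, B)))
    t1b[is.na(t1b)] <- 0; t2b[is.na(t2b)] <- 0
    evid_b <- t1b[li, , drop = FALSE] + t2b[ii, , drop = FALSE]
    if (mode == "fixed_weights") {
      wb <- st$wmat
    } else {
      wb <- matrix(0, nrow(st$wmat), ncol(st$wmat),
                   dimnames = dimnames(st$wmat))
      for (k in seq_len(nrow(pairs))) {
        wk <- build_weights(setNames(evid_b[k, ], st$immune_genes),
                            st$pathways, st$crit[k, ], wexp)
        if (length(wk) > 0L) wb[k, names(wk)] <- wk
      }
    }
    Sb <- rowSums(wb * evid_b)
    count <- count + (abs(Sb) >= s_obs)
  }
  pairs$p_perm <- (1 + count) / (B + 1)
  pairs$fdr <- bh_fdr(pairs$p_perm)
  st$pairs <- pairs
  st$params$B_perm <- B
  st$params$perm_mode <- mode
  st
}

#' Assemble ICP-LncCRCT triplets from scored pairs
#'
#' Pairs below the FDR cutoff are expanded into one row per mediating
#' immune gene, carrying the pathway weight and both partial-correlation
#' components.
#'
#' @param scores An `icp_triplet_scores` object with permutation FDR
#'   computed.
#' @param fdr_cut Strict FDR cutoff (default 0.01).
#' @param cancer_type Label stamped on the output rows.
#' @return Tibble with columns `cancer_type`, `lncRNA`, `icp`,
#'   `immune_gene`, `w`, `p1`, `cor1`, `p2`, `cor2`, `n_immune`, `s`,
#'   `p_perm`, `fdr`, one row per (pair, immune gene) contribution.
#' @export
assemble_triplets <- function(scores, fdr_cut = 0.01, cancer_type = "NA") {
  if (!"fdr" %in% names(scores$pairs)) {
    abort("run triplet_permutation_fdr() before assembling triplets")
  }
  keep_idx <- which(scores$pairs$fdr < fdr_cut)
  if (length(keep_idx) == 0L) {
    return(tibble::tibble(
      cancer_type = character(), lncRNA = character(), icp = character(),
      immune_gene = character(), w = numeric(), p1 = numeric(),
      cor1 = numeric(), p2 = numeric(), cor2 = numeric(),
      n_immune = integer(), s = numeric(), p_perm = numeric(),
      fdr = numeric()
    ))
  }
  rows <- lapply(keep_idx, function(k) {
    pr <- scores$pairs[k, ]
    genes <- colnames(scores$wmat)[scores$wmat[k, ] != 0]
    mi <- match(genes, scores$immune_genes)
    l_i <- match(pr$lncRNA, scores$lnc_genes)
    c_i <- match(pr$icp, scores$icp_genes)
    tibble::tibble(
      cancer_type = cancer_type, lncRNA = pr$lncRNA, icp = pr$icp,
      immune_gene = genes,
      w = scores$wmat[k, genes],
      p1 = scores$p1[l_i, mi], cor1 = scores$pc1$r[l_i, mi],
      p2 = scores$p2[c_i, mi], cor2 = scores$pc2$r[c_i, mi],
      n_immune = length(genes), s = pr$s,
      p_perm = pr$p_perm, fdr = pr$fdr
    )
  })
  dplyr::bind_rows(rows)
}
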