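#' Co-expression network, mutual-information validation and propagation
#'
#' Edges are Pearson correlations between differentially expressed lncRNAs,
#' immune genes and ICP genes, kept when a sample-label permutation test
#' (BH-corrected across candidate pairs) calls them significant. Mutual
#' information provides an independent nonparametric check of the same
#' pairs. Personalized PageRank with restart mass on the ICP genes then
#' ranks every lncRNA and immune gene by network proximity to the
#' checkpoint genes.
#'
#' @name network
NULL

role_pairs_default <- rbind(
  c("lncRNA", "immune"), c("lncRNA", "ICP"), c("immune", "ICP")
)

# Candidate (i, j) index pairs for the given roles. Pairs are unordered,
# i < j in matrix row order.
candidate_pairs <- function(roles, universe = c("role", "all")) {
  universe <- match.arg(universe)
  G <- length(roles)
  idx <- which(upper.tri(matrix(0, G, G)), arr.ind = TRUE)
  if (universe == "role") {
    ra <- roles[idx[, 1]]; rb <- roles[idx[, 2]]
    key <- paste(pmin(ra, rb), pmax(ra, rb))
    ok_keys <- paste(pmin(role_pairs_default[, 1], role_pairs_default[, 2]),
                     pmax(role_pairs_default[, 1], role_pairs_default[, 2]))
    idx <- idx[key %in% ok_keys, , drop = FALSE]
  }
  idx
}

#' Permutation-tested Pearson co-expression edges
#'
#' For every candidate gene pair (lncRNA-immune, lncRNA-ICP, immune-ICP by
#' default) the Pearson r is computed, and its two-sided permutation p-value
#' comes from B sample-label shuffles of one pair member (shuffles shared
#' across pairs). Edges are retained at BH FDR below `fdr_cut`.
#'
#' @param expr Log2 expression table restricted to the genes of interest.
#' @param catalog Gene catalog giving each gene's role.
#' @param B Number of label permutations (default 1000).
#' @param seed Mandatory RNG seed.
#' @param fdr_cut BH FDR cutoff for edge retention (default 0.01).
#' @param universe `"role"` (default) restricts candidate pairs to the role
#'   combinations the triplets need; `"all"` tests every pair.
#' @return A tibble of retained edges: `gene_a`, `gene_b`, `role_a`,
#'   `role_b`, `r`, `p_perm`, `fdr`, with the node table (gene_id, role) as
#'   attribute `nodes` and the full candidate-pair test as attribute
#'   `all_pairs`.
#' @export
pearson_edges <- function(expr, catalog, B = 1000L, seed, fdr_cut = 0.01,
                          universe = c("role", "all")) {
  check_seed(seed)
  universe <- match.arg(universe)
  X <- expr_values(expr)
  X <- X[rownames(X) %in% catalog$gene_id, , drop = FALSE]
  if (ncol(X) < 3L) abort("need at least 3 samples for correlation edges")
  constant <- apply(X, 1L, function(v) sd(v) == 0)
  if (any(constant)) {
    warn(paste0("constant gene(s) dropped from network: ",
                paste(rownames(X)[constant], collapse = ", ")))
    X <- X[!constant, , drop = FALSE]
  }
  genes <- rownames(X)
  roles <- catalog$role[match(genes, catalog$gene_id)]
  n <- ncol(X)
  Z <- zscore_rows(X)
  R <- tcrossprod(Z) / (n - 1)
  idx <- candidate_pairs(roles, universe)
  if (nrow(idx) == 0L) abort("no candidate gene pairs for the given roles")
  robs <- abs(R[idx])
  count <- numeric(nrow(idx))
  set.seed(seed)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    Rb <- tcrossprod(Z, Z[, perm, drop = FALSE]) / (n - 1)
    count <- count + (abs(Rb[idx]) >= robs)
  }
  p_perm <- (1 + count) / (B + 1)
  all_pairs <- tibble::tibble(
    gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
    role_a = roles[idx[, 1]], role_b = roles[idx[, 2]],
    r = R[idx], p_perm = p_perm, fdr = bh_fdr(p_perm)
  )
  edges <- dplyr::filter(all_pairs, .data$fdr < fdr_cut)
  attr(edges, "nodes") <- tibble::tibble(gene_id = genes, role = roles)
  attr(edges, "all_pairs") <- all_pairs
  edges
}

#' Plug-in mutual information on an equal-frequency grid
#'
#' Both vectors are discretized into `bins` equal-frequency bins and the
#' plug-in (maximum-likelihood) mutual information of the contingency table
#' is returned, in nats.
#'
#' @param x,y Numeric vectors of equal length.
#' @param bins Number of bins per axis (default `ceiling(sqrt(n))`).
#' @return Non-negative mutual information in nats.
#' @export
mutual_information <- function(x, y, bins = ceiling(sqrt(length(x)))) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (bins < 2L) abort("bins must be >= 2")
  if (length(x) < bins) abort("need at least `bins` observations")
  bx <- ceiling(rank(x, ties.method = "first") * bins / length(x))
  by <- ceiling(rank(y, ties.method = "first") * bins / length(y))
  # constant input: every value shares one rank ordering but spreads over
  # bins by ties.method = "first", which would fabricate structure, so map
  # constants to a single bin.
  if (sd(x) == 0) bx[] <- 1L
  if (sd(y) == 0) by[] <- 1L
  tab <- table(bx, by)
  pxy <- tab / sum(tab)
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
}

#' Mutual-information scores for candidate network pairs
#'
#' @inheritParams pearson_edges
#' @param bins Bins per axis for [mutual_information()].
#' @return Tibble `gene_a`, `gene_b`, `mi` over the same candidate universe
#'   as [pearson_edges()].
#' @export
mi_edges <- function(expr, catalog, bins = NULL,
                     universe = c("role", "all")) {
  universe <- match.arg(universe)
  X <- expr_values(expr)
  X <- X[rownames(X) %in% catalog$gene_id, , drop = FALSE]
  genes <- rownames(X)
  roles <- catalog$role[match(genes, catalog$gene_id)]
  bins <- bins %||% ceiling(sqrt(ncol(X)))
  idx <- candidate_pairs(roles, universe)
  mi <- vapply(seq_len(nrow(idx)), function(k) {
    mutual_information(X[idx[k, 1], ], X[idx[k, 2], ], bins = bins)
  }, numeric(1))
  tibble::tibble(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]], mi = mi)
}

#' Overlap of top PCC and top MI pairs
#'
#' Takes each method's top fraction of candidate pairs (by |r| and by MI)
#' and reports the shared-pair count with a hypergeometric tail p-value for
#' at least that much overlap.
#'
#' @param net_pcc Edge/pair tibble with columns `gene_a`, `gene_b`, `r`.
#' @param net_mi Pair tibble with columns `gene_a`, `gene_b`, `mi`.
#' @param top_fraction Fraction of pairs to keep per method (default 0.1).
#' @return A one-row tibble: `overlap`, `n_top_pcc`, `n_top_mi`,
#'   `universe`, `p_hyper`.
#' @export
mi_overlap_check <- function(net_pcc, net_mi, top_fraction = 0.1) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  kp <- key(net_pcc$gene_a, net_pcc$gene_b)
  km <- key(net_mi$gene_a, net_mi$gene_b)
  shared_universe <- intersect(kp, km)
  if (length(shared_universe) == 0L) {
    abort("PCC and MI pair tables share no gene pairs")
  }
  pcc <- net_pcc[kp %in% shared_universe, ]
  mi <- net_mi[km %in% shared_universe, ]
  U <- length(shared_universe)
  ntop <- ceiling(top_fraction * U)
  top_p <- key(pcc$gene_a, pcc$gene_b)[order(-abs(pcc$r))][seq_len(min(ntop, nrow(pcc)))]
  top_m <- key(mi$gene_a, mi$gene_b)[order(-mi$mi)][seq_len(min(ntop, nrow(mi)))]
  ov <- length(intersect(top_p, top_m))
  p_hyper <- stats::phyper(ov - 1L, length(top_p), U - length(top_p),
                           length(top_m), lower.tail = FALSE)
  tibble::tibble(overlap = ov, n_top_pcc = length(top_p),
                 n_top_mi = length(top_m), universe = U, p_hyper = p_hyper)
}

# Build the symmetric non-negative weight matrix used for propagation.
edge_weight_matrix <- function(edges, nodes = NULL) {
  nodes <- nodes %||% attr(edges, "nodes")$gene_id %||%
    sort(unique(c(edges$gene_a, edges$gene_b)))
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(edges) > 0L) {
    ia <- match(edges$gene_a, nodes); ib <- match(edges$gene_b, nodes)
    w <- abs(edges$r)
    W[cbind(ia, ib)] <- w
    W[cbind(ib, ia)] <- w
  }
  W
}

#' Personalized PageRank over the co-expression network
#'
#' Random walk with restart on the undirected network, edge weights |r|,
#' restart distribution uniform over `seed_genes` (the ICP genes). Dangling
#' (isolated) nodes hand their mass back to the restart distribution. Scores
#' sum to one over all nodes.
#'
#' @param edges Edge tibble from [pearson_edges()] (or any tibble with
#'   `gene_a`, `gene_b`, `r`).
#' @param seed_genes Genes receiving restart mass; must intersect the
#'   network nodes.
#' @param alpha Damping factor (default 0.85).
#' @param tol L1 convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @param catalog Optional catalog to attach roles and within-role ranks.
#' @return Tibble `gene_id`, `influence` (sums to 1), and when a catalog is
#'   given, `role` and dense `rank` within role (ties by gene ID).
#' @export
personalized_pagerank <- function(edges, seed_genes, alpha = 0.85,
                                  tol = 1e-8, max_iter = 1000L,
                                  catalog = NULL) {
  W <- edge_weight_matrix(edges)
  nodes <- rownames(W)
  seeds <- intersect(seed_genes, nodes)
  if (length(seeds) == 0L) abort("no seed gene is present in the network")
  v <- setNames(numeric(length(nodes)), nodes)
  v[seeds] <- 1 / length(seeds)
  deg <- rowSums(W)
  dangling <- deg == 0
  P <- W
  P[!dangling, ] <- W[!dangling, , drop = FALSE] / deg[!dangling]
  x <- v
  for (it in seq_len(max_iter)) {
    x_new <- alpha * (crossprod(P, x)[, 1] + sum(x[dangling]) * v) +
      (1 - alpha) * v
    delta <- sum(abs(x_new - x))
    x <- x_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    abort(paste0("PageRank did not converge in ", max_iter,
                 " iterations (residual ", signif(delta, 3), ")"))
  }
  out <- tibble::tibble(gene_id = nodes, influence = as.numeric(x))
  if (!is.null(catalog)) {
    out <- dplyr::inner_join(out, catalog, by = "gene_id")
    out <- dplyr::mutate(
      dplyr::group_by(out, .data$role),
      rank = as.integer(order(order(-.data$influence, .data$gene_id)))
    )
    out <- dplyr::ungroup(out)
  }
  dplyr::arrange(out, dplyr::desc(.data$influence), .data$gene_id)
}

#' Top-k genes of a role by propagation influence
#'
#' Ties at the boundary are broken by gene-ID lexicographic order, so the
#' selection is deterministic.
#'
#' @param prop Result of [personalized_pagerank()] (must carry `role`).
#' @param role `"lncRNA"` or `"immune"`.
#' @param k Number of genes to keep (default 200).
#' @return Character vector of at most `k` gene IDs.
#' @export
top_k_proximal <- function(prop, role, k = 200L) {
  if (!"role" %in% names(prop)) abort("propagation result lacks roles; pass a catalog")
  if (k < 0L) abort("k must be non-negative")
  sub <- dplyr::filter(prop, .data$role == !!role)
  sub <- dplyr::arrange(sub, dplyr::desc(.data$influence), .data$gene_id)
  head(sub$gene_id, k)
}

#' Unweighted shortest-path betweenness centrality
#'
#' @param edges Edge tibble (`gene_a`, `gene_b`).
#' @return Tibble `gene_id`, `betweenness` for every network node.
#' @export
node_betweenness <- function(edges) {
  nodes <- attr(edges, "nodes")$gene_id %||%
    sort(unique(c(edges$gene_a, edges$gene_b)))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  tibble::tibble(gene_id = names(b), betweenness = as.numeric(b))
}
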