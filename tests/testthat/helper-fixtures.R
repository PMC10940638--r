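# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# A tiny expression table with known values (raw scale).
tiny_expr <- function() {
  m <- matrix(c(0, 3, 7,
                1, 4, 15,
                2.5, 0, 31), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  as_expr(m)
}

# Catalog + expression for network-level tests: `k` genes per role with
# i.i.d. normal values, deterministic under `seed`.
role_expr <- function(n_lnc = 3, n_imm = 4, n_icp = 2, n = 30, seed = 1) {
  set.seed(seed)
  genes <- c(sprintf("L%02d", seq_len(n_lnc)),
             sprintf("M%02d", seq_len(n_imm)),
             sprintf("C%02d", seq_len(n_icp)))
  m <- matrix(rnorm(length(genes) * n), length(genes),
              dimnames = list(genes, sprintf("s%03d", seq_len(n))))
  list(
    expr = as_expr(m, is_log2 = TRUE),
    catalog = gene_catalog(lncRNA = genes[seq_len(n_lnc)],
                           immune = genes[n_lnc + seq_len(n_imm)],
                           icp = genes[n_lnc + n_imm + seq_len(n_icp)])
  )
}

# A reduced synthetic cohort for structural tests (acceptance tests use
# the full default configuration).
small_sim_config <- function(seed, ...) {
  sim_config(n_tumor = 40L, n_normal = 15L, n_lnc = 20L, n_immune = 80L,
             n_icp = 5L, n_background = 150L,
             planted = tibble::tibble(pattern = c("INDEP", "LGI"),
                                      a = 0.8, b = 0.8, sigma = 0.5),
             n_decoy_lnc = 2L, n_comembers = 6L, n_dropout = 10L,
             n_pathways = 10L, pathway_size = 15L, seed = seed, ...)
}

# Independent personalized-PageRank oracle: dense linear solve of
# x = alpha * (P^T x + dangling(x) v) + (1 - alpha) v, i.e.
# (I - alpha (P^T + v d^T)) x = (1 - alpha) v, with d the dangling
# indicator. Entirely separate from the package's power iteration.
pagerank_solve_oracle <- function(W, seeds, alpha = 0.85) {
  nodes <- rownames(W)
  v <- setNames(numeric(nrow(W)), nodes)
  v[seeds] <- 1 / length(seeds)
  deg <- rowSums(W)
  P <- W
  ok <- deg > 0
  P[ok, ] <- W[ok, , drop = FALSE] / deg[ok]
  d <- as.numeric(!ok)
  A <- diag(nrow(W)) - alpha * (t(P) + outer(v, d))
  x <- solve(A, (1 - alpha) * v)
  x / sum(x)
}

# Brute-force GSEA running-sum oracle (plain loop, no vectorization).
es_oracle <- function(scores, members, exponent = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  g <- names(scores)[ord]
  nh <- sum(g %in% members)
  wsum <- sum(abs(s[g %in% members])^exponent)
  phit <- 0; pmiss <- 0; best <- 0
  for (i in seq_along(g)) {
    if (g[i] %in% members) {
      phit <- phit + if (wsum > 0) abs(s[i])^exponent / wsum else 1 / nh
    } else {
      pmiss <- pmiss + 1 / (length(g) - nh)
    }
    if (abs(phit - pmiss) > abs(best) + 1e-12) best <- phit - pmiss
  }
  unname(best)
}

# Brute-force per-sample ssGSEA oracle.
ssgsea_oracle <- function(x, genes, members, exponent = 0.25) {
  r <- rank(x, ties.method = "average")
  ord <- order(-r, genes)
  tot <- 0; phit <- 0; pmiss <- 0
  wsum <- sum(r[ord][genes[ord] %in% members]^exponent)
  nm <- sum(!(genes %in% members))
  for (i in ord) {
    if (genes[i] %in% members) phit <- phit + r[i]^exponent / wsum
    else pmiss <- pmiss + 1 / nm
    tot <- tot + (phit - pmiss)
  }
  unname(tot)
}

# Exhaustive unweighted betweenness oracle over all simple shortest paths.
betweenness_oracle <- function(adj) {
  nodes <- rownames(adj)
  n <- length(nodes)
  bt <- setNames(numeric(n), nodes)
  # all-pairs BFS shortest-path enumeration
  paths_between <- function(s, t) {
    res <- list()
    queue <- list(s)
    best <- Inf
    while (length(queue) > 0) {
      path <- queue[[1]]; queue <- queue[-1]
      last <- path[length(path)]
      if (length(path) - 1 > best) next
      if (last == t) {
        if (length(path) - 1 < best) { best <- length(path) - 1; res <- list() }
        if (length(path) - 1 == best) res[[length(res) + 1]] <- path
        next
      }
      for (nb in nodes[adj[last, ] > 0]) {
        if (!(nb %in% path)) queue[[length(queue) + 1]] <- c(path, nb)
      }
    }
    res
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ps <- paths_between(nodes[i], nodes[j])
    if (length(ps) == 0) next
    for (p in ps) {
      inner <- setdiff(p, c(nodes[i], nodes[j]))
      for (v in inner) bt[v] <- bt[v] + 1 / length(ps)
    }
  }
  bt
}

# Reference BH step-up computed literally from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  # monotone enforcement: q_(i) = min_{j >= i} p_(j) m / j
  for (i in seq_len(m)) q[i] <- min(sorted[i:m], 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-group log-rank oracle from the risk-table definition.
logrank_oracle <- function(times, events, groups) {
  g <- as.integer(factor(groups))
  ts <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O1 - E1)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}
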