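test_that("pearson edges recover exact and null correlations", {
  set.seed(2)
  n <- 40
  x <- rnorm(n)
  m <- rbind(L01 = x, M01 = x, M02 = rnorm(n), C01 = rnorm(n))
  colnames(m) <- sprintf("s%03d", seq_len(n))
  cat_tbl <- gene_catalog(lncRNA = "L01", immune = c("M01", "M02"),
                          icp = "C01")
  edges <- pearson_edges(as_expr(m, is_log2 = TRUE), cat_tbl, B = 200,
                         seed = 3, fdr_cut = 0.05)
  ap <- attr(edges, "all_pairs")
  # y = x exactly -> r = 1
  e1 <- ap[ap$gene_a == "L01" & ap$gene_b == "M01", ]
  expect_equal(e1$r, 1, tolerance = 1e-12)
  expect_true(paste("L01", "M01") %in% paste(edges$gene_a, edges$gene_b))
  # r matrix equals the direct covariance/sigma oracle
  for (k in seq_len(nrow(ap))) {
    expect_equal(ap$r[k], cor(m[ap$gene_a[k], ], m[ap$gene_b[k], ]),
                 tolerance = 1e-12)
  }
  # independent pair: small |r|, large permutation p
  e0 <- ap[ap$gene_a == "M02" & ap$gene_b == "C01", ]
  expect_gt(e0$p_perm, 0.05)
})

test_that("constant genes are dropped from the network with a warning", {
  m <- rbind(L01 = rnorm(10), M01 = rep(1, 10), C01 = rnorm(10))
  colnames(m) <- sprintf("s%02d", 1:10)
  cat_tbl <- gene_catalog(lncRNA = "L01", immune = "M01", icp = "C01")
  expect_warning(
    edges <- pearson_edges(as_expr(m, is_log2 = TRUE), cat_tbl, B = 50,
                           seed = 1),
    "M01")
  expect_false("M01" %in% attr(edges, "nodes")$gene_id)
})

test_that("mutual information matches closed forms and is non-negative", {
  x <- seq_len(40)
  # y = x with k equal-frequency bins -> MI = ln k
  expect_equal(mutual_information(x, x, bins = 4), log(4), tolerance = 1e-12)
  expect_equal(mutual_information(x, rep(1, 40), bins = 4), 0)
  expect_error(mutual_information(x, x, bins = 1), "bins")
  expect_error(mutual_information(x, x[-1]), "equal length")
  set.seed(5)
  xi <- rnorm(2000); yi <- rnorm(2000)
  # independent: MI near 0 (plug-in bias ~ (k-1)^2 / (2n))
  expect_lt(mutual_information(xi, yi, bins = 10), 0.06)
  # MI(x, x) >= MI(x, y), MI >= 0 on random draws
  for (i in 1:10) {
    a <- rnorm(100); b <- rnorm(100)
    expect_gte(mutual_information(a, a), mutual_information(a, b))
    expect_gte(mutual_information(a, b), 0)
  }
})

test_that("PCC/MI overlap gives the exact hypergeometric tail", {
  # 20-pair universe, top-5 vs top-5 with overlap 3
  pairs <- tibble::tibble(gene_a = sprintf("A%02d", 1:20),
                          gene_b = sprintf("B%02d", 1:20))
  r <- rep(0.1, 20); r[1:5] <- 0.9
  mi <- rep(0.1, 20); mi[c(1, 2, 3, 6, 7)] <- 0.9
  ov <- mi_overlap_check(cbind(pairs, r = r), cbind(pairs, mi = mi),
                         top_fraction = 0.25)
  expect_identical(ov$overlap, 3L)
  p_exact <- sum(dhyper(3:5, 5, 15, 5))
  expect_equal(ov$p_hyper, p_exact, tolerance = 1e-12)
  # identical edge sets: full overlap, minimal p
  ov2 <- mi_overlap_check(cbind(pairs, r = r), cbind(pairs, mi = r),
                          top_fraction = 0.25)
  expect_identical(ov2$overlap, 5L)
  expect_lt(ov2$p_hyper, 1e-3)
  # zero top fraction: empty top sets
  ov3 <- mi_overlap_check(cbind(pairs, r = r), cbind(pairs, mi = mi),
                          top_fraction = 0)
  expect_identical(ov3$overlap, 0L)
  expect_error(
    mi_overlap_check(cbind(pairs, r = r),
                     tibble::tibble(gene_a = "x", gene_b = "y", mi = 1)),
    "no gene pairs")
})

test_that("personalized PageRank handles degenerate and symmetric graphs", {
  # single isolated seeded node keeps all mass
  e0 <- tibble::tibble(gene_a = character(), gene_b = character(),
                       r = numeric())
  attr(e0, "nodes") <- tibble::tibble(gene_id = "A", role = "ICP")
  pr <- personalized_pagerank(e0, "A")
  expect_equal(pr$influence, 1)
  # symmetric two-node graph, both seeded
  e2 <- tibble::tibble(gene_a = "A", gene_b = "B", r = 0.7)
  pr2 <- personalized_pagerank(e2, c("A", "B"))
  expect_equal(pr2$influence, c(0.5, 0.5), tolerance = 1e-9)
  expect_error(personalized_pagerank(e2, "Z"), "seed")
})

test_that("PageRank matches an independent linear-solve oracle and igraph", {
  set.seed(8)
  for (i in 1:10) {
    nn <- sample(4:12, 1)
    nodes <- sprintf("n%02d", seq_len(nn))
    W <- matrix(0, nn, nn, dimnames = list(nodes, nodes))
    ne <- sample(3:(nn * 2), 1)
    for (k in seq_len(ne)) {
      ij <- sample(nn, 2)
      W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- runif(1, 0.1, 1)
    }
    edges <- tibble::tibble(
      gene_a = nodes[row(W)[upper.tri(W) & W > 0]],
      gene_b = nodes[col(W)[upper.tri(W) & W > 0]],
      r = W[upper.tri(W) & W > 0]
    )
    attr(edges, "nodes") <- tibble::tibble(gene_id = nodes, role = "immune")
    seeds <- sample(nodes, sample(1:3, 1))
    pr <- personalized_pagerank(edges, seeds)
    oracle <- pagerank_solve_oracle(W, seeds)
    expect_equal(pr$influence, unname(oracle[pr$gene_id]),
                 tolerance = 1e-7)
    expect_equal(sum(pr$influence), 1, tolerance = 1e-9)
    expect_true(all(pr$influence >= 0))
    # igraph cross-check on the connected part
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    pv <- setNames(numeric(nn), nodes); pv[seeds] <- 1
    ig <- igraph::page_rank(g, personalized = pv,
                            weights = igraph::E(g)$r)$vector
    expect_equal(pr$influence, unname(ig[pr$gene_id]), tolerance = 1e-6)
  }
})

test_that("seeding a node never lowers its own PageRank score", {
  set.seed(13)
  for (i in 1:5) {
    nn <- 8
    nodes <- sprintf("n%02d", seq_len(nn))
    edges <- tibble::tibble(
      gene_a = sample(nodes, 10, TRUE), gene_b = sample(nodes, 10, TRUE),
      r = runif(10, 0.2, 1)
    )
    edges <- edges[edges$gene_a != edges$gene_b, ]
    attr(edges, "nodes") <- tibble::tibble(gene_id = nodes, role = "immune")
    base_seeds <- nodes[1:2]
    extra <- nodes[5]
    p1 <- personalized_pagerank(edges, base_seeds)
    p2 <- personalized_pagerank(edges, c(base_seeds, extra))
    s1 <- p1$influence[p1$gene_id == extra]
    s2 <- p2$influence[p2$gene_id == extra]
    expect_gte(s2, s1 - 1e-12)
  }
})

test_that("top-k proximal selection is deterministic with lexicographic ties", {
  prop <- tibble::tibble(
    gene_id = c("Lb", "La", "Lc", "M1"),
    influence = c(0.3, 0.3, 0.2, 0.2),
    role = c("lncRNA", "lncRNA", "lncRNA", "immune")
  )
  expect_identical(top_k_proximal(prop, "lncRNA", 2), c("La", "Lb"))
  expect_identical(top_k_proximal(prop, "lncRNA", 10), c("La", "Lb", "Lc"))
  expect_identical(top_k_proximal(prop, "lncRNA", 0), character(0))
  expect_identical(top_k_proximal(prop, "immune", 1), "M1")
})

test_that("betweenness matches exhaustive path enumeration", {
  # path graph: only the middle node mediates
  ep <- tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C"))
  b <- node_betweenness(ep)
  expect_gt(b$betweenness[b$gene_id == "B"], 0)
  expect_equal(b$betweenness[b$gene_id != "B"], c(0, 0))
  # complete graph: no intermediaries
  cmb <- utils::combn(LETTERS[1:4], 2)
  ek <- tibble::tibble(gene_a = cmb[1, ], gene_b = cmb[2, ])
  expect_true(all(node_betweenness(ek)$betweenness == 0))
  # random 5-6 node graphs vs brute force
  set.seed(21)
  for (i in 1:5) {
    nn <- sample(5:6, 1)
    nodes <- LETTERS[seq_len(nn)]
    adj <- matrix(0, nn, nn, dimnames = list(nodes, nodes))
    for (k in 1:sample(5:8, 1)) {
      ij <- sample(nn, 2)
      adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- 1
    }
    edges <- tibble::tibble(gene_a = nodes[row(adj)[upper.tri(adj) & adj > 0]],
                            gene_b = nodes[col(adj)[upper.tri(adj) & adj > 0]])
    attr(edges, "nodes") <- tibble::tibble(gene_id = nodes, role = "x")
    got <- node_betweenness(edges)
    want <- betweenness_oracle(adj)
    expect_equal(got$betweenness, unname(want[got$gene_id]),
                 tolerance = 1e-9)
  }
})
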