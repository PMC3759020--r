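test_that("5 distinct-weight nodes give the complete graph minus its weakest edge", {
  set.seed(31)
  W <- random_weight_matrix(5)
  g <- build_pmfg(W)
  expect_equal(igraph::ecount(g), 9) # 3(N-2)
  el <- igraph::as_edgelist(g)
  present <- paste(el[, 1], el[, 2])
  idx <- which(upper.tri(W), arr.ind = TRUE)
  weakest <- idx[which.min(W[idx]), ]
  missing_pair <- paste(rownames(W)[weakest[1]], colnames(W)[weakest[2]])
  expect_false(missing_pair %in% present)
  expect_equal(length(present), 9)
})

test_that("PMFG matches the brute-force greedy + Kuratowski oracle on a 6-node matrix", {
  set.seed(32)
  W <- random_weight_matrix(6)
  A_oracle <- brute_pmfg(W)
  g <- build_pmfg(W)
  expect_equal(igraph_to_adj(g)[rownames(W), colnames(W)],
               `dimnames<-`(A_oracle, dimnames(W)))
  expect_equal(igraph::ecount(g), 12)
})

test_that("PMFG invariants hold on random matrices, including heavy ties", {
  set.seed(33)
  for (rep in 1:8) {
    n <- sample(6:26, 1)
    W <- if (rep %% 2 == 0) {
      random_weight_matrix(n)
    } else {
      # binary-profile correlations produce many exact ties
      x <- matrix(rbinom(9 * n, 1, 0.5), 9, n,
                  dimnames = list(NULL, sprintf("w%02d", 1:n)))
      x[, apply(x, 2, var) == 0] <- rep(c(0L, 1L), length.out = 9)
      suppressWarnings(cor(x))
    }
    if (ncol(W) < 6) next
    g <- build_pmfg(W)
    n_eff <- igraph::vcount(g)
    expect_equal(igraph::ecount(g), 3 * (n_eff - 2))
    expect_true(igraph::is_connected(g))
    expect_true(is_planar(g))
    expect_true(all(igraph::E(g)$weight == 1))
    expect_false(igraph::any_multiple(g) || any(igraph::which_loop(g)))
    # determinism: identical input -> identical edge set
    g2 <- build_pmfg(W)
    expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
    # the top-ranked edge is always present
    idx <- which(upper.tri(W), arr.ind = TRUE)
    top <- idx[order(-W[idx], idx[, 1], idx[, 2])[1], ]
    expect_true(igraph::are_adjacent(g, rownames(W)[top[1]], colnames(W)[top[2]]))
  }
})

test_that("the single greedy pass is maximal: every absent edge breaks planarity", {
  set.seed(34)
  W <- random_weight_matrix(20)
  g <- build_pmfg(W)
  vn <- igraph::V(g)$name
  for (i in 1:19) for (j in (i + 1):20) {
    if (!igraph::are_adjacent(g, vn[i], vn[j])) {
      expect_false(is_planar_with(g, c(vn[i], vn[j])))
    }
  }
})

test_that("planarity subroutine agrees with the brute-force oracle and handles landmarks", {
  # any graph on <= 4 nodes is planar: tree plus any chord
  tree <- igraph::make_tree(4, mode = "undirected")
  expect_true(is_planar_with(tree, c(3, 4)))
  # K5 minus an edge is planar; restoring the edge is not
  k5e <- igraph::make_full_graph(5)
  k5e <- igraph::delete_edges(k5e, igraph::get_edge_ids(k5e, c(1, 2)))
  igraph::V(k5e)$name <- letters[1:5]
  expect_true(is_planar(k5e))
  expect_false(is_planar_with(k5e, c("a", "b")))
  expect_error(is_planar_with(k5e, c("a", "c")), class = "fluencynet_input_error")
  expect_error(is_planar_with(k5e, c("a", "zz")), class = "fluencynet_lookup_error")

  set.seed(35)
  for (rep in 1:25) {
    n <- 20
    m_target <- sample(15:30, 1)
    e <- t(combn(n, 2))[sample(choose(n, 2), m_target), , drop = FALSE]
    A <- matrix(0L, n, n)
    A[e] <- 1L
    A <- A + t(A)
    expect_equal(is_planar(e - 1L, n = n), brute_planar(A))
  }
})

test_that("degenerate PMFG inputs raise classed errors", {
  expect_error(build_pmfg(diag(2)), class = "fluencynet_size_error")
  W <- random_weight_matrix(5)
  W[1, 2] <- W[2, 1] <- NA
  expect_error(build_pmfg(W), class = "fluencynet_input_error")
})

test_that("networks export to GraphML and edge-list CSV with provenance", {
  set.seed(36)
  W <- random_weight_matrix(8)
  g <- build_pmfg(W, network_kind = "WMCN", group = "NH")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_equal(igraph::graph_attr(back, "network_kind"), "WMCN")
  expect_equal(igraph::graph_attr(back, "group_label"), "NH")

  csv <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(g, csv)
  el <- read.csv(csv)
  expect_identical(names(el), c("from", "to"))
  expect_equal(nrow(el), igraph::ecount(g))
})
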