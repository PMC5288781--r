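test_that("symmetrization combines directed probabilities as asked", {
  P <- matrix(c(NA, 0.2, 0.4, NA), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(build_graph(P, "mean")$W["a", "b"], 0.3)
  expect_equal(build_graph(P, "max")$W["a", "b"], 0.4)
  expect_equal(build_graph(P, "min")$W["a", "b"], 0.2)
  # symmetric input: all three agree
  S <- matrix(c(NA, 0.2, 0.2, NA), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(build_graph(S, "mean")$W, build_graph(S, "max")$W)
  expect_equal(build_graph(S, "mean")$W, build_graph(S, "min")$W)
  N <- matrix(c(NA, -0.1, 0.2, NA), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(build_graph(N), "non-negative")
})

test_that("the published 4-day matrix builds a complete 9-node graph", {
  m <- read_connectivity_matrix(seadrift_example("table2_4day.csv"))
  g <- build_graph(m, "mean")
  expect_length(g$labels, 9)
  expect_equal(nrow(graph_edges(g)), 36) # choose(9, 2): all pairs linked
})

test_that("percolation threshold is the last weight before disconnection", {
  # path a-b-c with weights 0.5, 0.1: removing the weakest disconnects
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.1
  g <- graph_from_w(W, c("a", "b", "c"))
  expect_equal(percolation_threshold(g), 0.1)
  # complete uniform graph: pruning at the common weight keeps everything
  Wu <- matrix(0.3, 4, 4); diag(Wu) <- 0
  expect_equal(percolation_threshold(graph_from_w(Wu)), 0.3)
  # disconnected input errors naming components
  Wd <- matrix(0, 4, 4)
  Wd[1, 2] <- Wd[2, 1] <- 1
  Wd[3, 4] <- Wd[4, 3] <- 1
  expect_error(percolation_threshold(graph_from_w(Wd, letters[1:4])), "a, b")
})

test_that("percolation threshold matches an exhaustive sweep on random graphs", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      g <- planted_graph(9)
      tau <- percolation_threshold(g)
      ws <- sort(unique(g$W[g$W > 0]))
      keep_connected <- vapply(ws, function(w) {
        A <- g$W
        A[A < w] <- 0
        all(seadrift:::graph_connected(A))
      }, logical(1))
      expect_equal(tau, max(ws[keep_connected]))
      # pruning at tau never disconnects
      pr <- prune_graph(g, tau, "keep")
      expect_true(all(seadrift:::graph_connected(pr$W)))
    }
  })
})

test_that("two disjoint triangles joined by nothing give Q = 0.5", {
  W <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    W[e[1], e[2]] <- W[e[2], e[1]] <- 1
  }
  g <- graph_from_w(W)
  p <- leading_eigenvector(g)
  expect_equal(p$n_communities, 2)
  expect_equal(p$Q, 0.5, tolerance = 1e-12)
  expect_equal(exhaustive_max_q(W), 0.5, tolerance = 1e-12)
  m <- p$membership$community
  expect_equal(length(unique(m[1:3])), 1)
  expect_equal(length(unique(m[4:6])), 1)
  expect_false(m[1] == m[4])
})

test_that("a uniform complete graph stays one community at Q = 0", {
  W <- matrix(0.2, 5, 5); diag(W) <- 0
  p <- leading_eigenvector(graph_from_w(W))
  expect_equal(p$n_communities, 1)
  expect_equal(p$Q, 0)
})

test_that("an edgeless graph puts each node alone with Q defined as 0", {
  W <- matrix(0, 4, 4)
  p <- leading_eigenvector(graph_from_w(W))
  expect_equal(p$n_communities, 4)
  expect_equal(p$Q, 0)
})

test_that("two cliques bridged by one weak edge are recovered", {
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 1
  W[6:10, 6:10] <- 1
  diag(W) <- 0
  W[5, 6] <- W[6, 5] <- 0.05
  p <- leading_eigenvector(graph_from_w(W))
  expect_equal(p$n_communities, 2)
  m <- p$membership$community
  expect_equal(length(unique(m[1:5])), 1)
  expect_equal(length(unique(m[6:10])), 1)
})

test_that("leading eigenvector attains the exhaustive modularity optimum on structured graphs", {
  withr::with_seed(303, {
    for (rep in 1:30) {
      g <- planted_graph(sample(4:7, 1))
      p <- leading_eigenvector(g)
      expect_equal(p$Q, exhaustive_max_q(g$W), tolerance = 1e-9)
    }
  })
})

test_that("partitions never score below the trivial single community", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      g <- planted_graph(sample(4:8, 1))
      p <- leading_eigenvector(g)
      expect_gte(p$Q, -1e-12)
      expect_lte(p$Q, 1)
      expect_equal(modularity_q(g, p$membership$community), p$Q)
      expect_equal(modularity_q(g, rep(1L, length(g$labels))), 0, tolerance = 1e-14)
    }
  })
})

test_that("our weighted modularity and communities agree with igraph", {
  skip_if_not_installed("igraph")
  m <- read_connectivity_matrix(seadrift_example("table2_4day.csv"))
  g <- build_graph(m, "mean")
  g <- prune_graph(g, percolation_threshold(g), "keep")
  p <- leading_eigenvector(g)
  ig <- igraph::graph_from_adjacency_matrix(g$W, mode = "undirected", weighted = TRUE)
  cl <- igraph::cluster_leading_eigen(ig, weights = igraph::E(ig)$weight)
  expect_equal(
    p$Q,
    igraph::modularity(ig, igraph::membership(cl), weights = igraph::E(ig)$weight),
    tolerance = 1e-12
  )
  # identical grouping up to label permutation
  ours <- split(p$membership$island, p$membership$community)
  theirs <- split(g$labels, as.vector(igraph::membership(cl)))
  norm <- function(x) sort(unname(vapply(x, function(s) paste(sort(s), collapse = "|"), character(1))))
  expect_identical(norm(ours), norm(theirs))
})

test_that("strong planted structure is significant, uniform graphs are not", {
  # complete graph whose *weights* carry two blocks: the topology-fixed
  # weight-shuffling null destroys exactly that signal
  W <- withr::with_seed(9, {
    memb <- rep(1:2, each = 4)
    W <- matrix(0, 8, 8)
    for (i in 1:7) for (j in (i + 1):8) {
      w <- if (memb[i] == memb[j]) runif(1, 0.8, 1) else runif(1, 0.02, 0.1)
      W[i, j] <- W[j, i] <- w
    }
    W
  })
  sig <- cluster_significance(graph_from_w(W), n_permutations = 499, seed = 7)
  expect_lte(sig$p_value, 0.01)
  expect_gte(sig$p_value, 1 / 500)

  # near-uniform complete graph: no structure to find
  withr::with_seed(3, {
    hits <- vapply(1:10, function(s) {
      Wu <- matrix(0, 6, 6)
      wu <- runif(15, 0.95, 1.05)
      Wu[upper.tri(Wu)] <- wu
      Wu <- Wu + t(Wu)
      cluster_significance(graph_from_w(Wu), n_permutations = 199, seed = s)$p_value
    }, numeric(1))
    expect_gte(mean(hits > 0.05), 0.8)
  })
})

test_that("the permutation p-value floors at 1/(n+1)", {
  # extreme weight contrast on a complete topology: no permutation matches
  W <- withr::with_seed(4, {
    memb <- rep(1:2, each = 4)
    W <- matrix(0, 8, 8)
    for (i in 1:7) for (j in (i + 1):8) {
      w <- if (memb[i] == memb[j]) runif(1, 0.9, 1) else runif(1, 0.001, 0.002)
      W[i, j] <- W[j, i] <- w
    }
    W
  })
  sig <- cluster_significance(graph_from_w(W), n_permutations = 99, seed = 1)
  expect_equal(sig$p_value, 0.01)
  expect_error(cluster_significance(graph_from_w(W), n_permutations = 50), "99")
})

test_that("the full clustering pipeline records its variant and co-clusters strong pairs", {
  labels <- paste0("i", 1:5)
  P <- matrix(1e-6, 5, 5, dimnames = list(labels, labels))
  diag(P) <- NA
  P["i1", "i2"] <- P["i2", "i1"] <- 0.5 # one strongly linked pair
  part <- cluster_islands(connectivity_matrix(P))
  m <- setNames(part$membership$community, part$membership$island)
  expect_equal(m[["i1"]], m[["i2"]])
  expect_equal(part$symmetrization, "mean")
  expect_false(is.null(part$threshold))
  g <- glance(part)
  expect_named(g, c("n_communities", "modularity", "threshold", "symmetrization"))
})
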