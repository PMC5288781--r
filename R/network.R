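#' Build an undirected island graph from a connectivity matrix
#'
#' Symmetrizes the directed island-to-island probabilities into undirected
#' edge weights. The default combines the two directions by arithmetic mean;
#' `max` and `min` are available because the directed-to-undirected step of a
#' connectivity network analysis is a modelling choice.
#'
#' @param matrix A `connectivity_matrix` (or plain labelled square matrix).
#' @param symmetrization One of `"mean"`, `"max"`, `"min"`.
#' @return A `conn_graph`: list with `labels`, the symmetric weight matrix
#'   `W` (zero diagonal; zero = no edge), and the symmetrization recorded.
#' @export
build_graph <- function(matrix, symmetrization = c("mean", "max", "min")) {
  symmetrization <- match.arg(symmetrization)
  P <- unclass(matrix)
  if (nrow(P) != ncol(P) || is.null(rownames(P))) {
    abort("`matrix` must be square with island labels")
  }
  if (any(P[row(P) != col(P)] < 0, na.rm = TRUE)) {
    abort("connectivity entries must be non-negative")
  }
  P[is.na(P)] <- 0
  diag(P) <- 0
  W <- switch(symmetrization,
    mean = (P + t(P)) / 2,
    max = pmax(P, t(P)),
    min = pmin(P, t(P))
  )
  structure(
    list(labels = rownames(P), W = W, symmetrization = symmetrization),
    class = "conn_graph"
  )
}

#' @export
print.conn_graph <- function(x, ...) {
  cat(sprintf(
    "<conn_graph> %d nodes, %d weighted edges (symmetrization: %s)\n",
    length(x$labels), sum(x$W[upper.tri(x$W)] > 0), x$symmetrization
  ))
  invisible(x)
}

#' Edge list of a connectivity graph
#'
#' @param graph A `conn_graph`.
#' @return Tibble with `from`, `to`, `weight` for every positive-weight edge.
#' @export
graph_edges <- function(graph) {
  idx <- which(upper.tri(graph$W) & graph$W > 0, arr.ind = TRUE)
  tibble(
    from = graph$labels[idx[, 1]],
    to = graph$labels[idx[, 2]],
    weight = graph$W[idx]
  ) %>%
    arrange(dplyr::desc(.data$weight))
}

# connectivity of the positive-weight graph (breadth-first)
graph_connected <- function(W) {
  n <- nrow(W)
  if (n == 0) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(W[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  seen
}

graph_components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cid <- cid + 1L
      queue <- v
      comp[v] <- cid
      while (length(queue)) {
        w <- queue[1]; queue <- queue[-1]
        nb <- which(W[w, ] > 0 & comp == 0L)
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

#' Percolation threshold of a weighted graph
#'
#' The largest edge weight `tau` such that keeping only edges with weight
#' `>= tau` leaves the graph connected: the point at which the network of
#' progressively stronger links is about to fragment. Found by a sweep over
#' the distinct edge weights in decreasing order.
#'
#' @param graph A `conn_graph`, connected at threshold 0.
#' @return The threshold weight (a scalar).
#' @export
percolation_threshold <- function(graph) {
  W <- graph$W
  if (!all(graph_connected(W))) {
    comp <- graph_components(W)
    tab <- split(graph$labels, comp)
    abort(paste0(
      "graph is disconnected before pruning; components: ",
      paste(vapply(tab, paste, character(1), collapse = ", "), collapse = " | ")
    ))
  }
  ws <- sort(unique(W[upper.tri(W) & W > 0]), decreasing = TRUE)
  for (tau in ws) {
    A <- W
    A[A < tau] <- 0
    if (all(graph_connected(A))) return(tau)
  }
  min(ws)
}

#' Prune a graph at a weight threshold
#'
#' @param graph A `conn_graph`.
#' @param tau Threshold weight.
#' @param rule `"keep"` removes edges with weight `< tau` (graph stays
#'   connected at the percolation threshold); `"past"` also removes the
#'   threshold edges themselves (`<= tau`), the variant just past
#'   disconnection.
#' @return The pruned `conn_graph` (threshold recorded as attribute).
#' @export
prune_graph <- function(graph, tau, rule = c("keep", "past")) {
  rule <- match.arg(rule)
  W <- graph$W
  if (rule == "keep") W[W < tau] <- 0 else W[W <= tau] <- 0
  out <- graph
  out$W <- W
  out$threshold <- tau
  out$prune_rule <- rule
  out
}

#' Weighted modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)` with `A` the
#' symmetric weight matrix, `k` the weighted degrees and `2m` the total
#' weight. Defined as 0 for an edgeless graph.
#'
#' @param graph A `conn_graph`.
#' @param membership Integer community ids, one per node.
#' @return Scalar `Q` in `[-0.5, 1]`.
#' @export
modularity_q <- function(graph, membership) {
  W <- graph$W
  m2 <- sum(W)
  if (m2 == 0) return(0)
  k <- rowSums(W)
  same <- outer(membership, membership, "==")
  sum((W - outer(k, k) / m2) * same) / m2
}

#' Leading-eigenvector community detection
#'
#' Newman's spectral method on the weighted modularity matrix
#' `B_ij = A_ij - k_i k_j / 2m`: the graph is recursively bisected by the sign
#' pattern of the leading eigenvector of the (generalized) modularity matrix,
#' each split is fine-tuned by Kernighan-Lin style single-vertex sweeps, and
#' recursion stops when no split increases `Q`. A final partition-level
#' refinement pass (single-vertex moves and community merges) is applied.
#' Zero eigenvector components are assigned to the positive side for
#' determinism. An edgeless graph yields one community per node with `Q = 0`.
#'
#' @param graph A `conn_graph`.
#' @return An `island_partition`: list with `membership` (tibble of `island`,
#'   `community`), `Q`, `n_communities`, plus the graph's symmetrization and
#'   any recorded threshold.
#' @export
leading_eigenvector <- function(graph) {
  W <- graph$W
  n <- nrow(W)
  if (n == 0) abort("empty graph")
  m2 <- sum(W)
  if (m2 == 0) {
    return(new_partition(graph, seq_len(n), Q = 0))
  }
  k <- rowSums(W)
  B <- W - outer(k, k) / m2
  memb <- rep(1L, n)

  bisect <- function(ids) {
    Bg <- B[ids, ids, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    ev <- eigen(Bg, symmetric = TRUE)
    if (ev$values[1] <= 1e-12) return(NULL)
    s <- ifelse(ev$vectors[, 1] >= 0, 1, -1)
    dq <- function(s) as.numeric(t(s) %*% Bg %*% s)
    # Kernighan-Lin fine-tuning: greedy full sweeps, keep the best prefix
    repeat {
      cur <- dq(s)
      sweep_s <- s
      moved <- logical(length(ids))
      best_s <- s
      best_val <- cur
      for (step in seq_along(ids)) {
        cand <- which(!moved)
        vals <- vapply(cand, function(i) {
          t2 <- sweep_s; t2[i] <- -t2[i]; dq(t2)
        }, numeric(1))
        b <- cand[which.max(vals)]
        sweep_s[b] <- -sweep_s[b]
        moved[b] <- TRUE
        if (max(vals) > best_val + 1e-12) {
          best_val <- max(vals)
          best_s <- sweep_s
        }
      }
      if (best_val > cur + 1e-12) s <- best_s else break
    }
    if (length(unique(s)) < 2) return(NULL)
    if (dq(s) / (2 * m2) <= 1e-12) return(NULL)
    s
  }

  recurse <- function(ids) {
    if (length(ids) < 2) return()
    s <- bisect(ids)
    if (is.null(s)) return()
    new_c <- max(memb) + 1L
    memb[ids[s < 0]] <<- new_c
    recurse(ids[s > 0])
    recurse(ids[s < 0])
  }
  recurse(seq_len(n))

  # final tuning: single-vertex moves between communities, then merges
  q_of <- function(mm) {
    same <- outer(mm, mm, "==")
    sum(B * same) / m2
  }
  repeat {
    improved <- FALSE
    q0 <- q_of(memb)
    for (v in seq_len(n)) {
      for (cc in unique(memb)) {
        if (memb[v] == cc) next
        t2 <- memb; t2[v] <- cc
        q1 <- q_of(t2)
        if (q1 > q0 + 1e-12) {
          memb <- t2; q0 <- q1; improved <- TRUE
        }
      }
    }
    comms <- unique(memb)
    if (length(comms) > 1) {
      for (a in comms) for (b in comms) {
        if (a >= b) next
        t2 <- memb; t2[t2 == b] <- a
        q1 <- q_of(t2)
        if (q1 > q0 + 1e-12) {
          memb <- t2; q0 <- q1; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  memb <- match(memb, unique(memb))
  new_partition(graph, memb, Q = modularity_q(graph, memb))
}

new_partition <- function(graph, membership, Q) {
  structure(
    list(
      membership = tibble(island = graph$labels, community = as.integer(membership)),
      Q = Q,
      n_communities = length(unique(membership)),
      symmetrization = graph$symmetrization,
      threshold = graph$threshold,
      prune_rule = graph$prune_rule
    ),
    class = "island_partition"
  )
}

#' @export
print.island_partition <- function(x, ...) {
  cat(sprintf(
    "<island_partition> %d communities, Q = %.4f%s\n",
    x$n_communities, x$Q,
    if (!is.null(x$threshold)) sprintf(", percolation threshold = %.3g", x$threshold) else ""
  ))
  groups <- split(x$membership$island, x$membership$community)
  for (g in seq_along(groups)) {
    cat(sprintf("  %d: %s\n", g, paste(groups[[g]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
tidy.island_partition <- function(x, ...) x$membership

#' @export
glance.island_partition <- function(x, ...) {
  tibble(
    n_communities = x$n_communities,
    modularity = x$Q,
    threshold = x$threshold %||% NA_real_,
    symmetrization = x$symmetrization %||% NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster islands from a connectivity matrix
#'
#' The full network pipeline: symmetrize the directed probabilities
#' ([build_graph()]), optionally prune weak edges at the percolation
#' threshold ([percolation_threshold()]), and detect communities with the
#' leading-eigenvector algorithm ([leading_eigenvector()]). The returned
#' partition records the threshold, symmetrization and pruning variant used,
#' so a run manifest can state the exact pipeline.
#'
#' @param matrix A `connectivity_matrix`.
#' @param symmetrization Directed-to-undirected combination (see
#'   [build_graph()]).
#' @param prune Apply percolation pruning?
#' @param prune_rule `"keep"` or `"past"` (see [prune_graph()]).
#' @return An `island_partition`.
#' @examples
#' m <- read_connectivity_matrix(seadrift_example("table2_4day.csv"))
#' cluster_islands(m)
#' @export
cluster_islands <- function(matrix, symmetrization = "mean", prune = TRUE,
                            prune_rule = "keep") {
  g <- build_graph(matrix, symmetrization)
  if (prune) {
    tau <- percolation_threshold(g)
    g <- prune_graph(g, tau, prune_rule)
  }
  leading_eigenvector(g)
}

#' Permutation test for clustering strength
#'
#' Assesses whether the observed modularity could arise without any relation
#' between edge weights and network position: edge weights are shuffled
#' uniformly among the existing edges (topology fixed), the clustering is
#' re-run on each permuted graph, and the add-one p-value
#' `p = (1 + #(Q* >= Q_obs)) / (n_permutations + 1)` is reported.
#'
#' @param graph A `conn_graph` (prune first if the observed partition was
#'   computed on the pruned graph).
#' @param n_permutations Number of permutations (>= 99; default 10000).
#' @param seed Integer seed.
#' @return A `permutation_test` list: `observed_Q`, `n_permutations`,
#'   `p_value`, `seed`, and the permuted `null_Q` values.
#' @export
cluster_significance <- function(graph, n_permutations = 10000, seed = 1L) {
  if (n_permutations < 99) abort("`n_permutations` must be at least 99")
  obs <- leading_eigenvector(graph)
  W <- graph$W
  eidx <- which(upper.tri(W) & W > 0)
  null_q <- numeric(n_permutations)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_permutations)) {
      Wb <- W * 0
      Wb[eidx] <- sample(W[eidx])
      Wb <- Wb + t(Wb)
      gb <- graph
      gb$W <- Wb
      null_q[b] <- leading_eigenvector(gb)$Q
    }
  })
  p <- (1 + sum(null_q >= obs$Q)) / (n_permutations + 1)
  structure(
    list(
      observed_Q = obs$Q, n_permutations = n_permutations,
      p_value = p, seed = as.integer(seed), null_Q = null_q
    ),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "<permutation_test> observed Q = %.4f, p = %.4g (%d permutations, seed %d)\n",
    x$observed_Q, x$p_value, x$n_permutations, x$seed
  ))
  invisible(x)
}
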