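#' Read and validate an ultrametric tree
#'
#' Parses a newick file with `ape`, resolves any multifurcations into binary
#' nodes with zero-length branches, and verifies ultrametricity: all
#' root-to-tip path lengths must agree within `tol` times the tree height
#' (contemporaneous tips are what gives node heights the meaning of times).
#'
#' @param path Newick file path (or a newick string ending in `;`).
#' @param tol Relative ultrametricity tolerance.
#' @return A rooted binary `phylo` object.
#' @export
read_ultrametric_tree <- function(path, tol = 1e-6) {
  tree <- if (grepl(";", path, fixed = TRUE)) {
    ape::read.tree(text = path)
  } else {
    ape::read.tree(path)
  }
  if (is.null(tree)) abort("could not parse newick input")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  height <- max(depths)
  spread <- max(depths) - min(depths)
  if (spread > tol * height) {
    hi <- tree$tip.label[which.max(depths)]
    lo <- tree$tip.label[which.min(depths)]
    abort(sprintf(
      "tree is not ultrametric: root-to-tip lengths differ by %.3g (x height); worst pair '%s' (%.6g) vs '%s' (%.6g)",
      spread / height, hi, max(depths), lo, min(depths)
    ))
  }
  tree
}

# Branching structure shared by the null and GMYC likelihoods.
#
# Node heights are sorted from the root (h_1) towards the tips (h_m,
# m = n_tips - 1). Waiting intervals run between successive branching
# events; interval i has n_i = i + 1 lineages and closes with the event at
# h_{i+1}, so there are m - 1 observed waiting times. Tied or zero waiting
# times are broken by forcing a strict decrease of 1e-9 x height, which the
# likelihood requires.
branching_structure <- function(tree) {
  n_tip <- ape::Ntip(tree)
  if (n_tip < 3) abort("at least 3 tips are required for fitting")
  bt <- ape::branching.times(tree)
  ord <- order(bt, decreasing = TRUE)
  nodes <- as.integer(names(bt))[ord]
  h <- as.numeric(bt)[ord]
  eps <- 1e-9 * h[1]
  for (i in seq_along(h)[-1]) {
    if (h[i] >= h[i - 1] - eps) h[i] <- h[i - 1] - eps
  }
  m <- length(h)
  # parent pointers (ape edge matrix)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # children of each internal node
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  list(
    tree = tree, n_tip = n_tip, m = m,
    nodes = nodes, heights = h,
    x = h[-m] - h[-1], # waiting times, length m - 1
    parent = parent, kids = kids,
    node_rank = setNames(seq_len(m), nodes)
  )
}

#' Fit a single-class branching model (GMYC null)
#'
#' The null hypothesis of the GMYC test: every waiting time between
#' successive branching events comes from one process with rate
#' `b_i = lambda * n_i^p`, where `n_i` is the number of lineages in interval
#' `i`. `lambda` is profiled analytically
#' (`lambda_hat = m_events / sum(n_i^p x_i)`) and `p` is optimized within
#' `(-5, 5)`; `p = 1` is a Yule process, `p` near `n-1` scaling mimics a
#' coalescent.
#'
#' @param tree Ultrametric `phylo` (>= 3 tips).
#' @param p_fixed Optional fixed scaling exponent (e.g. `1` for Yule).
#' @return A list: `lambda`, `p`, `logLik`, `n_intervals`.
#' @export
fit_bproc_null <- function(tree, p_fixed = NULL) {
  bs <- branching_structure(tree)
  n_lin <- seq_len(bs$m - 1) + 1 # lineages per interval
  x <- bs$x
  prof <- function(p) {
    shape <- n_lin^p
    A <- sum(shape * x)
    lam <- clamp_lambda(length(x) / A)
    sum(log(lam) + p * log(n_lin)) - lam * A
  }
  if (!is.null(p_fixed)) {
    p_hat <- p_fixed
  } else {
    opt <- optimize(prof, interval = c(-5, 5), maximum = TRUE, tol = 1e-8)
    p_hat <- opt$maximum
  }
  lam_hat <- clamp_lambda(length(x) / sum(n_lin^p_hat * x))
  list(
    lambda = lam_hat, p = p_hat, logLik = prof(p_hat),
    n_intervals = length(x)
  )
}

clamp_lambda <- function(l) min(max(l, 1e-10), 1e6)

# Interval bookkeeping for one candidate threshold: the k oldest nodes are
# diversification events, the rest coalescent.
#
# Interval i (i = 1..m-1) runs between the events of rank i (older end) and
# rank i+1; during it the events of rank <= i have happened, so the total
# lineage count is i+1 and a cluster holds 1 + (its events of rank <= i)
# lineages. Each interval contributes one waiting-time density whose rate
# class is that of the event at its older end (rank i): for the coalescent
# class this is the backward-time convention, under which the event closing
# a cluster interval always sees the cluster with >= 2 lineages. With k = m
# every interval is diversification-classed and the likelihood reduces
# exactly to the single-process null.
threshold_structure <- function(bs, k) {
  m <- bs$m
  n_int <- m - 1
  # cluster id for each coalescent node (rank > k): the entity subtree it
  # falls in. Walk up until the parent is a diversification node.
  coal_cluster <- integer(m) # by rank; 0 for diversification nodes
  if (k < m) {
    for (r in (k + 1):m) {
      node <- bs$nodes[r]
      up <- node
      repeat {
        par <- bs$parent[up]
        if (par == 0L || bs$node_rank[as.character(par)] <= k) break
        up <- par
      }
      coal_cluster[r] <- up # entity root node id labels the cluster
    }
  }
  # diversification (species-level) lineages during interval i
  n_div <- pmin(seq_len(n_int), k) + 1
  # cluster lineage counts per interval (only clusters with >= 2 lineages
  # contribute to the n(n-1) term)
  cl_sizes <- vector("list", n_int)
  if (k < m) {
    clusters <- as.character(unique(coal_cluster[coal_cluster != 0]))
    counts <- setNames(rep(1L, length(clusters)), clusters)
    for (i in seq_len(n_int)) {
      if (i > k) {
        ev_cluster <- as.character(coal_cluster[i])
        counts[ev_cluster] <- counts[ev_cluster] + 1L
      }
      cl_sizes[[i]] <- as.integer(counts[counts >= 2L])
    }
  } else {
    cl_sizes <- replicate(n_int, integer(0), simplify = FALSE)
  }
  # class of the event at the older end of interval i (rank i)
  event_div <- seq_len(n_int) <= k
  list(
    k = k, n_div = n_div, cl_sizes = cl_sizes, event_div = event_div,
    coal_cluster = coal_cluster
  )
}

# profile log-likelihood of the two-class model at (p_div, p_coal) for a
# fixed threshold structure; lambdas profiled analytically
gmyc_loglik <- function(bs, ts, p_div, p_coal) {
  x <- bs$x
  n_int <- length(x)
  m_div <- sum(ts$event_div)
  m_coal <- n_int - m_div
  shape_div <- ts$n_div^p_div
  shape_coal <- vapply(ts$cl_sizes, function(sz) {
    if (length(sz) == 0) 0 else sum((sz * (sz - 1))^p_coal)
  }, numeric(1))
  ll <- 0
  if (m_div > 0) {
    A <- sum(shape_div * x)
    lam_d <- clamp_lambda(m_div / A)
    ll <- ll + m_div * log(lam_d) + p_div * sum(log(ts$n_div[ts$event_div])) -
      lam_d * A
  }
  if (m_coal > 0) {
    C <- sum(shape_coal * x)
    if (C <= 0) return(-Inf)
    lam_c <- clamp_lambda(m_coal / C)
    ll <- ll + m_coal * log(lam_c) + sum(log(shape_coal[!ts$event_div])) -
      lam_c * C
  }
  ll
}

# maximize over (p_div, p_coal) with multi-start bounded quasi-Newton
fit_threshold <- function(bs, ts, starts) {
  nll <- function(par) -gmyc_loglik(bs, ts, par[1], par[2])
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[s, ], nll, method = "L-BFGS-B",
            lower = c(-5, -5), upper = c(5, 5),
            control = list(maxit = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) abort("GMYC likelihood optimization failed to converge")
  p_div <- best$par[1]; p_coal <- best$par[2]
  x <- bs$x
  m_div <- sum(ts$event_div)
  m_coal <- length(x) - m_div
  lam_d <- if (m_div > 0) clamp_lambda(m_div / sum(ts$n_div^p_div * x)) else 0
  shape_coal <- vapply(ts$cl_sizes, function(sz) {
    if (length(sz) == 0) 0 else sum((sz * (sz - 1))^p_coal)
  }, numeric(1))
  lam_c <- if (m_coal > 0) clamp_lambda(m_coal / sum(shape_coal * x)) else 0
  list(
    logLik = -best$value, p_div = p_div, p_coal = p_coal,
    lambda_div = lam_d, lambda_coal = lam_c
  )
}

#' Fit the single-threshold general mixed Yule-coalescent model
#'
#' Places a threshold time on an ultrametric tree: branching events older
#' than the threshold are diversification (between-species) events, younger
#' ones are coalescent (within-species) events. For each candidate threshold
#' (each observed node height, i.e. the `k` oldest nodes diversifying for
#' `k = 1..n_tips-1`), the two-class waiting-time likelihood
#' `L = prod_i b_event,i * exp(-(b_div,i + b_coal,i) x_i)` is maximized,
#' with `b_div,i = lambda_div * n_div,i^p_div` and
#' `b_coal,i = lambda_coal * sum_j (n_j (n_j - 1))^p_coal` over the clusters
#' crossing interval `i`. The threshold with the highest profile likelihood
#' wins; tips descending from each lineage crossing it form one delimited
#' entity (clusters plus singletons).
#'
#' The largest candidate (`k = n_tips - 1`) reduces to the single-process
#' null, so the fitted log-likelihood is never below the null's.
#'
#' @param tree Ultrametric `phylo` (>= 3 tips).
#' @param n_starts Number of optimizer starts per candidate threshold.
#' @return A `gmyc_fit` object; see [tidy.gmyc_fit()] and
#'   [glance.gmyc_fit()] for tidy accessors.
#' @export
fit_gmyc <- function(tree, n_starts = 5) {
  bs <- branching_structure(tree)
  if (bs$m < 2) abort("fewer than 2 candidate thresholds; need >= 3 tips")
  starts <- matrix(
    c(1, 1,
      0, 0,
      1, 0.5,
      0.5, 1,
      -1, 1),
    ncol = 2, byrow = TRUE
  )[seq_len(min(n_starts, 5)), , drop = FALSE]
  fits <- vector("list", bs$m)
  for (k in seq_len(bs$m)) {
    ts <- threshold_structure(bs, k)
    fits[[k]] <- c(fit_threshold(bs, ts, starts), list(k = k))
  }
  ll <- vapply(fits, function(f) f$logLik, numeric(1))
  k_hat <- which.max(ll)
  best <- fits[[k_hat]]
  null <- fit_bproc_null(tree)
  entities <- threshold_entities(bs, k_hat)
  profile <- tibble(
    k = seq_len(bs$m),
    threshold_height = bs$heights,
    n_entities = seq_len(bs$m) + 1L,
    logLik = ll
  )
  structure(
    list(
      tree = tree,
      k = k_hat,
      threshold_height = bs$heights[k_hat],
      lambda_div = best$lambda_div, p_div = best$p_div,
      lambda_coal = best$lambda_coal, p_coal = best$p_coal,
      logLik = best$logLik,
      null = null,
      n_entities = k_hat + 1L,
      entities = entities,
      profile = profile
    ),
    class = "gmyc_fit"
  )
}

# tip membership for candidate threshold k: one entity per lineage crossing
# the threshold (children of diversification nodes that are not themselves
# diversification nodes)
threshold_entities <- function(bs, k) {
  div_nodes <- bs$nodes[seq_len(k)]
  roots <- unlist(lapply(div_nodes, function(nd) {
    kk <- bs$kids[[as.character(nd)]]
    kk[!kk %in% div_nodes]
  }))
  tree <- bs$tree
  n_tip <- bs$n_tip
  tips_under <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(bs$kids[[as.character(node)]], tips_under))
  }
  purrr::map_dfr(seq_along(roots), function(e) {
    tips <- tips_under(roots[e])
    tibble(
      tip = tree$tip.label[tips],
      entity = e,
      singleton = length(tips) == 1
    )
  }) %>%
    arrange(.data$entity, .data$tip)
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat(sprintf(
    "<gmyc_fit> %d entities (threshold height %.4g)\n",
    x$n_entities, x$threshold_height
  ))
  cat(sprintf(
    "  lnL = %.4f (null %.4f); lambda_div = %.4g (p %.3g), lambda_coal = %.4g (p %.3g)\n",
    x$logLik, x$null$logLik, x$lambda_div, x$p_div, x$lambda_coal, x$p_coal
  ))
  invisible(x)
}

#' Tidy a GMYC fit into a tip-to-entity table
#'
#' @param x A `gmyc_fit`.
#' @param ... Unused.
#' @return Tibble with `tip`, `entity`, `singleton`.
#' @export
tidy.gmyc_fit <- function(x, ...) x$entities

#' One-row summary of a GMYC fit
#'
#' @param x A `gmyc_fit`.
#' @param ... Unused.
#' @return Tibble with entity count, threshold, rates and log-likelihoods.
#' @export
glance.gmyc_fit <- function(x, ...) {
  tibble(
    n_entities = x$n_entities,
    threshold_height = x$threshold_height,
    lambda_div = x$lambda_div, p_div = x$p_div,
    lambda_coal = x$lambda_coal, p_coal = x$p_coal,
    logLik = x$logLik, logLik_null = x$null$logLik
  )
}

#' Likelihood-ratio test of the GMYC model against the one-process null
#'
#' `D = 2 (lnL_GMYC - lnL_null)`, compared to a chi-square upper tail. The
#' default `df = 3` counts the threshold and the extra rate and scaling
#' parameters; `df = 2` is available since implementations differ, and the
#' choice is recorded in the result.
#'
#' @param fit A `gmyc_fit` (or an ultrametric `phylo`, which is fitted
#'   first).
#' @param df Degrees of freedom for the chi-square reference.
#' @return Tibble with `statistic`, `df`, `p_value`, `n_entities`.
#' @export
gmyc_lrt <- function(fit, df = 3) {
  if (inherits(fit, "phylo")) fit <- fit_gmyc(fit)
  if (!inherits(fit, "gmyc_fit")) abort("`fit` must be a gmyc_fit or a phylo")
  D <- max(0, 2 * (fit$logLik - fit$null$logLik))
  tibble(
    statistic = D,
    df = df,
    p_value = pchisq(D, df = df, lower.tail = FALSE),
    n_entities = fit$n_entities
  )
}

#' Simulate a tree with known species structure
#'
#' Grows a Yule (pure-birth) species tree — the waiting time while `k`
#' lineages exist is exponential with rate `speciation_rate * k`, stopping
#' after the draw at `k = n_species`, so the expected root height is
#' `sum_{k=2..n} 1/(lambda k)` — and grafts an independent standard
#' coalescent subtree onto each species tip. Each subtree is rescaled so its
#' height is the shallowest species divergence divided by
#' `within_species_height_scale` (times a uniform factor in `[0.5, 1]` so
#' clusters differ in depth), giving well-separated species for
#' `within_species_height_scale >= 20`.
#'
#' @param n_species Number of species (>= 1). `n_species = 1` returns a pure
#'   coalescent tree.
#' @param tips_per_species Tips sampled per species (scalar or vector).
#' @param speciation_rate Yule rate `lambda`.
#' @param within_species_height_scale Separation factor between the
#'   shallowest species split and the deepest within-species coalescence.
#' @param seed Integer seed; the newick string is reproducible.
#' @return An ultrametric `phylo` with tips labelled `sp<i>_<j>`.
#' @export
simulate_gmyc_tree <- function(n_species, tips_per_species, speciation_rate = 1,
                               within_species_height_scale = 20, seed = 1L) {
  if (n_species < 1) abort("`n_species` must be >= 1")
  tips <- rep_len(tips_per_species, n_species)
  if (any(tips < 1)) abort("`tips_per_species` must be >= 1")
  withr::with_seed(as.integer(seed), {
    if (n_species == 1) {
      if (tips[1] < 2) abort("a single species needs >= 2 tips")
      tr <- ape::rcoal(tips[1], tip.label = paste0("sp1_", seq_len(tips[1])))
      return(tr)
    }
    yule <- simulate_yule(n_species, speciation_rate)
    min_div <- yule$min_node_height
    sub_newick <- vapply(seq_len(n_species), function(i) {
      if (tips[i] == 1) {
        return(NA_character_)
      }
      sub <- ape::rcoal(tips[i], tip.label = paste0("sp", i, "_", seq_len(tips[i])))
      target <- (min_div / within_species_height_scale) * runif(1, 0.5, 1)
      h <- max(ape::node.depth.edgelength(sub))
      sub$edge.length <- sub$edge.length * target / h
      sub_txt <- ape::write.tree(sub)
      sub("; *$", "", sub_txt)
    }, character(1))
    txt <- yule$newick
    for (i in seq_len(n_species)) {
      if (is.na(sub_newick[i])) {
        # singleton species: rename the backbone tip
        txt <- sub(paste0("sp", i, ":"), paste0("sp", i, "_1:"), txt, fixed = TRUE)
        next
      }
      # replace "spI:len" with "(subtree):len - subtree_height"
      pat <- paste0("sp", i, ":([0-9.eE+-]+)")
      mt <- regmatches(txt, regexpr(pat, txt))
      len <- as.numeric(sub(pat, "\\1", mt))
      sub_h <- max(ape::node.depth.edgelength(ape::read.tree(text = paste0(sub_newick[i], ";"))))
      repl <- paste0(sub_newick[i], ":", format(len - sub_h, digits = 17))
      txt <- sub(pat, repl, txt)
    }
    ape::read.tree(text = txt)
  })
}

# Yule tree conditioned on n tips: grow lineage by lineage; returns newick
# with tips sp1..spn all at height 0 and the minimum internal node height
simulate_yule <- function(n, rate) {
  # waiting times while k = 2..n lineages exist
  waits <- rexp(n - 1, rate = rate * (2:n))
  total <- sum(waits)
  # event times measured from the root (root split at time 0)
  split_times <- cumsum(c(0, waits[-length(waits)]))
  # active lineages: list of (id); splits recorded as id -> (t, c1, c2)
  next_id <- 3L
  active <- c(1L, 2L)
  birth <- c(0, 0)
  split_t <- list()
  split_kids <- list()
  for (e in seq_len(n - 2)) {
    t_e <- split_times[e + 1]
    pick <- active[sample.int(length(active), 1)]
    c1 <- next_id; c2 <- next_id + 1L
    next_id <- next_id + 2L
    split_t[[pick]] <- t_e
    split_kids[[pick]] <- c(c1, c2)
    birth[c1] <- t_e
    birth[c2] <- t_e
    active <- c(setdiff(active, pick), c1, c2)
  }
  tip_counter <- 0L
  as_newick <- function(id) {
    if (id <= length(split_kids) && !is.null(split_kids[[id]])) {
      kk <- split_kids[[id]]
      len <- split_t[[id]] - birth[id]
      paste0("(", as_newick(kk[1]), ",", as_newick(kk[2]), "):",
             format(len, digits = 17))
    } else {
      tip_counter <<- tip_counter + 1L
      paste0("sp", tip_counter, ":", format(total - birth[id], digits = 17))
    }
  }
  inner <- paste0("(", as_newick(1L), ",", as_newick(2L), ");")
  tree_tmp <- ape::read.tree(text = inner)
  min_node_height <- min(ape::branching.times(tree_tmp))
  list(newick = inner, min_node_height = min_node_height, height = total)
}
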