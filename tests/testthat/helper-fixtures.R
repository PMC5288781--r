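# shared fixture builders; everything is generated in code

# an empty coastal grid: open ocean for pure-advection tests
open_coast <- function(grid) {
  x <- tibble::tibble(
    cell_id = integer(), lon = numeric(), lat = numeric(),
    island = integer(), substrate = character()
  )
  attr(x, "grid") <- grid
  x
}

# hand-built two-island coast on a given grid: square islands centred at
# (lon1, lat0) and (lon2, lat0), side `side` cells of land, with the coastal
# ring labelled; substrate all rock
two_island_coast <- function(grid, lon1, lon2, lat0, half_deg) {
  lons <- seadrift:::grid_lons(grid)
  lats <- seadrift:::grid_lats(grid)
  land <- matrix(0L, grid$n_lat, grid$n_lon)
  for (k in 1:2) {
    lc <- if (k == 1) lon1 else lon2
    land[abs(lats - lat0) <= half_deg, abs(lons - lc) <= half_deg] <- k
  }
  ring <- seadrift:::coastal_ring(land)
  out <- tibble::tibble(
    cell_id = seadrift:::grid_cell_id(grid, ring$row, ring$col),
    lon = lons[ring$col],
    lat = lats[ring$row],
    island = ring$island,
    substrate = "rock"
  )
  out <- out[order(out$cell_id), ]
  attr(out, "grid") <- grid
  attr(out, "land") <- land > 0L
  out
}

# synthetic dispersal event tibble from explicit (source, dest) pairs
make_events <- function(source_cell, dest_cell, source_island = 1L,
                        dest_island = 1L, drift_days = 1, distance_km = 10) {
  n <- length(source_cell)
  tibble::tibble(
    particle_id = seq_len(n),
    source_cell = as.integer(source_cell),
    source_island = rep_len(as.integer(source_island), n),
    dest_cell = as.integer(dest_cell),
    dest_island = rep_len(as.integer(dest_island), n),
    drift_days = ifelse(is.na(dest_cell), NA_real_, rep_len(drift_days, n)),
    distance_km = ifelse(is.na(dest_cell), NA_real_, rep_len(distance_km, n)),
    fate = ifelse(is.na(dest_cell), "expired", "landed"),
    out_of_domain = FALSE
  )
}

make_schedule <- function(cell_id, times = 0) {
  out <- tidyr::expand_grid(time_h = times, cell_id = cell_id)
  out <- out[, c("cell_id", "time_h")]
  attr(out, "interval_hours") <- if (length(times) > 1) diff(times)[1] else 12
  class(out) <- c("release_schedule", class(out))
  out
}

# plain labelled matrix -> connectivity graph quickly
graph_from_w <- function(W, labels = NULL) {
  if (is.null(labels)) labels <- paste0("n", seq_len(nrow(W)))
  dimnames(W) <- list(labels, labels)
  structure(list(labels = labels, W = W, symmetrization = "mean"),
            class = "conn_graph")
}

# all set partitions of n elements (restricted growth strings); cached
.partition_cache <- new.env(parent = emptyenv())
partitions_of <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  res <- list()
  rec <- function(pre, mx) {
    if (length(pre) == n) {
      res[[length(res) + 1]] <<- pre + 1L
      return()
    }
    for (v in 0:(mx + 1)) rec(c(pre, v), max(mx, v))
  }
  rec(0L, 0L)
  .partition_cache[[key]] <- res
  res
}

# maximum weighted modularity over all partitions (brute force), using the
# community-sum form Q = sum_c [W_cc / 2m - (k_c / 2m)^2]
exhaustive_max_q <- function(W) {
  m2 <- sum(W)
  k <- rowSums(W)
  best <- -Inf
  for (p in partitions_of(nrow(W))) {
    wcc <- sum(vapply(split(seq_along(p), p), function(ix) {
      sum(W[ix, ix])
    }, numeric(1)))
    kc <- vapply(split(k, p), sum, numeric(1))
    q <- wcc / m2 - sum((kc / m2)^2)
    if (q > best) best <- q
  }
  best
}

# connected weighted graph with planted 2-3 block structure: strong within
# weights, sparse weak between weights
planted_graph <- function(n) {
  ng <- sample(2:min(3, n %/% 2), 1)
  memb <- sort(rep_len(seq_len(ng), n))
  W <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    w <- if (memb[i] == memb[j]) {
      runif(1, 0.6, 1)
    } else if (runif(1) < 0.5) {
      runif(1, 0, 0.25)
    } else {
      0
    }
    W[i, j] <- W[j, i] <- w
  }
  repeat {
    reach <- seadrift:::graph_connected(W)
    if (all(reach)) break
    i <- which(!reach)[1]
    j <- sample(which(reach), 1)
    W[i, j] <- W[j, i] <- runif(1, 0, 0.25)
  }
  graph_from_w(W)
}
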