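#' Build a release schedule for coastal cells
#'
#' One particle release per eligible cell per release time. Eligible cells are
#' those with rocky substrate (`rock` or `both`) when `rocky_only = TRUE`,
#' since the limpets whose larvae the particles emulate live on rocky shores.
#' Simulation time 0 is Jan 1, 00:00 of year 1; years are 365 days. The
#' default season (August-December, months 8-12, 153 days) is the spawning
#' window assumed for the dispersal analysis.
#'
#' @param coast Coastal-cell tibble.
#' @param season `c(start_month, end_month)` (inclusive), or `NULL` to release
#'   on every day of the year (useful for toy runs that start at time 0).
#' @param interval_hours Hours between releases; must divide 24.
#' @param years Number of years to repeat the season.
#' @param rocky_only Keep only cells with substrate in `rock`/`both`.
#' @param max_hours Optional cap: drop release times at or beyond this limit
#'   (e.g. the extent of a short synthetic current record).
#' @return A `release_schedule`: tibble with `cell_id` and `time_h`, sorted by
#'   time, with the release interval recorded as an attribute.
#' @examples
#' g <- grid_spec(-1, 1, -1, 1, resolution = 0.05)
#' coast <- make_archipelago(1, g, c(0.15, 0.2), c(rock = 1), seed = 2)
#' sched <- schedule_releases(coast, season = NULL, years = 1, max_hours = 48)
#' nrow(sched)
#' @export
schedule_releases <- function(coast, season = c(8, 12), interval_hours = 12,
                              years = 1, rocky_only = TRUE, max_hours = NULL) {
  if (nrow(coast) == 0) abort("`coast` is empty")
  if (24 %% interval_hours != 0) abort("`interval_hours` must divide 24")
  cells <- if (rocky_only) {
    filter(coast, .data$substrate %in% c("rock", "both"))
  } else {
    coast
  }
  if (nrow(cells) == 0) abort("no eligible release cells (all shores are sand?)")
  days <- if (is.null(season)) {
    seq_len(365L)
  } else {
    month_start <- cumsum(c(0, c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30)))
    month_len <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
    if (season[1] < 1 || season[2] > 12 || season[1] > season[2]) {
      abort("`season` must be c(start_month, end_month) with 1 <= start <= end <= 12")
    }
    seq(month_start[season[1]] + 1L, month_start[season[2]] + month_len[season[2]])
  }
  per_day <- seq(0, 24 - interval_hours, by = interval_hours)
  times <- as.vector(outer(
    per_day,
    as.vector(outer((days - 1) * 24, (seq_len(years) - 1) * 365 * 24, "+")),
    "+"
  ))
  if (!is.null(max_hours)) times <- times[times < max_hours]
  if (length(times) == 0) abort("no release times inside the requested window")
  out <- tidyr::expand_grid(time_h = sort(times), cell_id = cells$cell_id) %>%
    select("cell_id", "time_h") %>%
    arrange(.data$time_h, .data$cell_id)
  attr(out, "interval_hours") <- interval_hours
  class(out) <- c("release_schedule", class(out))
  out
}

# bilinear (space) + linear (time) velocity interpolation; vectorised over
# positions. Returns m/s; NA outside the grid or the time record.
field_velocity <- function(field, lon, lat, t_h) {
  g <- field$grid
  lons <- grid_lons(g); lats <- grid_lats(g)
  # clamp to the outermost cell-center frame; positions beyond it are outside
  fx <- (lon - lons[1]) / g$resolution
  fy <- (lat - lats[1]) / g$resolution
  outside <- fx < -0.5 | fx > g$n_lon - 0.5 | fy < -0.5 | fy > g$n_lat - 0.5 |
    t_h < field$times[1] | t_h > field$times[length(field$times)]
  fx <- pmin(pmax(fx, 0), g$n_lon - 1)
  fy <- pmin(pmax(fy, 0), g$n_lat - 1)
  ix <- pmin(floor(fx), g$n_lon - 2); wx <- fx - ix
  iy <- pmin(floor(fy), g$n_lat - 2); wy <- fy - iy
  if (g$n_lon < 2 || g$n_lat < 2) abort("current grid needs at least 2x2 cells")
  ft <- (t_h - field$times[1]) / (field$times[2] - field$times[1])
  ft <- pmin(pmax(ft, 0), length(field$times) - 1)
  it <- pmin(floor(ft), length(field$times) - 2); wt <- ft - it
  bil <- function(arr, it) {
    i <- it + 1L
    a11 <- arr[cbind(i, iy + 1L, ix + 1L)]
    a12 <- arr[cbind(i, iy + 1L, ix + 2L)]
    a21 <- arr[cbind(i, iy + 2L, ix + 1L)]
    a22 <- arr[cbind(i, iy + 2L, ix + 2L)]
    (1 - wy) * ((1 - wx) * a11 + wx * a12) + wy * ((1 - wx) * a21 + wx * a22)
  }
  if (length(field$times) == 1) {
    u <- bil(field$u, it * 0); v <- bil(field$v, it * 0)
  } else {
    u <- (1 - wt) * bil(field$u, it) + wt * bil(field$u, it + 1L)
    v <- (1 - wt) * bil(field$v, it) + wt * bil(field$v, it + 1L)
  }
  u[outside] <- NA_real_; v[outside] <- NA_real_
  list(u = u, v = v)
}

# m/s -> degrees/hour at a given latitude
deg_per_hour <- function(u, v, lat) {
  list(
    dlon = u * 3600 / (.M_PER_DEG * cos(lat * pi / 180)),
    dlat = v * 3600 / .M_PER_DEG
  )
}

#' Advect a passive particle through a current field
#'
#' Integrates the drift trajectory with a fourth-order Runge-Kutta scheme,
#' using bilinear spatial and linear temporal interpolation of the gridded
#' velocities; metres per second are converted to degrees per hour with the
#' local metric (longitude scaled by `cos(latitude)`). The particle terminates
#' on first *entry* into a coastal cell other than the one it currently
#' occupies, or into a land cell (fate `"landed"`), or after `max_days`
#' adrift (fate `"expired"`). Leaving the current-field domain expires the
#' particle with `out_of_domain = TRUE` rather than raising an error.
#'
#' @param start `c(lon, lat)` release position (degrees).
#' @param t0 Release time, hours since the start of the field record.
#' @param field A `current_field`.
#' @param step_hours Integration step (<= the field's time step).
#' @param max_days Maximum pelagic drift time (days), e.g. 4 or 30.
#' @param coast Coastal-cell tibble (with `grid` and optionally `land`
#'   attributes) defining landing targets.
#' @param record_trajectory Keep the sampled positions?
#' @return A list: `fate` (`"landed"`/`"expired"`), `out_of_domain`, landing
#'   info (`dest_cell`, `dest_island`, `lon`, `lat`), `drift_hours`, and
#'   `trajectory` (tibble of `time_h`, `lon`, `lat`, or `NULL`).
#' @export
advect <- function(start, t0, field, step_hours = 1, max_days, coast,
                   record_trajectory = FALSE) {
  if (length(field$times) > 1 && step_hours > (field$times[2] - field$times[1])) {
    abort("`step_hours` must not exceed the field's time step")
  }
  cg <- attr(coast, "grid")
  if (is.null(cg)) abort("`coast` must carry its grid attribute for landing checks")
  land <- attr(coast, "land")
  if (!is.null(land) && !identical(dim(land), c(cg$n_lat, cg$n_lon))) {
    abort("`land` attribute dimensions do not match the coast grid")
  }
  coast_lookup <- coast_cell_lookup(coast, cg)

  lon <- start[1]; lat <- start[2]
  pos0 <- grid_locate(cg, lon, lat)
  prev_cell <- if (!is.na(pos0$row[1])) grid_cell_id(cg, pos0$row, pos0$col) else NA_integer_
  n_steps <- ceiling(max_days * 24 / step_hours)
  traj <- if (record_trajectory) {
    list(time_h = numeric(n_steps + 1), lon = numeric(n_steps + 1), lat = numeric(n_steps + 1))
  } else {
    NULL
  }
  if (record_trajectory) {
    traj$time_h[1] <- t0; traj$lon[1] <- lon; traj$lat[1] <- lat
  }
  t <- t0
  fate <- "expired"; out_of_domain <- FALSE
  dest_cell <- NA_integer_; dest_island <- NA_integer_
  for (s in seq_len(n_steps)) {
    h <- min(step_hours, t0 + max_days * 24 - t)
    if (h <= 0) break
    nxt <- rk4_step(field, lon, lat, t, h)
    if (!is.finite(nxt$lon) || !is.finite(nxt$lat)) {
      out_of_domain <- TRUE
      break
    }
    lon <- nxt$lon; lat <- nxt$lat; t <- t + h
    if (record_trajectory) {
      traj$time_h[s + 1] <- t; traj$lon[s + 1] <- lon; traj$lat[s + 1] <- lat
    }
    pos <- grid_locate(cg, lon, lat)
    if (is.na(pos$row[1])) next # outside the (finer) coastal grid: open ocean
    cell <- grid_cell_id(cg, pos$row, pos$col)
    is_land <- !is.null(land) && land[pos$row[1], pos$col[1]]
    at_coast <- !is.na(coast_lookup[cell])
    if (is_land || (at_coast && !identical(cell, prev_cell))) {
      if (at_coast) {
        hit <- coast_lookup[cell]
      } else {
        hit <- nearest_coast_cell(coast, lon, lat)
      }
      fate <- "landed"
      dest_cell <- coast$cell_id[hit]
      dest_island <- coast$island[hit]
      break
    }
    prev_cell <- cell
  }
  if (record_trajectory) {
    keep <- seq_len(if (fate == "landed" || out_of_domain) s + 1 else n_steps + 1)
    keep <- keep[keep <= length(traj$time_h)]
    traj <- tibble(time_h = traj$time_h[keep], lon = traj$lon[keep], lat = traj$lat[keep])
  }
  list(
    fate = fate, out_of_domain = out_of_domain,
    dest_cell = dest_cell, dest_island = dest_island,
    lon = lon, lat = lat, drift_hours = t - t0,
    trajectory = traj
  )
}

# one RK4 step of h hours; returns NA position if any stage leaves the field
rk4_step <- function(field, lon, lat, t, h) {
  vel <- function(lo, la, tt) {
    uv <- field_velocity(field, lo, la, tt)
    deg_per_hour(uv$u, uv$v, la)
  }
  k1 <- vel(lon, lat, t)
  if (!is.finite(k1$dlon)) return(list(lon = NA_real_, lat = NA_real_))
  k2 <- vel(lon + h / 2 * k1$dlon, lat + h / 2 * k1$dlat, t + h / 2)
  if (!is.finite(k2$dlon)) return(list(lon = NA_real_, lat = NA_real_))
  k3 <- vel(lon + h / 2 * k2$dlon, lat + h / 2 * k2$dlat, t + h / 2)
  if (!is.finite(k3$dlon)) return(list(lon = NA_real_, lat = NA_real_))
  k4 <- vel(lon + h * k3$dlon, lat + h * k3$dlat, t + h)
  if (!is.finite(k4$dlon)) return(list(lon = NA_real_, lat = NA_real_))
  list(
    lon = lon + h / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon),
    lat = lat + h / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
  )
}

# vector mapping linear grid cell id -> row index into `coast`, NA elsewhere
coast_cell_lookup <- function(coast, grid) {
  lookup <- rep(NA_integer_, grid$n_lat * grid$n_lon)
  lookup[coast$cell_id] <- seq_len(nrow(coast))
  lookup
}

nearest_coast_cell <- function(coast, lon, lat) {
  which.min((coast$lon - lon)^2 + (coast$lat - lat)^2)
}

#' Run a Lagrangian dispersal simulation
#'
#' Releases one passive particle per schedule entry from the centroid of its
#' coastal cell and advects it until landing or until the maximum pelagic
#' larval duration. Advection is deterministic; the seed is used only for the
#' optional sub-cell release jitter (off by default).
#'
#' @param coast Coastal-cell tibble.
#' @param field A `current_field`.
#' @param schedule A `release_schedule` (its times must fall inside the field
#'   record).
#' @param max_days Maximum drift time in days (the assumed PLD).
#' @param step_hours RK4 integration step in hours.
#' @param jitter_sd Standard deviation (degrees) of Gaussian release jitter.
#' @param seed Seed for the jitter.
#' @param record_trajectories Keep per-particle trajectories (memory-hungry).
#' @return A tibble of dispersal events, one row per released particle:
#'   `particle_id`, `source_cell`, `source_island`, `dest_cell`,
#'   `dest_island`, `drift_days`, `distance_km` (great-circle, release point
#'   to landing point), `fate`, `out_of_domain`. When trajectories are
#'   recorded they are attached as a list attribute `trajectories`.
#' @export
run_simulation <- function(coast, field, schedule, max_days, step_hours = 1,
                           jitter_sd = 0, seed = 1L,
                           record_trajectories = FALSE) {
  if (max(schedule$time_h) >= max(field$times)) {
    abort("release schedule extends beyond the current-field record")
  }
  cells <- match(schedule$cell_id, coast$cell_id)
  if (anyNA(cells)) abort("schedule contains cell_ids absent from `coast`")
  n <- nrow(schedule)
  jit_lon <- jit_lat <- numeric(n)
  if (jitter_sd > 0) {
    withr::with_seed(as.integer(seed), {
      jit_lon <- rnorm(n, 0, jitter_sd)
      jit_lat <- rnorm(n, 0, jitter_sd)
    })
  }
  res <- vector("list", n)
  trajs <- if (record_trajectories) vector("list", n) else NULL
  for (i in seq_len(n)) {
    ci <- cells[i]
    a <- advect(
      start = c(coast$lon[ci] + jit_lon[i], coast$lat[ci] + jit_lat[i]),
      t0 = schedule$time_h[i], field = field, step_hours = step_hours,
      max_days = max_days, coast = coast,
      record_trajectory = record_trajectories
    )
    res[[i]] <- tibble(
      particle_id = i,
      source_cell = coast$cell_id[ci],
      source_island = coast$island[ci],
      dest_cell = if (a$fate == "landed") a$dest_cell else NA_integer_,
      dest_island = if (a$fate == "landed") a$dest_island else NA_integer_,
      drift_days = if (a$fate == "landed") a$drift_hours / 24 else NA_real_,
      distance_km = if (a$fate == "landed") {
        geosphere::distHaversine(
          c(coast$lon[ci], coast$lat[ci]), c(a$lon, a$lat)
        ) / 1000
      } else {
        NA_real_
      },
      fate = a$fate,
      out_of_domain = a$out_of_domain
    )
    if (record_trajectories) trajs[[i]] <- a$trajectory
  }
  out <- bind_rows(res)
  if (record_trajectories) attr(out, "trajectories") <- trajs
  out
}

#' Read and write dispersal event tables
#'
#' Plain CSV with one row per particle, the format produced by
#' [run_simulation()].
#'
#' @param events Event tibble.
#' @param path File path.
#' @return `read_events()` returns the tibble; `write_events()` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    particle_id = readr::col_integer(),
    source_cell = readr::col_integer(),
    source_island = readr::col_integer(),
    dest_cell = readr::col_integer(),
    dest_island = readr::col_integer(),
    drift_days = readr::col_double(),
    distance_km = readr::col_double(),
    fate = readr::col_character(),
    out_of_domain = readr::col_logical()
  ))
}
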