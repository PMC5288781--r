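#' Generate a synthetic ocean current field
#'
#' Builds a time-varying surface velocity field on a regular grid from a
#' streamfunction: a sum of Gaussian gyre bumps plus a linear term for a mean
#' background flow. Velocities are obtained as the discrete central-difference
#' curl of the streamfunction sampled at cell centers, which makes the discrete
#' divergence of `(u, v)` vanish identically at interior cells (central
#' difference operators commute). Optional seeded Gaussian noise makes the
#' field time-varying and is the only stochastic ingredient.
#'
#' The planar metric uses a fixed reference latitude (the grid mid-latitude),
#' so a gyre's circulation is solid-body-like near its core and analytic
#' streamlines (circles around the gyre center) serve as advection oracles.
#'
#' @param grid A [grid_spec()] for the current grid.
#' @param duration_days Length of the simulated record, in days.
#' @param time_step_hours Time step between stored fields, in hours.
#' @param gyres List of gyres, each a list with `center = c(lon, lat)`
#'   (degrees), `radius` (degrees; the radius of peak azimuthal speed) and
#'   `peak_speed` (m/s, <= 3).
#' @param mean_flow Background flow `c(u0, v0)` in m/s.
#' @param noise_sd Standard deviation (m/s) of i.i.d. Gaussian noise added to
#'   every velocity sample; `0` keeps the field exactly divergence-free.
#' @param seed Integer seed for the noise.
#' @param land_mask Optional logical matrix `[lat, lon]` marking land cells.
#' @return A `current_field` object: list with `grid`, `times` (hours since
#'   start), velocity arrays `u`, `v` indexed `[time, lat, lon]` (m/s), and
#'   `land_mask`.
#' @examples
#' g <- grid_spec(-2, 2, -2, 2, resolution = 0.1)
#' f <- make_current_field(g, duration_days = 2, time_step_hours = 24,
#'   gyres = list(list(center = c(0, 0), radius = 0.5, peak_speed = 0.4)))
#' max(abs(field_divergence(f)))
#' @export
make_current_field <- function(grid, duration_days, time_step_hours = 24,
                               gyres = list(), mean_flow = c(0, 0),
                               noise_sd = 0, seed = 1L, land_mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (duration_days <= 0) abort("`duration_days` must be positive")
  if (time_step_hours <= 0) abort("`time_step_hours` must be positive")
  for (gy in gyres) {
    if (!all(c("center", "radius", "peak_speed") %in% names(gy))) {
      abort("each gyre needs `center`, `radius` and `peak_speed`")
    }
    if (gy$peak_speed > 3) abort("gyre `peak_speed` above 3 m/s is not a plausible ocean speed")
    if (gy$radius <= 0) abort("gyre `radius` must be positive")
  }
  times <- seq(0, duration_days * 24, by = time_step_hours)
  lons <- grid_lons(grid)
  lats <- grid_lats(grid)
  lat_ref <- (grid$lat_min + grid$lat_max) / 2
  mx <- .M_PER_DEG * cos(lat_ref * pi / 180) # metres per deg lon
  my <- .M_PER_DEG                           # metres per deg lat

  # streamfunction on cell centers, in m^2/s, on the local plane
  x <- lons * mx
  y <- lats * my
  psi <- outer(y, x, function(yy, xx) mean_flow[2] * xx - mean_flow[1] * yy)
  for (gy in gyres) {
    xc <- gy$center[1] * mx; yc <- gy$center[2] * my
    sigma <- gy$radius * my # radius quoted in degrees of latitude
    amp <- gy$peak_speed * sigma * exp(0.5)
    psi <- psi + outer(y, x, function(yy, xx) {
      amp * exp(-((xx - xc)^2 + (yy - yc)^2) / (2 * sigma^2))
    })
  }

  # discrete curl: u = -dpsi/dy, v = dpsi/dx (central; one-sided at edges)
  u0 <- -ddiff(psi, along = "row") / my / grid$resolution
  v0 <- ddiff(psi, along = "col") / mx / grid$resolution

  nt <- length(times)
  u <- array(rep(u0, each = nt), dim = c(nt, grid$n_lat, grid$n_lon))
  v <- array(rep(v0, each = nt), dim = c(nt, grid$n_lat, grid$n_lon))
  if (noise_sd > 0) {
    withr::with_seed(as.integer(seed), {
      u <- u + array(rnorm(length(u), 0, noise_sd), dim = dim(u))
      v <- v + array(rnorm(length(v), 0, noise_sd), dim = dim(v))
    })
  }
  if (is.null(land_mask)) {
    land_mask <- matrix(FALSE, grid$n_lat, grid$n_lon)
  }
  stopifnot(nrow(land_mask) == grid$n_lat, ncol(land_mask) == grid$n_lon)
  structure(
    list(grid = grid, times = times, u = u, v = v, land_mask = land_mask),
    class = "current_field"
  )
}

# central difference along rows (lat) or cols (lon), one-sided at the edges;
# returns the difference per *cell index*, caller divides by the step
ddiff <- function(m, along = c("row", "col")) {
  along <- match.arg(along)
  n <- if (along == "row") nrow(m) else ncol(m)
  if (n < 2) abort("grid too small for finite differences")
  d <- m * 0
  if (along == "row") {
    d[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
    d[1, ] <- m[2, ] - m[1, ]
    d[n, ] <- m[n, ] - m[n - 1, ]
  } else {
    d[, 2:(n - 1)] <- (m[, 3:n] - m[, 1:(n - 2)]) / 2
    d[, 1] <- m[, 2] - m[, 1]
    d[, n] <- m[, n] - m[, n - 1]
  }
  d
}

#' @export
print.current_field <- function(x, ...) {
  cat(sprintf(
    "<current_field> %d time steps x %d x %d cells, t in [0, %g] h, max speed %.3g m/s\n",
    length(x$times), x$grid$n_lat, x$grid$n_lon, max(x$times),
    max(sqrt(x$u^2 + x$v^2))
  ))
  invisible(x)
}

#' Discrete divergence of a current field
#'
#' Central-difference divergence du/dx + dv/dy (1/s) at interior cells, for
#' the first stored time slice by default. Used to verify that noise-free
#' synthetic fields are non-divergent.
#'
#' @param field A `current_field`.
#' @param time_index Which stored time slice to evaluate.
#' @return Matrix `[lat, lon]` of divergence values at interior cells (edge
#'   rows/columns are dropped).
#' @export
field_divergence <- function(field, time_index = 1L) {
  grid <- field$grid
  lat_ref <- (grid$lat_min + grid$lat_max) / 2
  mx <- .M_PER_DEG * cos(lat_ref * pi / 180)
  my <- .M_PER_DEG
  u <- field$u[time_index, , ]
  v <- field$v[time_index, , ]
  dudx <- ddiff(u, "col") / mx / grid$resolution
  dvdy <- ddiff(v, "row") / my / grid$resolution
  div <- dudx + dvdy
  div[2:(grid$n_lat - 1), 2:(grid$n_lon - 1), drop = FALSE]
}

#' Read and write current fields as gridded text
#'
#' A self-describing plain-text layout with the dimensions and variables of a
#' gridded ocean product: a header with the grid and time axis, then one block
#' per variable (`u`, `v` in m/s, `land_mask`) and time slice, each block a
#' `lat x lon` matrix of values in full double precision.
#'
#' @param field A `current_field`.
#' @param path File path.
#' @return `read_current_field()` returns the `current_field`;
#'   `write_current_field()` returns `path` invisibly.
#' @export
write_current_field <- function(field, path) {
  g <- field$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# seadrift current field v1",
    sprintf("grid %.17g %.17g %.17g %.17g %.17g", g$lon_min, g$lon_max,
            g$lat_min, g$lat_max, g$resolution),
    paste("times", paste(sprintf("%.17g", field$times), collapse = " "))
  ), con)
  fmt_slice <- function(m) apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  for (ti in seq_along(field$times)) {
    writeLines(sprintf("u %d", ti), con)
    writeLines(fmt_slice(field$u[ti, , ]), con)
    writeLines(sprintf("v %d", ti), con)
    writeLines(fmt_slice(field$v[ti, , ]), con)
  }
  writeLines("land_mask", con)
  writeLines(apply(field$land_mask, 1, function(r) paste(as.integer(r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_current_field
#' @export
read_current_field <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "# seadrift current field v1")) {
    abort("not a seadrift current field file")
  }
  gl <- as.numeric(strsplit(sub("^grid ", "", lines[2]), " ")[[1]])
  grid <- grid_spec(gl[1], gl[2], gl[3], gl[4], gl[5])
  times <- as.numeric(strsplit(sub("^times ", "", lines[3]), " ")[[1]])
  nt <- length(times)
  u <- array(NA_real_, c(nt, grid$n_lat, grid$n_lon))
  v <- array(NA_real_, c(nt, grid$n_lat, grid$n_lon))
  i <- 4L
  parse_block <- function(at) {
    block <- lines[at:(at + grid$n_lat - 1L)]
    t(vapply(strsplit(block, " "), as.numeric, numeric(grid$n_lon)))
  }
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], " ")[[1]]
    if (hdr[1] %in% c("u", "v")) {
      ti <- as.integer(hdr[2])
      m <- parse_block(i + 1L)
      if (hdr[1] == "u") u[ti, , ] <- m else v[ti, , ] <- m
      i <- i + 1L + grid$n_lat
    } else if (hdr[1] == "land_mask") {
      m <- parse_block(i + 1L)
      land_mask <- m > 0
      i <- i + 1L + grid$n_lat
    } else {
      abort(paste0("unrecognised block header at line ", i, ": ", lines[i]))
    }
  }
  structure(
    list(grid = grid, times = times, u = u, v = v, land_mask = land_mask),
    class = "current_field"
  )
}
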