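#' Generate a synthetic archipelago of coastal cells
#'
#' Places `n_islands` non-overlapping, roughly circular islands on a grid and
#' returns the ring of coastal cells around each one. Coastal cells are the
#' ocean cells 8-adjacent to land, so every island presents a closed shoreline
#' that drifting particles can reach from any direction. Each coastal cell
#' carries a substrate label (`rock`, `sand` or `both`) drawn from
#' `substrate_mix`, emulating a shore-substrate survey raster.
#'
#' @param n_islands Number of islands (>= 1).
#' @param grid A [grid_spec()] for the coastal grid.
#' @param island_radius_range Island radius bounds in degrees,
#'   `c(min, max)`; radii are drawn uniformly.
#' @param substrate_mix Named probabilities for `rock`, `sand`, `both`
#'   (normalised internally; missing classes get probability 0).
#' @param seed Integer seed; the result is bit-reproducible for a fixed seed.
#' @param max_retries Placement attempts per island before giving up.
#' @return A tibble with one row per coastal cell: `cell_id`, `lon`, `lat`,
#'   `island` (integer id), `substrate`. Attributes: `grid` (the grid spec) and
#'   `land` (logical land-mask matrix indexed `[lat, lon]`).
#' @examples
#' g <- grid_spec(-1, 1, -1, 1, resolution = 0.05)
#' coast <- make_archipelago(2, g, c(0.1, 0.2), c(rock = 0.6, sand = 0.4), seed = 1)
#' dplyr::count(coast, island)
#' @export
make_archipelago <- function(n_islands, grid,
                             island_radius_range = c(0.05, 0.15),
                             substrate_mix = c(rock = 0.5, sand = 0.3, both = 0.2),
                             seed = 1L,
                             max_retries = 200L) {
  stopifnot(inherits(grid, "grid_spec"))
  if (n_islands < 1) abort("`n_islands` must be >= 1")
  if (length(island_radius_range) != 2 || any(island_radius_range <= 0)) {
    abort("`island_radius_range` must be two positive radii in degrees")
  }
  mix <- substrate_classes(substrate_mix)

  withr::with_seed(as.integer(seed), {
    centers <- place_islands(n_islands, grid, island_radius_range, max_retries)
    lons <- grid_lons(grid)
    lats <- grid_lats(grid)
    land <- matrix(0L, nrow = grid$n_lat, ncol = grid$n_lon) # island id or 0
    for (k in seq_len(n_islands)) {
      d2 <- outer(
        (lats - centers$lat[k])^2,
        (lons - centers$lon[k])^2, "+"
      )
      land[d2 <= centers$radius[k]^2] <- k
    }
    coast <- coastal_ring(land)
    if (!all(seq_len(n_islands) %in% coast$island)) {
      missing_isl <- setdiff(seq_len(n_islands), unique(coast$island))
      abort(paste0(
        "island(s) ", paste(missing_isl, collapse = ", "),
        " produced no coastal cells; radius below the grid resolution?"
      ))
    }
    substrate <- sample(names(mix), length(coast$row), replace = TRUE, prob = mix)
    out <- tibble(
      cell_id = grid_cell_id(grid, coast$row, coast$col),
      lon = lons[coast$col],
      lat = lats[coast$row],
      island = coast$island,
      substrate = substrate
    ) %>%
      arrange(.data$cell_id)
    attr(out, "grid") <- grid
    attr(out, "land") <- land > 0L
    out
  })
}

# normalise a substrate mix to the three canonical classes
substrate_classes <- function(mix) {
  classes <- c("rock", "sand", "both")
  if (is.null(names(mix)) || !all(names(mix) %in% classes)) {
    abort("`substrate_mix` must be named with classes among 'rock', 'sand', 'both'")
  }
  full <- setNames(numeric(3), classes)
  full[names(mix)] <- mix
  if (sum(full) <= 0) abort("`substrate_mix` probabilities must sum to > 0")
  full / sum(full)
}

# rejection-sample island centers and radii that fit with clearance
place_islands <- function(n_islands, grid, radius_range, max_retries) {
  margin <- 2 * grid$resolution
  lon <- lat <- radius <- numeric(0)
  for (k in seq_len(n_islands)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      r <- runif(1, radius_range[1], radius_range[2])
      x <- runif(1, grid$lon_min + r + margin, grid$lon_max - r - margin)
      y <- runif(1, grid$lat_min + r + margin, grid$lat_max - r - margin)
      if (!is.finite(x) || !is.finite(y)) break # island larger than the grid
      ok <- all(sqrt((lon - x)^2 + (lat - y)^2) > radius + r + 2 * margin)
      if (ok) {
        lon <- c(lon, x); lat <- c(lat, y); radius <- c(radius, r)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(paste0(
        "could not place island ", k, " of ", n_islands, " after ", max_retries,
        " retries: islands must fit inside the grid without overlap; ",
        "enlarge the grid or shrink `island_radius_range`"
      ))
    }
  }
  list(lon = lon, lat = lat, radius = radius)
}

# ocean cells 8-adjacent to land, labelled with the adjacent island's id
coastal_ring <- function(land) {
  n_lat <- nrow(land); n_lon <- ncol(land)
  rows <- cols <- isl <- integer(0)
  land_idx <- which(land > 0L, arr.ind = TRUE)
  seen <- matrix(FALSE, n_lat, n_lon)
  for (i in seq_len(nrow(land_idx))) {
    r0 <- land_idx[i, 1]; c0 <- land_idx[i, 2]
    id <- land[r0, c0]
    for (dr in -1:1) for (dc in -1:1) {
      r <- r0 + dr; c <- c0 + dc
      if (r < 1 || r > n_lat || c < 1 || c > n_lon) next
      if (land[r, c] == 0L && !seen[r, c]) {
        seen[r, c] <- TRUE
        rows <- c(rows, r); cols <- c(cols, c); isl <- c(isl, id)
      }
    }
  }
  list(row = rows, col = cols, island = as.integer(isl))
}

#' Quantify shore substrate composition per island
#'
#' Tallies coastal cells by substrate class for each island and converts counts
#' to shoreline lengths (km) and percentages. Percentages are taken over each
#' island's own coastal cells, so `pct_rock + pct_sand + pct_both = 100`.
#'
#' @param coast A coastal-cell tibble as returned by [make_archipelago()] or
#'   [read_coast_grid()].
#' @param cell_length_km Shoreline length one cell represents, in km. Default:
#'   the great-circle length of one grid cell side at the island's mean
#'   latitude (requires the `grid` attribute).
#' @return A tibble with one row per island: counts `n_rock`, `n_sand`,
#'   `n_both`, lengths `length_rock_km`, `length_sand_km`, `length_both_km`,
#'   and percentages `pct_rock`, `pct_sand`, `pct_both`.
#' @export
substrate_summary <- function(coast, cell_length_km = NULL) {
  if (nrow(coast) == 0) abort("`coast` is empty")
  bad <- !coast$substrate %in% c("rock", "sand", "both")
  if (any(bad)) {
    abort(paste0(
      "unknown substrate label '", coast$substrate[which(bad)[1]],
      "' in cell ", coast$cell_id[which(bad)[1]]
    ))
  }
  grid <- attr(coast, "grid")
  if (is.null(cell_length_km) && is.null(grid)) {
    abort("supply `cell_length_km` when `coast` carries no grid attribute")
  }
  coast %>%
    group_by(.data$island) %>%
    summarise(
      n_rock = sum(.data$substrate == "rock"),
      n_sand = sum(.data$substrate == "sand"),
      n_both = sum(.data$substrate == "both"),
      mean_lat = mean(.data$lat),
      .groups = "drop"
    ) %>%
    mutate(
      cell_km = if (!is.null(cell_length_km)) cell_length_km else
        cell_side_km(grid$resolution, .data$mean_lat),
      length_rock_km = .data$n_rock * .data$cell_km,
      length_sand_km = .data$n_sand * .data$cell_km,
      length_both_km = .data$n_both * .data$cell_km,
      n_total = .data$n_rock + .data$n_sand + .data$n_both,
      pct_rock = 100 * .data$n_rock / .data$n_total,
      pct_sand = 100 * .data$n_sand / .data$n_total,
      pct_both = 100 * .data$n_both / .data$n_total
    ) %>%
    select(-"mean_lat", -"n_total", -"cell_km")
}

# great-circle length (km) of one east-west cell side at a given latitude
cell_side_km <- function(resolution_deg, lat) {
  vapply(lat, function(phi) {
    geosphere::distHaversine(
      c(0, phi), c(resolution_deg, phi)
    ) / 1000
  }, numeric(1))
}

#' Read and write coastal cell grids as delimited text
#'
#' The on-disk format is a plain CSV with columns `cell_id`, `lon`, `lat`,
#' `island`, `substrate`. `write_coast_grid()` stores the grid bounds in
#' comment headers so the grid specification round-trips.
#'
#' @param coast Coastal-cell tibble.
#' @param path File path.
#' @return `read_coast_grid()` returns the coastal-cell tibble (with `grid`
#'   attribute when present in the file); `write_coast_grid()` returns `path`
#'   invisibly.
#' @export
write_coast_grid <- function(coast, path) {
  grid <- attr(coast, "grid")
  header <- character(0)
  if (!is.null(grid)) {
    header <- sprintf(
      "# grid %.10g %.10g %.10g %.10g %.10g",
      grid$lon_min, grid$lon_max, grid$lat_min, grid$lat_max, grid$resolution
    )
  }
  body <- c(
    header,
    paste(c("cell_id", "lon", "lat", "island", "substrate"), collapse = ","),
    sprintf(
      "%d,%.10g,%.10g,%d,%s",
      coast$cell_id, coast$lon, coast$lat, coast$island, coast$substrate
    )
  )
  writeLines(body, path)
  invisible(path)
}

#' @rdname write_coast_grid
#' @export
read_coast_grid <- function(path) {
  lines <- readLines(path)
  grid <- NULL
  gl <- grep("^# grid ", lines, value = TRUE)
  if (length(gl) == 1) {
    nums <- as.numeric(strsplit(sub("^# grid ", "", gl), " ")[[1]])
    grid <- grid_spec(nums[1], nums[2], nums[3], nums[4], nums[5])
  }
  out <- readr::read_csv(
    I(lines[!startsWith(lines, "#")]),
    col_types = readr::cols(
      cell_id = readr::col_integer(),
      lon = readr::col_double(),
      lat = readr::col_double(),
      island = readr::col_integer(),
      substrate = readr::col_character()
    )
  )
  if (anyDuplicated(out$cell_id)) abort("duplicate cell_id in coast grid file")
  attr(out, "grid") <- grid
  out
}
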