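#' Cell-level connectivity probabilities
#'
#' For every scheduled source cell `a` and destination cell `b`, the entry is
#' the number of particles released from `a` that landed on `b`, divided by the
#' number released from `a`. Rows are sources; self-cell landings appear on
#' the diagonal.
#'
#' @param events Dispersal events from [run_simulation()].
#' @param schedule The `release_schedule` the events came from (provides the
#'   release denominators).
#' @return A square numeric matrix with dimnames = cell ids (all scheduled
#'   cells plus any landing cells), rows = source.
#' @export
cell_connectivity <- function(events, schedule) {
  released <- count(as_tibble(schedule), .data$cell_id, name = "n_released")
  if (any(released$n_released == 0)) abort("schedule lists a cell with zero releases")
  bad <- setdiff(unique(events$source_cell), released$cell_id)
  if (length(bad)) {
    abort(paste0("events contain source cells absent from the schedule: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  landed <- filter(events, .data$fate == "landed")
  cells <- sort(union(released$cell_id, landed$dest_cell))
  P <- matrix(0, length(cells), length(cells), dimnames = list(cells, cells))
  if (nrow(landed) > 0) {
    tallies <- count(landed, .data$source_cell, .data$dest_cell)
    P[cbind(
      match(tallies$source_cell, cells),
      match(tallies$dest_cell, cells)
    )] <- tallies$n
  }
  denom <- setNames(rep(NA_real_, length(cells)), cells)
  denom[as.character(released$cell_id)] <- released$n_released
  sweep_rows <- !is.na(denom)
  P[sweep_rows, ] <- P[sweep_rows, , drop = FALSE] / denom[sweep_rows]
  P[!sweep_rows, ] <- NA_real_
  attr(P, "n_released") <- denom
  P
}

#' Island-level connectivity matrix
#'
#' Aggregates a cell-level probability matrix to islands. The default
#' (`method = "mean"`) sets `P[I, J]` to the arithmetic mean, over source
#' cells of island `I`, of each cell's total probability of landing anywhere
#' on island `J` — a mean connectivity matrix. `method = "pooled"` instead
#' weights source cells by their release counts (pooled particle counts).
#'
#' @param cell_matrix Matrix from [cell_connectivity()].
#' @param coast Coastal-cell tibble mapping cells to islands.
#' @param method Aggregation across source cells: `"mean"` or `"pooled"`.
#' @param labels Optional island names (defaults to `island <id>`).
#' @param pld_days,n_released Optional metadata recorded on the result.
#' @return A `connectivity_matrix`: square numeric matrix, rows = source
#'   island, with island labels as dimnames, plus metadata attributes.
#'   Islands with no scheduled source cells get `NA` rows (flagged with a
#'   warning).
#' @export
island_connectivity <- function(cell_matrix, coast, method = c("mean", "pooled"),
                                labels = NULL, pld_days = NULL, n_released = NULL) {
  method <- match.arg(method)
  cells <- as.integer(rownames(cell_matrix))
  isl_of <- coast$island[match(cells, coast$cell_id)]
  if (anyNA(isl_of)) {
    abort(paste0("cells not present in `coast`: ",
                 paste(head(cells[is.na(isl_of)], 5), collapse = ", ")))
  }
  islands <- sort(unique(coast$island))
  if (is.null(labels)) labels <- paste("island", islands)
  if (length(labels) != length(islands)) abort("`labels` must name every island")

  weights <- attr(cell_matrix, "n_released")
  P <- matrix(NA_real_, length(islands), length(islands),
              dimnames = list(labels, labels))
  for (jj in seq_along(islands)) {
    dest_cols <- which(isl_of == islands[jj])
    # per source cell: total probability of landing anywhere on island J
    p_cell <- rowSums(cell_matrix[, dest_cols, drop = FALSE])
    for (ii in seq_along(islands)) {
      src_rows <- which(isl_of == islands[ii] & !is.na(p_cell))
      if (length(src_rows) == 0) next
      P[ii, jj] <- if (method == "mean") {
        mean(p_cell[src_rows])
      } else {
        w <- weights[src_rows]
        sum(p_cell[src_rows] * w) / sum(w)
      }
    }
  }
  if (anyNA(P[row(P) != col(P)])) {
    warn("islands with no scheduled source cells produce NA rows")
  }
  connectivity_matrix(P, pld_days = pld_days, n_released = n_released)
}

#' Construct a connectivity matrix object
#'
#' @param P Square numeric matrix with matching row/column island labels;
#'   rows are source islands. The diagonal (self-recruitment) is kept as
#'   given but ignored by downstream network analysis.
#' @param pld_days,n_released Optional metadata (pelagic larval duration in
#'   days; particles released per source).
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(P, pld_days = NULL, n_released = NULL) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) abort("`P` must be a square matrix")
  if (is.null(rownames(P)) || !identical(rownames(P), colnames(P))) {
    abort("`P` must carry matching row and column island labels")
  }
  if (anyDuplicated(rownames(P))) abort("island labels must be unique")
  off <- P[row(P) != col(P)]
  if (any(off < 0 | off > 1, na.rm = TRUE)) {
    abort("connectivity probabilities must lie in [0, 1]")
  }
  structure(P, class = c("connectivity_matrix", "matrix", "array"),
            pld_days = pld_days, n_released = n_released)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d islands (rows = source)\n", nrow(x)))
  y <- unclass(x)
  attr(y, "pld_days") <- NULL; attr(y, "n_released") <- NULL
  print(signif(y, 3))
  invisible(x)
}

#' @export
as_tibble.connectivity_matrix <- function(x, ...) {
  tibble(
    source = rep(rownames(x), times = ncol(x)),
    dest = rep(colnames(x), each = nrow(x)),
    probability = as.vector(unclass(x))
  ) %>%
    filter(.data$source != .data$dest)
}

#' Summary statistics of effective dispersal
#'
#' Statistics over particles that effectively connected *different* coastal
#' cells: landed events whose destination differs from the source cell
#' (self-cell recruitment excluded). Probability statistics are per connected
#' source-destination cell pair and need the release denominators, so they are
#' filled only when `schedule` is given.
#'
#' @param events Dispersal events.
#' @param schedule Optional `release_schedule` for probability statistics.
#' @return A one-row tibble: `n_events`, then `max/mean/sd` for
#'   `distance_km`, `probability` and `time_days`. All `NA` when no
#'   qualifying event exists.
#' @export
dispersal_summary <- function(events, schedule = NULL) {
  eff <- filter(
    events,
    .data$fate == "landed", .data$dest_cell != .data$source_cell
  )
  out <- tibble(
    n_events = nrow(eff),
    max_distance_km = NA_real_, mean_distance_km = NA_real_, sd_distance_km = NA_real_,
    max_probability = NA_real_, mean_probability = NA_real_, sd_probability = NA_real_,
    max_time_days = NA_real_, mean_time_days = NA_real_, sd_time_days = NA_real_
  )
  if (nrow(eff) == 0) return(out)
  out$max_distance_km <- max(eff$distance_km)
  out$mean_distance_km <- mean(eff$distance_km)
  out$sd_distance_km <- if (nrow(eff) > 1) sd(eff$distance_km) else 0
  out$max_time_days <- max(eff$drift_days)
  out$mean_time_days <- mean(eff$drift_days)
  out$sd_time_days <- if (nrow(eff) > 1) sd(eff$drift_days) else 0
  if (!is.null(schedule)) {
    released <- count(as_tibble(schedule), .data$cell_id, name = "n_released")
    pairs <- eff %>%
      count(.data$source_cell, .data$dest_cell) %>%
      left_join(released, by = c(source_cell = "cell_id")) %>%
      mutate(p = .data$n / .data$n_released)
    out$max_probability <- max(pairs$p)
    out$mean_probability <- mean(pairs$p)
    out$sd_probability <- if (nrow(pairs) > 1) sd(pairs$p) else 0
  }
  out
}

#' Read and write island connectivity matrices
#'
#' The delimited layout of the published tables: a CSV whose first row and
#' first column hold the island labels (rows = source island), with an em
#' dash on the diagonal. `write_connectivity_matrix()` writes full double
#' precision by default so that write-then-read round-trips exactly;
#' `format = "paper"` mimics the tables' `%.2E` presentation.
#'
#' @param path File path.
#' @param matrix A `connectivity_matrix`.
#' @param format `"full"` (default) or `"paper"`.
#' @return `read_connectivity_matrix()` returns a `connectivity_matrix` with
#'   `NA` on the diagonal; the writer returns `path` invisibly.
#' @examples
#' m <- read_connectivity_matrix(seadrift_example("table2_4day.csv"))
#' m["Santo Antao", "Maio"]
#' @export
read_connectivity_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  labels <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (nrow(vals) != ncol(vals)) {
    abort(paste0("matrix in '", path, "' is not square: ",
                 nrow(vals), " rows vs ", ncol(vals), " columns"))
  }
  if (!identical(labels, colnames(vals))) {
    abort(paste0("row labels do not match column labels in '", path, "'"))
  }
  P <- matrix(NA_real_, nrow(vals), ncol(vals), dimnames = list(labels, labels))
  for (i in seq_len(nrow(vals))) for (j in seq_len(ncol(vals))) {
    cell <- trimws(vals[i, j])
    if (i == j) {
      if (!cell %in% c("\u2014", "-", "", NA)) {
        abort(paste0("diagonal cell [", labels[i], ", ", labels[j],
                     "] should be an em dash, got '", cell, "'"))
      }
      next
    }
    x <- suppressWarnings(as.numeric(cell))
    if (is.na(x)) {
      abort(paste0("non-numeric entry '", cell, "' at row '", labels[i],
                   "', column '", labels[j], "'"))
    }
    P[i, j] <- x
  }
  connectivity_matrix(P)
}

#' @rdname read_connectivity_matrix
#' @export
write_connectivity_matrix <- function(matrix, path, format = c("full", "paper")) {
  format <- match.arg(format)
  labels <- rownames(matrix)
  fmt <- function(x) {
    if (is.na(x)) return("\u2014")
    if (format == "paper") sprintf("%.2E", x) else sprintf("%.17g", x)
  }
  body <- vapply(seq_along(labels), function(i) {
    cells <- vapply(seq_along(labels), function(j) {
      if (i == j) "\u2014" else fmt(matrix[i, j])
    }, character(1))
    paste(c(labels[i], cells), collapse = ",")
  }, character(1))
  writeLines(c(paste(c("island", labels), collapse = ","), body), path,
             useBytes = FALSE)
  invisible(path)
}
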