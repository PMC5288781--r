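#' Validated configuration for the dispersal pipeline
#'
#' A single flat list of every knob the pipeline uses, validated up front so
#' a run fails before any computation when mis-configured. Unknown keys are
#' rejected (typos should not silently fall back to defaults).
#'
#' @param ... Overrides for the defaults listed below.
#' @return A `pipeline_config` list.
#' @section Keys:
#' * `seed` integer seed used by every stochastic stage
#' * `lon_min`, `lon_max`, `lat_min`, `lat_max`, `coast_resolution`,
#'   `current_resolution` grid geometry (degrees)
#' * `n_islands`, `island_radius_min`, `island_radius_max`,
#'   `p_rock`, `p_sand`, `p_both` archipelago layout and substrate mix
#' * `gyres` list of gyres (`center`, `radius`, `peak_speed`)
#' * `mean_flow_u`, `mean_flow_v`, `noise_sd` background current (m/s)
#' * `duration_days`, `field_step_hours` current record
#' * `season_start`, `season_end` release months (`NA` = all days),
#'   `release_interval_hours`, `years`, `rocky_only`
#' * `pld_days` numeric vector of maximum drift durations (default `c(4, 30)`)
#' * `step_hours` RK4 step
#' * `symmetrization`, `prune`, `prune_rule`, `n_permutations` network stage
#' * `gmyc_df` degrees of freedom for the GMYC likelihood-ratio test
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    lon_min = -1, lon_max = 1, lat_min = -1, lat_max = 1,
    coast_resolution = 0.02, current_resolution = 0.05,
    n_islands = 2L, island_radius_min = 0.08, island_radius_max = 0.15,
    p_rock = 0.5, p_sand = 0.3, p_both = 0.2,
    gyres = list(list(center = c(0, 0), radius = 0.4, peak_speed = 0.5)),
    mean_flow_u = 0.05, mean_flow_v = 0, noise_sd = 0,
    duration_days = 40, field_step_hours = 24,
    season_start = NA, season_end = NA,
    release_interval_hours = 12, years = 1L, rocky_only = TRUE,
    pld_days = c(4, 30),
    step_hours = 1,
    symmetrization = "mean", prune = TRUE, prune_rule = "keep",
    n_permutations = 999L,
    gmyc_df = 3L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  stopifnot(
    cfg$coast_resolution > 0, cfg$current_resolution > 0,
    cfg$n_islands >= 1, cfg$duration_days > 0,
    cfg$release_interval_hours > 0, 24 %% cfg$release_interval_hours == 0,
    all(cfg$pld_days > 0), cfg$step_hours > 0,
    cfg$symmetrization %in% c("mean", "max", "min"),
    cfg$prune_rule %in% c("keep", "past"),
    cfg$n_permutations >= 99, cfg$gmyc_df %in% c(2L, 3L)
  )
  structure(cfg, class = "pipeline_config")
}

#' Run the dispersal-to-clustering pipeline
#'
#' Seascape generation, particle release and advection for each pelagic
#' larval duration, connectivity aggregation, and network clustering, with
#' every artifact written as delimited text under `outdir` together with a
#' JSON run manifest (configuration echo, seed, package version, wall time)
#' from which the run can be reproduced exactly.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param quiet Suppress stage log lines?
#' @return Invisibly, a list with `coast`, `field`, and per-PLD `events`,
#'   `matrix` and `partition`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))

  coast_grid <- grid_spec(config$lon_min, config$lon_max, config$lat_min,
                          config$lat_max, config$coast_resolution)
  coast <- make_archipelago(
    config$n_islands, coast_grid,
    island_radius_range = c(config$island_radius_min, config$island_radius_max),
    substrate_mix = c(rock = config$p_rock, sand = config$p_sand, both = config$p_both),
    seed = config$seed
  )
  write_coast_grid(coast, file.path(outdir, "coast.csv"))
  say("seascape: %d coastal cells on %d islands", nrow(coast), config$n_islands)

  current_grid <- grid_spec(config$lon_min, config$lon_max, config$lat_min,
                            config$lat_max, config$current_resolution)
  field <- make_current_field(
    current_grid, config$duration_days, config$field_step_hours,
    gyres = config$gyres,
    mean_flow = c(config$mean_flow_u, config$mean_flow_v),
    noise_sd = config$noise_sd, seed = config$seed
  )
  write_current_field(field, file.path(outdir, "currents.txt"))

  season <- if (is.na(config$season_start)) NULL else c(config$season_start, config$season_end)
  schedule <- schedule_releases(
    coast, season = season, interval_hours = config$release_interval_hours,
    years = config$years, rocky_only = config$rocky_only,
    max_hours = max(field$times) - max(config$pld_days) * 24
  )
  say("schedule: %d releases from %d cells", nrow(schedule), length(unique(schedule$cell_id)))

  results <- list(coast = coast, field = field, config = config)
  for (pld in config$pld_days) {
    events <- run_simulation(coast, field, schedule, max_days = pld,
                             step_hours = config$step_hours, seed = config$seed)
    write_events(events, file.path(outdir, sprintf("events_pld%g.csv", pld)))
    n_landed <- sum(events$fate == "landed")
    say("simulate (PLD %g d): %d particles, %d landed", pld, nrow(events), n_landed)

    cellm <- cell_connectivity(events, schedule)
    islm <- island_connectivity(cellm, coast, pld_days = pld)
    write_connectivity_matrix(islm, file.path(outdir, sprintf("matrix_pld%g.csv", pld)))

    part <- tryCatch(
      cluster_islands(islm, symmetrization = config$symmetrization,
                      prune = config$prune, prune_rule = config$prune_rule),
      error = function(e) {
        say("cluster (PLD %g d): skipped (%s)", pld, conditionMessage(e))
        NULL
      }
    )
    if (!is.null(part)) {
      readr::write_csv(tidy(part), file.path(outdir, sprintf("partition_pld%g.csv", pld)))
      say("cluster (PLD %g d): %d communities, Q = %.3f", pld, part$n_communities, part$Q)
    }
    results[[sprintf("pld%g", pld)]] <- list(events = events, matrix = islm, partition = part)
  }

  manifest <- list(
    package = "seadrift",
    version = as.character(utils::packageVersion("seadrift")),
    seed = config$seed,
    config = unclass(config),
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

#' Command-line interface
#'
#' A thin argument-vector interface over the package functions, used by the
#' `inst/cli/seadrift` Rscript wrapper. Subcommands:
#'
#' * `fixtures --out DIR` — materialize the packaged published connectivity
#'   matrices.
#' * `cluster --matrix FILE [--symmetrization mean|max|min] [--no-prune]
#'   [--prune-rule keep|past] [--permutations N] [--seed S] --out DIR` —
#'   network pipeline on a matrix file.
#' * `simulate --out DIR [--config FILE] [key=value ...]` — full dispersal
#'   pipeline from a flat `key = value` configuration file plus overrides.
#' * `stats lrt --null X --alt Y --df D` and
#'   `stats cor --table FILE` (two-column delimited input) — biogeographic
#'   statistics to stdout.
#' * `delimit --tree FILE [--df D] --out DIR` — GMYC species delimitation.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(args) {
  status <- tryCatch(
    {
      if (length(args) == 0) abort("usage: seadrift <subcommand> [options]")
      sub <- args[1]
      rest <- args[-1]
      switch(sub,
        fixtures = cli_fixtures(rest),
        cluster = cli_cluster(rest),
        simulate = cli_simulate(rest),
        stats = cli_stats(rest),
        delimit = cli_delimit(rest),
        abort(paste0("unknown subcommand '", sub, "'"))
      )
      0L
    },
    error = function(e) {
      message("seadrift error: ", conditionMessage(e))
      1L
    }
  )
  invisible(status)
}

cli_opt <- function(rest, flag, default = NULL) {
  i <- which(rest == flag)
  if (length(i) == 0) return(default)
  if (i[1] == length(rest)) abort(paste0(flag, " needs a value"))
  rest[i[1] + 1]
}

cli_has <- function(rest, flag) any(rest == flag)

cli_fixtures <- function(rest) {
  out <- cli_opt(rest, "--out", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (f in c("table2_4day.csv", "table3_30day.csv")) {
    file.copy(seadrift_example(f), file.path(out, f), overwrite = TRUE)
    message("wrote ", file.path(out, f))
  }
}

cli_cluster <- function(rest) {
  path <- cli_opt(rest, "--matrix") %||% abort("cluster needs --matrix FILE")
  out <- cli_opt(rest, "--out", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sym <- cli_opt(rest, "--symmetrization", "mean")
  prune <- !cli_has(rest, "--no-prune")
  rule <- cli_opt(rest, "--prune-rule", "keep")
  n_perm <- as.integer(cli_opt(rest, "--permutations", "999"))
  seed <- as.integer(cli_opt(rest, "--seed", "1"))
  m <- read_connectivity_matrix(path)
  part <- cluster_islands(m, symmetrization = sym, prune = prune, prune_rule = rule)
  g <- build_graph(m, sym)
  if (prune) g <- prune_graph(g, percolation_threshold(g), rule)
  sig <- cluster_significance(g, n_permutations = n_perm, seed = seed)
  readr::write_csv(tidy(part), file.path(out, "membership.csv"))
  readr::write_csv(graph_edges(g), file.path(out, "edges.csv"))
  summary_tbl <- glance(part) %>%
    mutate(prune_rule = if (prune) rule else NA_character_,
           p_value = sig$p_value, n_permutations = n_perm, seed = seed)
  readr::write_csv(summary_tbl, file.path(out, "summary.csv"))
  message(sprintf(
    "clusters: %d, Q = %.4f, threshold = %.3g, p = %.4g (%d permutations)",
    part$n_communities, part$Q, part$threshold %||% NA, sig$p_value, n_perm
  ))
}

cli_simulate <- function(rest) {
  out <- cli_opt(rest, "--out") %||% abort("simulate needs --out DIR")
  cfg_file <- cli_opt(rest, "--config")
  opts <- list()
  if (!is.null(cfg_file)) opts <- read_flat_config(cfg_file)
  kv <- grep("^[A-Za-z_]+=", rest, value = TRUE)
  for (pair in kv) {
    key <- sub("=.*", "", pair)
    val <- sub("^[^=]*=", "", pair)
    opts[[key]] <- parse_config_value(val)
  }
  config <- do.call(pipeline_config, opts)
  run_pipeline(config, out)
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  opts <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) abort(paste0("bad config line: ", ln))
    key <- trimws(sub("=.*", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    opts[[key]] <- parse_config_value(val)
  }
  opts
}

parse_config_value <- function(val) {
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) return(if (length(num) == 1) num else num)
  if (length(parts) == 1 && parts %in% c("TRUE", "FALSE", "true", "false")) {
    return(toupper(parts) == "TRUE")
  }
  if (length(parts) == 1 && parts %in% c("NA", "null")) return(NA)
  if (length(parts) == 1) return(parts)
  parts
}

cli_stats <- function(rest) {
  if (length(rest) == 0) abort("stats needs a mode: lrt or cor")
  mode <- rest[1]
  rest <- rest[-1]
  if (mode == "lrt") {
    res <- nested_lrt(
      as.numeric(cli_opt(rest, "--null") %||% abort("stats lrt needs --null")),
      as.numeric(cli_opt(rest, "--alt") %||% abort("stats lrt needs --alt")),
      df = as.integer(cli_opt(rest, "--df", "1"))
    )
    writeLines(readr::format_csv(res))
  } else if (mode == "cor") {
    path <- cli_opt(rest, "--table") %||% abort("stats cor needs --table FILE")
    d <- readr::read_csv(path, col_types = readr::cols())
    if (ncol(d) < 2) abort("stats cor table needs two numeric columns")
    num <- d[vapply(d, is.numeric, logical(1))]
    res <- richness_correlation(num, !!rlang::sym(names(num)[1]), !!rlang::sym(names(num)[2]))
    writeLines(readr::format_csv(res))
  } else {
    abort(paste0("unknown stats mode '", mode, "'"))
  }
}

cli_delimit <- function(rest) {
  path <- cli_opt(rest, "--tree") %||% abort("delimit needs --tree FILE")
  out <- cli_opt(rest, "--out", ".")
  df <- as.integer(cli_opt(rest, "--df", "3"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tree <- read_ultrametric_tree(path)
  fit <- fit_gmyc(tree)
  lrt <- gmyc_lrt(fit, df = df)
  readr::write_csv(tidy(fit), file.path(out, "entities.csv"))
  readr::write_csv(
    dplyr::bind_cols(glance(fit), select(lrt, "statistic", "df", "p_value")),
    file.path(out, "summary.csv")
  )
  message(sprintf(
    "entities: %d; lnL = %.3f vs null %.3f; D = %.3f, df = %d, p = %.3g",
    fit$n_entities, fit$logLik, fit$null$logLik,
    lrt$statistic, lrt$df, lrt$p_value
  ))
}
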