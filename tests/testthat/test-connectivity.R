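test_that("cell connectivity is the landed/released ratio", {
  ev <- make_events(rep(1, 10), c(rep(2, 3), rep(NA, 7)))
  sched <- make_schedule(1, times = seq(0, 108, by = 12))
  P <- cell_connectivity(ev, sched)
  expect_equal(P["1", "2"], 0.3)
  expect_equal(P["1", "1"], 0)
})

test_that("no landings gives an all-zero matrix and schedule mismatches error", {
  ev <- make_events(c(1, 2), c(NA, NA))
  sched <- make_schedule(1:2, times = 0)
  P <- cell_connectivity(ev, sched)
  expect_true(all(P == 0))
  expect_error(cell_connectivity(make_events(3, 1), sched), "absent from the schedule")
})

test_that("cell connectivity equals a brute-force tally on random event lists", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      cells <- 1:6
      n <- 400
      src <- sample(cells, n, replace = TRUE)
      dst <- ifelse(runif(n) < 0.6, sample(cells, n, replace = TRUE), NA)
      ev <- make_events(src, dst)
      sched <- make_schedule(cells, times = seq(0, by = 12, length.out = 5))
      # count releases per cell: every cell appears once per time
      P <- cell_connectivity(ev, sched)
      for (a in cells) for (b in cells) {
        hits <- 0
        for (i in seq_len(n)) {
          if (src[i] == a && !is.na(dst[i]) && dst[i] == b) hits <- hits + 1
        }
        expect_equal(P[as.character(a), as.character(b)], hits / 5)
      }
    }
  })
})

test_that("row sums of the cell matrix stay at or below one", {
  withr::with_seed(8, {
    src <- sample(1:4, 200, replace = TRUE)
    dst <- ifelse(runif(200) < 0.8, sample(1:4, 200, replace = TRUE), NA)
    sched <- make_schedule(1:4, times = seq(0, by = 6, length.out = 100))
    P <- cell_connectivity(make_events(src, dst), sched)
    expect_true(all(rowSums(P) <= 1 + 1e-12))
  })
})

test_that("island aggregation averages source cells and matches a loop oracle", {
  coast <- tibble::tibble(
    cell_id = 1:6, lon = 0, lat = 0,
    island = c(1, 1, 2, 2, 3, 3), substrate = "rock"
  )
  withr::with_seed(13, {
    src <- sample(1:6, 500, replace = TRUE)
    dst <- ifelse(runif(500) < 0.7, sample(1:6, 500, replace = TRUE), NA)
    ev <- make_events(src, dst)
    sched <- make_schedule(1:6, times = seq(0, by = 12, length.out = 200))
    cm <- cell_connectivity(ev, sched)
    im <- island_connectivity(cm, coast)
    for (I in 1:3) for (J in 1:3) {
      src_cells <- coast$cell_id[coast$island == I]
      dst_cells <- as.character(coast$cell_id[coast$island == J])
      acc <- 0
      for (a in src_cells) acc <- acc + sum(cm[as.character(a), dst_cells])
      expect_equal(unclass(im)[I, J], acc / length(src_cells), tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  })
})

test_that("island aggregation collapses trivially for one cell per island", {
  coast <- tibble::tibble(cell_id = 1:2, lon = 0, lat = 0,
                          island = 1:2, substrate = "rock")
  ev <- make_events(c(1, 1, 2, 2), c(2, 2, 1, NA))
  sched <- make_schedule(1:2, times = c(0, 12))
  cm <- cell_connectivity(ev, sched)
  im <- island_connectivity(cm, coast)
  expect_equal(unclass(im)["island 1", "island 2"], cm["1", "2"])
  expect_equal(unclass(im)["island 2", "island 1"], cm["2", "1"])
})

test_that("islands without scheduled sources yield flagged NA rows", {
  coast <- tibble::tibble(cell_id = 1:3, lon = 0, lat = 0,
                          island = c(1L, 1L, 2L), substrate = "rock")
  ev <- make_events(c(1, 2), c(3, NA), source_island = 1, dest_island = c(2, NA))
  sched <- make_schedule(1:2, times = c(0, 12)) # island 2 never releases
  cm <- cell_connectivity(ev, sched)
  expect_warning(im <- island_connectivity(cm, coast), "NA rows")
  expect_true(all(is.na(unclass(im)["island 2", ])))
  expect_false(anyNA(unclass(im)["island 1", ]))
})

test_that("island connectivity is invariant to permuting the event list", {
  coast <- tibble::tibble(cell_id = 1:4, lon = 0, lat = 0,
                          island = c(1, 1, 2, 2), substrate = "rock")
  withr::with_seed(5, {
    src <- sample(1:4, 300, replace = TRUE)
    dst <- ifelse(runif(300) < 0.5, sample(1:4, 300, replace = TRUE), NA)
    ev <- make_events(src, dst)
    sched <- make_schedule(1:4, times = seq(0, by = 12, length.out = 150))
    im1 <- island_connectivity(cell_connectivity(ev, sched), coast)
    perm <- sample(nrow(ev))
    ev2 <- ev[perm, ]
    ev2$particle_id <- seq_len(nrow(ev2))
    im2 <- island_connectivity(cell_connectivity(ev2, sched), coast)
    expect_equal(unclass(im1), unclass(im2))
  })
})

test_that("dispersal summaries use only between-cell landings", {
  # one qualifying event
  ev <- make_events(1, 2, drift_days = 2, distance_km = 10)
  s <- dispersal_summary(ev)
  expect_equal(s$n_events, 1L)
  expect_equal(s$max_distance_km, 10)
  expect_equal(s$mean_distance_km, 10)
  expect_equal(s$sd_distance_km, 0)
  # all self-cell -> empty summary
  ev2 <- make_events(c(1, 2), c(1, 2))
  s2 <- dispersal_summary(ev2)
  expect_equal(s2$n_events, 0L)
  expect_true(is.na(s2$mean_distance_km))
})

test_that("dispersal summaries match direct formulas on synthetic events", {
  withr::with_seed(77, {
    n <- 1000
    src <- sample(1:5, n, replace = TRUE)
    dst <- sample(1:5, n, replace = TRUE)
    d_km <- runif(n, 1, 300)
    t_d <- runif(n, 0.1, 4)
    ev <- make_events(src, dst)
    ev$distance_km <- d_km
    ev$drift_days <- t_d
    sched <- make_schedule(1:5, times = seq(0, by = 12, length.out = 40))
    s <- dispersal_summary(ev, sched)
    keep <- src != dst
    expect_equal(s$n_events, sum(keep))
    expect_equal(s$max_distance_km, max(d_km[keep]), tolerance = 1e-12)
    expect_equal(s$mean_distance_km, mean(d_km[keep]), tolerance = 1e-12)
    expect_equal(s$sd_distance_km, sd(d_km[keep]), tolerance = 1e-12)
    expect_equal(s$mean_time_days, mean(t_d[keep]), tolerance = 1e-12)
    # probability stats: per connected pair, landed / released-from-source
    rel <- table(factor(src[keep], levels = 1:5))
    tab <- table(src[keep], dst[keep])
    p <- as.vector(tab[tab > 0]) / 40
    expect_equal(s$max_probability, max(p), tolerance = 1e-12)
    expect_equal(s$mean_probability, mean(p), tolerance = 1e-12)
  })
})

test_that("matrix files round-trip exactly and reject malformed input", {
  withr::with_seed(2, {
    labels <- paste0("isl", 1:9)
    P <- matrix(runif(81, 0, 1e-3), 9, 9, dimnames = list(labels, labels))
    diag(P) <- NA
    m <- connectivity_matrix(P)
    p <- withr::local_tempfile(fileext = ".csv")
    write_connectivity_matrix(m, p)
    back <- read_connectivity_matrix(p)
    expect_identical(unclass(back), unclass(m))
  })
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("island,a,b", "a,—,x", "b,0.1,—"), bad)
  expect_error(read_connectivity_matrix(bad), "non-numeric")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("island,a,b", "b,—,0.2", "a,0.1,—"), bad2)
  expect_error(read_connectivity_matrix(bad2), "labels")
})

test_that("the packaged published matrices parse to their printed values", {
  m2 <- read_connectivity_matrix(seadrift_example("table2_4day.csv"))
  expect_equal(dim(m2), c(9, 9))
  expect_equal(m2["Santo Antao", "Maio"], 2.30e-06)
  expect_equal(m2["Sao Vincente", "Santo Antao"], 2.20e-03)
  expect_equal(m2["Maio", "Santiago"], 3.50e-03)
  off <- m2[row(m2) != col(m2)]
  expect_equal(min(off), 2.3e-06)

  m3 <- read_connectivity_matrix(seadrift_example("table3_30day.csv"))
  expect_equal(m3["Maio", "Santiago"], 4.70e-03)
  expect_equal(m3["Sao Vincente", "Santo Antao"], 2.30e-03)
})

test_that("the paper-style writer mimics the printed notation", {
  m <- read_connectivity_matrix(seadrift_example("table2_4day.csv"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_connectivity_matrix(m, p, format = "paper")
  lines <- readLines(p)
  expect_match(lines[2], "3.40E-04", fixed = TRUE)
  back <- read_connectivity_matrix(p)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
})
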