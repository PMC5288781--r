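test_that("release schedules count cells times times", {
  g <- grid_spec(-1, 1, -1, 1, resolution = 0.1)
  coast <- tibble::tibble(
    cell_id = 1:10, lon = 0, lat = 0, island = 1L, substrate = "rock"
  )
  attr(coast, "grid") <- g
  # 1 rocky cell, 1 day, 12 h interval -> 2 entries
  one <- coast[1, ]
  attr(one, "grid") <- g
  s1 <- schedule_releases(one, season = NULL, years = 1, max_hours = 24)
  expect_equal(nrow(s1), 2)
  # 10 cells x 153-day season x 2/day x 1 year -> 3060
  s2 <- schedule_releases(coast, season = c(8, 12), interval_hours = 12, years = 1)
  expect_equal(nrow(s2), 3060)
  # two years double it
  s3 <- schedule_releases(coast, season = c(8, 12), years = 2)
  expect_equal(nrow(s3), 6120)
  expect_true(all(diff(s3$time_h) >= 0))
})

test_that("rocky-only scheduling drops all-sand islands", {
  g <- grid_spec(-1, 1, -1, 1, resolution = 0.1)
  coast <- tibble::tibble(
    cell_id = 1:6, lon = 0, lat = 0,
    island = rep(1:2, each = 3),
    substrate = rep(c("rock", "sand"), each = 3)
  )
  attr(coast, "grid") <- g
  s <- schedule_releases(coast, season = NULL, years = 1, max_hours = 12)
  expect_setequal(unique(s$cell_id), 1:3)
  all_sand <- dplyr::mutate(coast, substrate = "sand")
  expect_error(schedule_releases(all_sand, season = NULL), "sand")
})

test_that("constant-velocity drift matches the closed form to 0.1%", {
  oc <- open_coast(grid_spec(-2, 2, -2, 2, 0.02))
  f <- make_current_field(grid_spec(-2, 2, -2, 2, 0.05), 10, 24, mean_flow = c(0.1, 0))
  a <- advect(c(-1.5, 0.3), 0, f, step_hours = 1, max_days = 4, coast = oc)
  expect_equal(a$fate, "expired")
  d_km <- geosphere::distHaversine(c(-1.5, 0.3), c(a$lon, a$lat)) / 1000
  expect_lt(abs(d_km - 34.56) / 34.56, 0.001) # 0.1 m/s * 4 d = 34.56 km
  expect_equal(a$lat, 0.3, tolerance = 1e-9)
})

test_that("gyre circulation conserves radial distance within 0.5%", {
  oc <- open_coast(grid_spec(-2, 2, -2, 2, 0.02))
  f <- make_current_field(
    grid_spec(-2, 2, -2, 2, 0.02), 10, 24,
    gyres = list(list(center = c(0, 0), radius = 0.5, peak_speed = 0.5))
  )
  for (r0 in c(0.3, 0.5, 0.8)) {
    a <- advect(c(r0, 0), 0, f, step_hours = 1, max_days = 4, coast = oc)
    r1 <- sqrt(a$lon^2 + a$lat^2)
    expect_lt(abs(r1 - r0) / r0, 0.005)
  }
})

test_that("halving the step barely moves 4-day trajectories", {
  oc <- open_coast(grid_spec(-2, 2, -2, 2, 0.02))
  fu <- make_current_field(grid_spec(-2, 2, -2, 2, 0.05), 10, 24, mean_flow = c(0.1, 0.05))
  a1 <- advect(c(-1, 0), 0, fu, step_hours = 1, max_days = 4, coast = oc)
  a2 <- advect(c(-1, 0), 0, fu, step_hours = 0.5, max_days = 4, coast = oc)
  expect_lt(geosphere::distHaversine(c(a1$lon, a1$lat), c(a2$lon, a2$lat)) / 1000, 1e-9)

  fg <- make_current_field(
    grid_spec(-2, 2, -2, 2, 0.02), 10, 24,
    gyres = list(list(center = c(0, 0), radius = 0.5, peak_speed = 0.5))
  )
  b1 <- advect(c(0.5, 0), 0, fg, step_hours = 1, max_days = 4, coast = oc)
  b2 <- advect(c(0.5, 0), 0, fg, step_hours = 0.5, max_days = 4, coast = oc)
  expect_lt(geosphere::distHaversine(c(b1$lon, b1$lat), c(b2$lon, b2$lat)) / 1000, 0.1)
})

test_that("a zero field expires particles in place", {
  oc <- open_coast(grid_spec(-1, 1, -1, 1, 0.02))
  f0 <- make_current_field(grid_spec(-1, 1, -1, 1, 0.1), 5, 24)
  a <- advect(c(0.3, -0.2), 0, f0, step_hours = 2, max_days = 2, coast = oc)
  expect_equal(a$fate, "expired")
  expect_false(a$out_of_domain)
  expect_identical(c(a$lon, a$lat), c(0.3, -0.2))
})

test_that("leaving the domain expires with a flag, not an error", {
  oc <- open_coast(grid_spec(-1, 1, -1, 1, 0.02))
  f <- make_current_field(grid_spec(-1, 1, -1, 1, 0.1), 30, 24, mean_flow = c(0.5, 0))
  a <- advect(c(0.9, 0), 0, f, step_hours = 1, max_days = 10, coast = oc)
  expect_equal(a$fate, "expired")
  expect_true(a$out_of_domain)
})

test_that("eastward flow carries particles from a west island onto the east island's west shore", {
  g <- grid_spec(-1, 1, -1, 1, resolution = 0.04)
  coast <- two_island_coast(g, lon1 = -0.5, lon2 = 0.5, lat0 = 0, half_deg = 0.1)
  f <- make_current_field(grid_spec(-1, 1, -1, 1, 0.1), 40, 24, mean_flow = c(0.5, 0))
  # release only from island 1's east-facing cells so particles head to sea
  east_cells <- coast[coast$island == 1 & coast$lon > -0.4, ]
  sched <- make_schedule(east_cells$cell_id, times = 0)
  ev <- run_simulation(coast, f, sched, max_days = 8, step_hours = 1)
  crossed <- ev[!is.na(ev$dest_island) & ev$dest_island == 2, ]
  expect_gt(nrow(crossed), 0)
  dest <- coast[match(crossed$dest_cell, coast$cell_id), ]
  # island 2 spans lon 0.5 +/- 0.1: its west shore is left of the center
  expect_true(all(dest$lon < 0.5))
  # every landing is on a coastal cell of some island
  landed <- ev[ev$fate == "landed", ]
  expect_true(all(landed$dest_cell %in% coast$cell_id))
  expect_true(all(landed$drift_days <= 8 + 1e-9))
})

test_that("simulation equals the concatenation of per-particle advect calls", {
  g <- grid_spec(-1, 1, -1, 1, resolution = 0.04)
  coast <- two_island_coast(g, -0.5, 0.5, 0, 0.1)
  f <- make_current_field(
    grid_spec(-1, 1, -1, 1, 0.1), 20, 24,
    gyres = list(list(center = c(0, 0.2), radius = 0.4, peak_speed = 0.4)),
    mean_flow = c(0.2, 0)
  )
  cells <- coast$cell_id[c(1, 25)]
  sched <- make_schedule(cells, times = c(0, 12))
  ev <- run_simulation(coast, f, sched, max_days = 4, step_hours = 1)
  expect_equal(nrow(ev), nrow(sched))
  for (i in seq_len(nrow(sched))) {
    ci <- match(sched$cell_id[i], coast$cell_id)
    a <- advect(c(coast$lon[ci], coast$lat[ci]), sched$time_h[i], f,
                step_hours = 1, max_days = 4, coast = coast)
    expect_identical(ev$fate[i], a$fate)
    if (a$fate == "landed") {
      expect_identical(ev$dest_cell[i], a$dest_cell)
      expect_equal(ev$drift_days[i], a$drift_hours / 24)
    }
  }
})

test_that("zero currents produce zero landed events", {
  g <- grid_spec(-1, 1, -1, 1, resolution = 0.04)
  coast <- two_island_coast(g, -0.5, 0.5, 0, 0.1)
  f0 <- make_current_field(grid_spec(-1, 1, -1, 1, 0.1), 10, 24)
  sched <- make_schedule(coast$cell_id[seq(1, nrow(coast), by = 7)], times = 0)
  ev <- run_simulation(coast, f0, sched, max_days = 2, step_hours = 2)
  expect_true(all(ev$fate == "expired"))
  expect_true(all(is.na(ev$dest_cell)))
})

test_that("event tables round-trip through delimited text", {
  ev <- make_events(c(1, 1, 2), c(2, NA, 1), source_island = c(1, 1, 2),
                    dest_island = c(2, NA, 1))
  p <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, p)
  expect_equal(as.data.frame(read_events(p)), as.data.frame(ev))
})
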