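test_that("state assignment maps locations to the five states", {
  geom <- state_geometry()
  expect_identical(assign_state(-150.0, 30, geom), 2L)
  expect_identical(assign_state(-152.0, 30, geom), 1L)
  expect_identical(assign_state(-152.0, 60, geom), 3L)
  expect_identical(assign_state(-150.0, 60, geom), 4L)
  # outside the longitude window or beyond the offshore band -> Elsewhere
  expect_identical(assign_state(-139.0, 30, geom), 5L)
  expect_identical(assign_state(-160.0, 30, geom), 5L)
  expect_identical(assign_state(-150.0, 120, geom), 5L)
})

test_that("state assignment boundary conventions are closed toward shore/west", {
  geom <- state_geometry()
  expect_identical(assign_state(-150.0, 43.246, geom), 2L)   # nearshore edge
  expect_identical(assign_state(-150.0, 104.606, geom), 4L)  # offshore edge
  expect_identical(assign_state(-151.0, 30, geom), 1L)       # split -> west
  expect_identical(assign_state(-158.5, 10, geom), 1L)
  expect_identical(assign_state(-141.0, 10, geom), 2L)
})

test_that("state assignment partitions the plane (exactly one state each)", {
  geom <- state_geometry()
  set.seed(1)
  lon <- runif(500, -170, -130)
  dist <- runif(500, 0, 200)
  st <- assign_state(lon, dist, geom)
  expect_true(all(st %in% 1:5))
  expect_length(st, 500)
  expect_error(assign_state(-150, -1, geom), "non-negative")
})

test_that("search-point filtering removes leading records of bad steps", {
  mk <- function(step_m, searching = TRUE) {
    n <- length(step_m) + 1L
    data.frame(timestamp = seq_len(n) * 30,
               lon = -150, coast_distance_km = 10,
               searching = rep(searching, n),
               step_m = c(NA, step_m))
  }
  # 5 m step: leading record removed
  expect_identical(nrow(filter_search_points(mk(5))), 1L)
  # 1000 m step: both retained
  expect_identical(nrow(filter_search_points(mk(1000))), 2L)
  # 2500 m step: leading record removed
  expect_identical(nrow(filter_search_points(mk(2500))), 1L)
  # boundary steps are admissible
  expect_identical(nrow(filter_search_points(mk(c(10, 2083)))), 3L)
  # only searching segments are filtered
  expect_identical(nrow(filter_search_points(mk(5, searching = FALSE))), 2L)
  # a burst of short steps collapses onto the first admissible record
  tr <- mk(c(5, 5, 5, 1000))
  expect_identical(nrow(filter_search_points(tr)), 2L)
  bad <- mk(1000); bad$timestamp <- rev(bad$timestamp)
  expect_error(filter_search_points(bad), "non-decreasing")
})

test_that("search-point filtering recomputes steps from planar coordinates", {
  tr <- data.frame(timestamp = c(30, 60, 90),
                   lon = -150, coast_distance_km = 10,
                   searching = TRUE,
                   x_km = c(0, 0.005, 1.2), y_km = 0)
  # first step 5 m (removed); survivor-to-next step 1.2 km (kept)
  out <- filter_search_points(tr)
  expect_identical(out$x_km, c(0, 1.2))
})

test_that("boundary quantiles use linear interpolation and are monotone", {
  b <- derive_boundaries(1:100, 0.5, 0.9)
  expect_equal(unname(b["nearshore_km"]), 50.5)
  expect_equal(unname(b["offshore_km"]), 90.1)
  # invariance to ordering; degenerate distribution
  expect_equal(derive_boundaries(sample(1:100), 0.5, 0.9), b)
  expect_equal(unname(derive_boundaries(rep(7, 50), 0.67, 0.995)), c(7, 7))
  # monotone in q
  qs <- seq(0.1, 0.9, by = 0.2)
  vals <- vapply(qs, function(q)
    derive_boundaries(1:100, q, 0.995)[["nearshore_km"]], numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(derive_boundaries(numeric(0)), "no search distances")
})

test_that("annual telemetry state follows the asymmetric majority rule", {
  # Elsewhere requires a strict majority of days
  expect_identical(annual_telemetry_state(rep(c(5L, 4L), c(6, 2))), 5L)
  expect_identical(annual_telemetry_state(rep(c(1L, 2L, 5L), c(3, 4, 3))), 2L)
  # exactly half Elsewhere is not a majority
  expect_identical(annual_telemetry_state(c(5L, 5L, 3L, 3L)), 3L)
  # ties among states 1-4 break to the lowest id
  expect_identical(annual_telemetry_state(rep(c(1L, 2L), c(5, 5))), 1L)
  expect_identical(annual_telemetry_state(integer(0)), NA_integer_)
  expect_error(annual_telemetry_state(c(1L, 7L)), "1..5")
})

test_that("effort compilation sums, inflates, and stays additive", {
  yrs <- 2001:2003
  steps <- data.frame(year = c(2001, 2001, 2002, 2002, 2003),
                      state = c(1, 1, 2, 5, 3),
                      length_km = c(600, 400, 250, 99, 50))
  e0 <- compile_effort(steps, yrs)
  expect_equal(unname(e0[1, "2001"]), 1000)
  expect_equal(unname(e0[2, "2002"]), 250)   # state-5 steps ignored
  expect_equal(unname(e0[4, "2003"]), 0)     # empty cell
  # multiplicative inflation: 1,000 km at fraction 0.2 -> 1,200 km
  e2 <- compile_effort(steps, yrs, untracked_fraction = 0.2)
  expect_equal(unname(e2[1, "2001"]), 1200)
  expect_equal(unclass(compile_effort(steps, yrs, untracked_fraction = 0)),
               unclass(e0))
  # the alternative inverse convention
  einv <- compile_effort(steps, yrs, untracked_fraction = 0.2,
                         inflation = "inverse")
  expect_equal(unname(einv[1, "2001"]), 1000 / 0.8)
  # additive over flights, monotone in the untracked fraction
  s1 <- steps[1:2, ]; s2 <- steps[3:5, ]
  expect_equal(unclass(compile_effort(s1, yrs)) +
                 unclass(compile_effort(s2, yrs)), unclass(e0))
  expect_true(all(unclass(compile_effort(steps, yrs, 0.3)) >=
                    unclass(compile_effort(steps, yrs, 0.1))))
})

test_that("effort tables round-trip through CSV", {
  e <- effort_table(matrix(c(0, 10.5, 2000, 3000), 4, 3), 2001:2003)
  path <- withr::local_tempfile(fileext = ".csv")
  write_effort_csv(e, path)
  expect_equal(unclass(read_effort_csv(path)), unclass(e))
})
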