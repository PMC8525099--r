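#' Spatial-state geometry of the southern Beaufort Sea study area
#'
#' The study area off Alaska's north coast is partitioned into four spatial
#' states: a nearshore and an offshore band, each split at a fixed longitude
#' into a western and an eastern region.  Everywhere else (farther offshore,
#' or east/west of the study area) is state 5, "Elsewhere", where bears are
#' alive but unobservable.  The default band widths are the 67th and 99.5th
#' quantiles of coast distances of aircraft locations recorded while actively
#' searching for bears; the default longitudinal split sits where historically
#' few captures occurred.
#'
#' @param lon_west,lon_east Western and eastern longitude limits of the study
#'   area, decimal degrees (negative = west).
#' @param lon_split Longitude dividing western from eastern states.
#' @param nearshore_km Outer edge of the nearshore band, km from the mainland
#'   coast.
#' @param offshore_km Outer edge of the offshore band, km from the coast.
#' @return An object of class `state_geometry`.
#' @examples
#' geom <- state_geometry()
#' assign_state(-150, 30, geom)   # Nearshore-east
#' @export
state_geometry <- function(lon_west = -158.5, lon_east = -141.0,
                           lon_split = -151.0, nearshore_km = 43.246,
                           offshore_km = 104.606) {
  stopifnot(lon_west < lon_split, lon_split < lon_east,
            nearshore_km > 0, nearshore_km < offshore_km)
  structure(list(lon_west = lon_west, lon_east = lon_east,
                 lon_split = lon_split, nearshore_km = nearshore_km,
                 offshore_km = offshore_km),
            class = "state_geometry")
}

#' @export
print.state_geometry <- function(x, ...) {
  cat("Spatial-state geometry\n")
  cat(sprintf("  longitude: [%.3f, %.3f], west/east split at %.3f\n",
              x$lon_west, x$lon_east, x$lon_split))
  cat(sprintf("  nearshore band: 0-%.3f km, offshore band: %.3f-%.3f km\n",
              x$nearshore_km, x$nearshore_km, x$offshore_km))
  invisible(x)
}

#' Assign locations to spatial states
#'
#' Maps a location (longitude, distance to the mainland coast) to one of the
#' five spatial states: 1 Nearshore-west, 2 Nearshore-east, 3 Offshore-west,
#' 4 Offshore-east, 5 Elsewhere.  The assignment is total: every location
#' receives exactly one state.  Boundary locations (coast distance exactly at
#' a band edge, longitude exactly at the split) are assigned to the
#' nearer-shore and western state respectively, a deterministic convention
#' for ties the geometry itself does not resolve.
#'
#' @param lon Numeric vector of longitudes, decimal degrees.
#' @param coast_distance Numeric vector of distances to the mainland coast, km
#'   (non-negative).
#' @param geom A [state_geometry()].
#' @return Integer vector of state ids in 1..5.
#' @export
assign_state <- function(lon, coast_distance, geom = state_geometry()) {
  stopifnot(length(lon) == length(coast_distance))
  if (any(coast_distance < 0, na.rm = TRUE))
    stop("coast_distance must be non-negative")
  in_lon <- lon >= geom$lon_west & lon <= geom$lon_east
  west <- lon <= geom$lon_split
  near <- coast_distance <= geom$nearshore_km
  off  <- coast_distance > geom$nearshore_km & coast_distance <= geom$offshore_km
  state <- rep.int(5L, length(lon))
  state[in_lon & near & west]  <- 1L
  state[in_lon & near & !west] <- 2L
  state[in_lon & off & west]   <- 3L
  state[in_lon & off & !west]  <- 4L
  state
}

#' Filter flight-track points incompatible with search activity
#'
#' Flight paths are standardized to one estimated location every 30 s.  For
#' consecutive location pairs recorded while the crew was searching for bears,
#' a step shorter than `min_step_m` or longer than `max_step_m` implies a
#' speed incompatible with searching, and the leading (second) record of the
#' pair is removed.  Removal is iterative in track order, so a burst of
#' too-short steps collapses onto the first admissible record.
#'
#' @param track A data.frame with columns `timestamp` (sortable; POSIXct or
#'   numeric seconds), `lon`, `coast_distance_km`, `searching` (logical), and
#'   columns `x_km`/`y_km` (planar coordinates, km) or `step_m` (precomputed
#'   distance in metres from the previous record).
#' @param min_step_m,max_step_m Admissible step-length band, metres.
#' @return The track with offending leading records removed, order preserved.
#' @export
filter_search_points <- function(track, min_step_m = 10, max_step_m = 2083) {
  if (nrow(track) == 0L) return(track)
  ts <- as.numeric(track$timestamp)
  if (is.unsorted(ts, strictly = FALSE))
    stop("track timestamps must be non-decreasing")
  has_xy <- all(c("x_km", "y_km") %in% names(track))
  if (!has_xy && !("step_m" %in% names(track)))
    stop("track needs either x_km/y_km or a step_m column")
  keep <- rep(TRUE, nrow(track))
  last_kept <- 1L
  for (i in seq_len(nrow(track))[-1L]) {
    if (isTRUE(track$searching[i]) && isTRUE(track$searching[last_kept])) {
      step <- if (has_xy) {
        1000 * sqrt((track$x_km[i] - track$x_km[last_kept])^2 +
                    (track$y_km[i] - track$y_km[last_kept])^2)
      } else {
        track$step_m[i]
      }
      if (step < min_step_m || step > max_step_m) {
        keep[i] <- FALSE
        next
      }
    }
    last_kept <- i
  }
  track[keep, , drop = FALSE]
}

#' Derive nearshore/offshore band boundaries from search distances
#'
#' The band edges of the spatial states are empirical quantiles of the coast
#' distances of locations recorded while searching for bears.  Quantiles use
#' linear interpolation between order statistics ([stats::quantile()] type 7),
#' a declared convention so the derivation is reproducible.
#'
#' @param search_distances Numeric vector of coast distances, km.
#' @param q_near,q_off Quantile levels for the nearshore and offshore edges.
#' @return Named numeric vector `c(nearshore_km =, offshore_km =)`.
#' @examples
#' derive_boundaries(1:100, 0.5, 0.9)
#' @export
derive_boundaries <- function(search_distances, q_near = 0.67, q_off = 0.995) {
  if (length(search_distances) == 0L || all(is.na(search_distances)))
    stop("no search distances supplied")
  stopifnot(q_near > 0, q_near < q_off, q_off <= 1)
  q <- stats::quantile(search_distances, c(q_near, q_off),
                       na.rm = TRUE, names = FALSE, type = 7)
  c(nearshore_km = q[1], offshore_km = q[2])
}

#' Annual state assignment for a telemetry-instrumented bear
#'
#' Each instrumented bear contributing daily (12:00 UTC) locations within the
#' spring sampling window is assigned one state per year: state 5
#' ("Elsewhere") if strictly more than half of its daily states are 5,
#' otherwise the state among 1-4 holding the greatest number of its locations.
#' Ties among states 1-4 are broken toward the lowest state id, a declared
#' convention.
#'
#' @param daily_states Integer vector of daily state ids (1..5) inside the
#'   spring window.
#' @return A single state id in 1..5, or `NA_integer_` for an empty window
#'   (the bear contributes no state that year).
#' @export
annual_telemetry_state <- function(daily_states) {
  daily_states <- daily_states[!is.na(daily_states)]
  if (length(daily_states) == 0L) return(NA_integer_)
  if (!all(daily_states %in% 1:5)) stop("daily states must be in 1..5")
  n <- length(daily_states)
  if (sum(daily_states == 5L) * 2L > n) return(5L)
  counts <- tabulate(daily_states[daily_states != 5L], nbins = 4L)
  if (all(counts == 0L)) return(5L)  # exactly half elsewhere, nothing in 1-4
  which.max(counts)  # which.max takes the first (lowest id) on ties
}

#' Compile the search-effort table
#'
#' Sums searching step lengths by spatial state and year, then inflates each
#' state-year total by the proportion of flight time in that year that lacked
#' GPS tracks, approximating effort on flights whose tracks were lost.  The
#' default inflation is multiplicative, `d * (1 + p)`; setting
#' `inflation = "inverse"` uses `d / (1 - p)` instead.
#'
#' @param steps A data.frame of searching steps with columns `year`,
#'   `state` (1..4; rows in state 5 are ignored), and `length_km`.
#' @param years Integer vector of study years defining the table rows.
#' @param untracked_fraction Either a single number in `[0, 1)`, or a matrix
#'   (4 x length(years)) of per state-year fractions, or `NULL` for 0.
#' @param inflation `"multiplicative"` (default) or `"inverse"`.
#' @return An `effort_table`: a 4 x length(years) matrix of km flown,
#'   dimnames `state`, `year`.
#' @export
compile_effort <- function(steps, years, untracked_fraction = NULL,
                           inflation = c("multiplicative", "inverse")) {
  inflation <- match.arg(inflation)
  d <- matrix(0, nrow = 4L, ncol = length(years),
              dimnames = list(state = 1:4, year = years))
  if (nrow(steps) > 0L) {
    ok <- steps$state %in% 1:4 & steps$year %in% years
    s <- steps[ok, , drop = FALSE]
    if (nrow(s) > 0L) {
      agg <- stats::aggregate(s$length_km,
                              by = list(state = s$state, year = s$year), sum)
      d[cbind(agg$state, match(agg$year, years))] <- agg$x
    }
  }
  p <- untracked_fraction
  if (is.null(p)) p <- 0
  if (length(p) == 1L) p <- matrix(p, 4L, length(years))
  stopifnot(all(dim(p) == dim(d)), all(p >= 0), all(p < 1))
  d <- switch(inflation,
              multiplicative = d * (1 + p),
              inverse        = d / (1 - p))
  effort_table(d, years)
}

#' Construct an effort table
#'
#' @param distance A 4 x n_years numeric matrix of km flown per state-year
#'   (non-negative; zeros allowed).
#' @param years Integer vector of years labelling the columns.
#' @return An `effort_table` object.
#' @export
effort_table <- function(distance, years) {
  distance <- as.matrix(distance)
  stopifnot(nrow(distance) == 4L, ncol(distance) == length(years),
            all(distance >= 0), !anyNA(distance))
  dimnames(distance) <- list(state = 1:4, year = years)
  class(distance) <- c("effort_table", class(distance))
  distance
}

#' Read / write an effort table as CSV (columns state, year, distance_km)
#'
#' @param path File path.
#' @rdname effort_io
#' @export
read_effort_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("state", "year", "distance_km") %in% names(df)))
  years <- sort(unique(df$year))
  d <- matrix(0, 4L, length(years))
  d[cbind(df$state, match(df$year, years))] <- df$distance_km
  effort_table(d, years)
}

#' @param effort An `effort_table`.
#' @rdname effort_io
#' @export
write_effort_csv <- function(effort, path) {
  years <- as.integer(colnames(effort))
  df <- data.frame(state = rep(1:4, times = length(years)),
                   year = rep(years, each = 4L),
                   distance_km = as.vector(effort))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
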