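#' Capture counts by state and year
#'
#' Counts the bears observed (captured or biopsy-identified) in each spatial
#' state 1-4 in each abundance year.  Abundance is estimable for every year
#' except the first (no recapture probability) and the last (recapture
#' confounded with final-year survival).
#'
#' @param data An [mscjs_data()] object.
#' @return A 4 x (K - 2) integer matrix `C_mk`, columns named by year.
#' @export
capture_counts <- function(data) {
  years <- data$years
  K <- length(years)
  ab_years <- years[-c(1L, K)]
  obs <- data$observations
  C <- matrix(0L, 4L, length(ab_years),
              dimnames = list(state = 1:4, year = ab_years))
  sel <- obs$year %in% ab_years
  tab <- table(factor(obs$state[sel], levels = 1:4),
               factor(obs$year[sel], levels = ab_years))
  C[] <- as.integer(tab)
  C
}

#' Horvitz-Thompson estimate of within-area abundance
#'
#' Inflates the capture count in each spatial state by the inverse of its
#' recapture probability and sums over states 1-4:
#' `N* = sum_m C_m / rho_m`.  Very small probabilities propagate division
#' instability into the estimate, so counts inflated by a probability below
#' `warn_below` trigger a warning; an optional floor can be imposed for
#' diagnostic runs (none by default).
#'
#' @param C Integer vector of capture counts for states 1-4.
#' @param rho Numeric vector of recapture probabilities for states 1-4.
#' @param warn_below Warn when a state with captures has `rho` below this.
#' @param rho_floor Optional lower bound imposed on `rho` (diagnostics only).
#' @return The abundance estimate (scalar).
#' @examples
#' horvitz_thompson(c(5, 0, 2, 3), c(0.5, 0.2, 0.25, 0.3))  # 28
#' @export
horvitz_thompson <- function(C, rho, warn_below = 1e-4, rho_floor = NULL) {
  stopifnot(length(C) == 4L, length(rho) == 4L, all(C >= 0))
  if (!is.null(rho_floor)) rho <- pmax(rho, rho_floor)
  if (any(C > 0 & rho <= 0))
    stop("captures in a state with zero recapture probability")
  if (any(C > 0 & rho < warn_below))
    warning("recapture probability below ", warn_below,
            " in a state with captures; estimate may be unstable")
  used <- C > 0
  sum(C[used] / rho[used])
}

#' Proportion of living marked bears inside the sampled states
#'
#' Given one realization of the latent states of all marked bears in a year,
#' the fraction of the living (states 1-5) that occupy the sampled states
#' 1-4.  Dead bears are excluded from both counts.
#'
#' @param states Integer vector of latent states for one year (1..6;
#'   0 entries, i.e. pre-entry bears, are ignored).
#' @return Fraction in `[0, 1]`, or `NaN` when no bear is alive.
#' @export
alive_proportion <- function(states) {
  alive <- sum(states >= 1L & states <= 5L)
  inside <- sum(states >= 1L & states <= 4L)
  inside / alive
}

#' Posterior abundance series
#'
#' For each stored posterior draw: a Horvitz-Thompson estimate `N*_k` of the
#' number of bears in states 1-4 (capture counts divided by that draw's
#' recapture probabilities), and total abundance `N_k = N*_k / p_k`, where
#' `p_k` is the proportion of marked bears alive in that year occupying
#' states 1-4 in one exact latent-state realization drawn by
#' forward-filtering / backward-sampling conditional on the draw's
#' parameters.  Draws in which no marked bear is alive inside states 1-5, or
#' the alive proportion is zero, yield no `N_k` for that year and are
#' skipped with a warning tally.
#'
#' @param fit An `mscjs_fit`.
#' @param counts Optional capture-count matrix as from [capture_counts()]
#'   (defaults to the counts of the fitted data).
#' @param seed Seed for the latent-state realizations.
#' @param n_draws Use at most this many stored draws (evenly thinned);
#'   `NULL` for all.
#' @param rho_floor Optional diagnostic floor passed to
#'   [horvitz_thompson()].
#' @return An object of class `mscjs_abundance`: per-draw matrices
#'   `Nstar` and `N` (draws x years) and a `summary` data.frame with mean
#'   and 50%/95% credible intervals.
#' @export
abundance_series <- function(fit, counts = NULL, seed = 1L, n_draws = NULL,
                             rho_floor = NULL) {
  data <- fit$data
  years <- data$years
  K <- length(years)
  ab_years <- years[-c(1L, K)]
  if (is.null(counts)) counts <- capture_counts(data)
  stopifnot(all(colnames(counts) == ab_years))
  builders <- make_builders(fit$spec, years, fit$param_info, data$effort)
  all_draws <- do.call(rbind, fit$draws)
  if (!is.null(n_draws) && n_draws < nrow(all_draws)) {
    idx <- unique(round(seq(1L, nrow(all_draws), length.out = n_draws)))
    all_draws <- all_draws[idx, , drop = FALSE]
  }
  D <- nrow(all_draws)
  Nstar <- N <- matrix(NA_real_, D, length(ab_years),
                       dimnames = list(NULL, ab_years))
  skipped <- 0L
  set.seed(seed)
  for (d in seq_len(D)) {
    theta <- all_draws[d, ]
    phi <- builders$phi(theta); tau <- builders$tau(theta)
    rho <- builders$rho(theta)
    latent <- cpp_cjs_ffbs(data$encounter, data$first_idx, data$sex_idx,
                           data$age_class_idx, as.vector(phi), tau, rho)
    for (j in seq_along(ab_years)) {
      k <- j + 1L   # occasion index of this abundance year
      Nstar[d, j] <- horvitz_thompson(counts[, j], rho[, k],
                                      rho_floor = rho_floor,
                                      warn_below = 0)
      p <- alive_proportion(latent[, k])
      if (is.finite(p) && p > 0) N[d, j] <- Nstar[d, j] / p
      else skipped <- skipped + 1L
    }
  }
  if (skipped > 0L)
    warning(skipped, " draw-years skipped (no living marked bear in ",
            "states 1-4)")
  summ <- data.frame(
    year = ab_years,
    Nstar_mean = colMeans(Nstar),
    N_mean = colMeans(N, na.rm = TRUE),
    q2.5 = apply(N, 2L, stats::quantile, 0.025, na.rm = TRUE),
    q25 = apply(N, 2L, stats::quantile, 0.25, na.rm = TRUE),
    q75 = apply(N, 2L, stats::quantile, 0.75, na.rm = TRUE),
    q97.5 = apply(N, 2L, stats::quantile, 0.975, na.rm = TRUE))
  rownames(summ) <- NULL
  structure(list(Nstar = Nstar, N = N, summary = summ, skipped = skipped,
                 years = ab_years),
            class = "mscjs_abundance")
}

#' @export
print.mscjs_abundance <- function(x, ...) {
  cat("Posterior abundance series (", nrow(x$Nstar), " draws)\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write an abundance summary as CSV
#'
#' @param ab An `mscjs_abundance`.
#' @param path File path.
#' @export
write_abundance_csv <- function(ab, path) {
  utils::write.csv(ab$summary, path, row.names = FALSE)
  invisible(path)
}
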