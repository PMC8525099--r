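#' True parameter set and design knobs for the synthetic-data generator
#'
#' Bundles everything needed to simulate a data set with exactly the
#' statistical structure the models assume: a full parameter vector (on the
#' same scale as [param_info()]), plus study-design knobs (annual cohort
#' sizes, telemetry deployments, entry-state distribution, effort).
#' Defaults emulate the southern Beaufort Sea study design: 16 annual
#' occasions, roughly 80 newly marked bears per year with a realistic
#' sex/age mix, adult survival near 0.92 with a mid-study low-survival
#' period, diagonal-dominant Markovian movement among 5 spatial states,
#' nearshore recapture probability near 0.35 with lower offshore
#' probabilities, a small unknown-age fraction mirroring biopsy sampling,
#' and around 8 telemetry deployments per year each contributing 3 annual
#' states.
#'
#' Any named parameter can be overridden through `params`; the derived
#' probability tables can be overridden wholesale through `phi`, `tau`,
#' `rho` (useful for degenerate limits such as perfect survival or
#' detection, which sit outside the open prior support).
#'
#' @param spec An [mscjs_spec()].
#' @param years Integer vector of study years.
#' @param cohort_size New first captures per year (scalar or per-year
#'   vector).  The last year's cohort is still generated (observed once,
#'   contributing nothing to the conditional likelihood).
#' @param telemetry_per_year Telemetry deployments per year.
#' @param telemetry_span Consecutive annual states contributed per
#'   deployment (clipped at the final year).
#' @param entry_state_probs Probability distribution over states 1-4 for
#'   first-capture / deployment states.
#' @param age_probs Named vector of probabilities over entry age groups
#'   `c(a0, a1, a2, a3_4, a5_19, a20)`.
#' @param unknown_age_fraction Fraction of newly captured bears aged >= 3
#'   whose age is hidden (recorded as biopsy identifications).
#' @param params Named numeric vector of parameter overrides.
#' @param phi,tau,rho Optional table overrides (see Details).
#' @param effort An [effort_table()] or `NULL` for the default.
#' @param recruitment `"cohort"` (first captures injected, guaranteeing the
#'   marked sample size) or `"population"` (bears enter a latent population
#'   and every capture, including the first, is a Bernoulli(rho) detection;
#'   capture counts then satisfy E[C_mk] = rho_mk * N_mk exactly, which the
#'   Horvitz-Thompson calibration relies on).
#' @return An object of class `mscjs_truth`.
#' @export
mscjs_truth <- function(spec = mscjs_spec(), years = 2001:2016,
                        cohort_size = 80, telemetry_per_year = 8,
                        telemetry_span = 3,
                        entry_state_probs = c(0.30, 0.40, 0.06, 0.24),
                        age_probs = c(a0 = 0.10, a1 = 0.10, a2 = 0.08,
                                      a3_4 = 0.12, a5_19 = 0.55, a20 = 0.05),
                        unknown_age_fraction = 0.10,
                        params = NULL, phi = NULL, tau = NULL, rho = NULL,
                        effort = NULL,
                        recruitment = c("cohort", "population")) {
  recruitment <- match.arg(recruitment)
  K <- length(years)
  stopifnot(K >= 3L, all(diff(years) == 1L))
  surv_years <- years[-K]
  recap_years <- years[-1L]
  stopifnot(length(entry_state_probs) == 4L,
            abs(sum(entry_state_probs) - 1) < 1e-8,
            abs(sum(age_probs) - 1) < 1e-8)

  # default true transition matrix: strong state fidelity, east/west
  # affinity, a persistent Elsewhere state
  tau_default <- rbind(c(0.55, 0.15, 0.10, 0.05, 0.15),
                       c(0.10, 0.60, 0.03, 0.12, 0.15),
                       c(0.20, 0.10, 0.40, 0.10, 0.20),
                       c(0.05, 0.25, 0.05, 0.45, 0.20),
                       c(0.10, 0.15, 0.05, 0.10, 0.60))

  # adult-male annual survival ~0.92, dipping to ~0.80 in a mid-study block
  lo <- seq_len(K - 1L) %in% seq(from = max(2L, floor((K - 1) / 3)),
                                 length.out = min(4L, K - 2L))
  aT5 <- ifelse(lo, log(1 / 0.80 - 1), log(1 / 0.92 - 1))

  p <- stats::setNames(numeric(0), character(0))
  add <- function(v) p <<- c(p, v)
  add(c(alphaF = 0.25))
  if (spec$survival == "additive") {
    add(c(alphaA0 = 0.9, alphaA1 = 0.6, alphaA2 = 0.5, alphaA3 = 0.35,
          alphaA20 = 0.45))
  } else {
    add(c(alphaA1 = 0.6, alphaA3 = 0.35, alphaA20 = 0.45))
  }
  add(stats::setNames(aT5, paste0("alphaT5_", surv_years)))
  if (spec$survival == "interactive") {
    add(stats::setNames(rep(0.9, K - 1L), paste0("alphaT0_", surv_years)))
    add(stats::setNames(rep(0.5, K - 1L), paste0("alphaT2_", surv_years)))
  }
  add(c(alphaW1 = 0.3, alphaW2 = 0.8))
  ups <- upsilon_from_tau(tau_default)
  add(stats::setNames(as.vector(t(ups)),
                      as.vector(t(outer(1:5, 1:4, function(m, n)
                        sprintf("upsilon_%d_%d", m, n))))))
  if (spec$recapture == "state_time") {
    add(stats::setNames(rep(0.6, K - 1L), paste0("beta1_", recap_years)))
  } else if (spec$time_varying_beta1) {
    add(stats::setNames(rep(2.5, K - 1L), paste0("beta1_", recap_years)))
  } else {
    add(c(beta1 = 2.5))
  }
  add(c(beta2 = 0.15, beta3 = 1.2, beta4 = 0.4))
  if (spec$recapture == "state_distance") {
    add(c(omega = 0.9))
    add(stats::setNames(rep(-6, 4L), paste0("theta_", 1:4)))
  }
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(p))
    if (length(bad)) stop("unknown parameter override: ",
                          paste(bad, collapse = ", "))
    p[names(params)] <- params
  }
  pinfo <- param_info(spec, years)
  p <- p[pinfo$name]
  if (any(p <= pinfo$lower | p >= pinfo$upper))
    stop("truth parameters must lie strictly inside the prior support")

  if (is.null(effort)) {
    effort <- effort_table(matrix(c(4500, 5000, 2000, 2500), 4L, K), years)
  }
  tabs <- list(
    phi = if (is.null(phi)) phi_table(p, spec, years) else phi,
    tau = if (is.null(tau)) transition_matrix(p) else tau,
    rho = if (is.null(rho)) rho_table(p, spec, years, effort) else rho)

  structure(list(spec = spec, years = years, params = p, tables = tabs,
                 effort = effort,
                 design = list(cohort_size = rep_len(cohort_size, K),
                               telemetry_per_year = telemetry_per_year,
                               telemetry_span = telemetry_span,
                               entry_state_probs = entry_state_probs,
                               age_probs = age_probs,
                               unknown_age_fraction = unknown_age_fraction,
                               recruitment = recruitment)),
            class = "mscjs_truth")
}

#' Invert the stick-breaking parameterization
#'
#' Given a 5 x 5 row-stochastic transition matrix (or its first four
#' columns), returns the 5 x 4 stick-breaking parameters that reproduce it.
#'
#' @param tau A 5 x 5 (or 5 x 4) matrix of transition probabilities.
#' @return 5 x 4 matrix of stick-breaking parameters in (0, 1).
#' @export
upsilon_from_tau <- function(tau) {
  tau <- as.matrix(tau)
  ups <- matrix(NA_real_, 5L, 4L)
  rem <- rep(1, 5L)
  for (n in 1:4) {
    ups[, n] <- tau[, n] / rem
    rem <- rem - tau[, n]
  }
  stopifnot(all(ups > 0 & ups < 1))
  ups
}

#' Simulate a synthetic mark-recapture / telemetry data set
#'
#' Generates capture histories, telemetry series, and the effort table under
#' the data-generating process the models assume: each bear's latent chain
#' follows sex/age/year survival then Markovian movement among the 5 spatial
#' states; bears alive in states 1-4 are detected with the state-year
#' recapture probability, and bears in state 5 or dead are never detected.
#' Telemetry bears contribute annual state sequences only (their survival is
#' not simulated; the models treat them as known alive).  The same seed
#' reproduces the identical data set.
#'
#' @param truth An [mscjs_truth()].
#' @param seed Integer seed.
#' @return An object of class `mscjs_sim`: `data` (an [mscjs_data()]),
#'   `latent` (bears x years matrix of true states; 6 = dead, 0 = pre-entry),
#'   `occupancy` (5 x years matrix counting simulated bears alive per state),
#'   `capture_counts` (4 x years matrix of captures C_mk), `entry_year`,
#'   and `truth`.
#' @export
simulate_dataset <- function(truth, seed = 1L) {
  set.seed(seed)
  years <- truth$years
  K <- length(years)
  phi <- truth$tables$phi; tau <- truth$tables$tau; rho <- truth$tables$rho
  rho[is.na(rho)] <- 0
  des <- truth$design
  pop_mode <- des$recruitment == "population"

  n <- sum(des$cohort_size)
  entry <- rep(seq_len(K), times = des$cohort_size)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  grp <- sample(seq_along(des$age_probs), n, replace = TRUE,
                prob = des$age_probs)
  age0 <- c(0L, 1L, 2L, 3L, 5L, 20L)[grp] +
    ifelse(grp == 4L, sample(0:1, n, replace = TRUE),
    ifelse(grp == 5L, sample(0:14, n, replace = TRUE),
    ifelse(grp == 6L, sample(0:5, n, replace = TRUE), 0L)))
  hide <- age0 >= 3 & stats::runif(n) < des$unknown_age_fraction

  latent <- matrix(0L, n, K)
  detected <- matrix(FALSE, n, K)
  si <- ifelse(sex == "F", 2L, 1L)
  for (b in seq_len(n)) {
    e <- entry[b]
    st <- sample.int(4L, 1L, prob = des$entry_state_probs)
    latent[b, e] <- st
    if (pop_mode) {
      detected[b, e] <- stats::runif(1) <= rho[st, e]
    } else {
      detected[b, e] <- TRUE   # injected first capture
    }
    if (e < K) for (t in (e + 1L):K) {
      cur <- latent[b, t - 1L]
      if (cur == 6L) { latent[b, t] <- 6L; next }
      cls <- age_class_index(if (is.na(age0[b]) || hide[b]) NA_integer_
                             else age0[b] + (t - 1L - e))
      ph <- phi[si[b], cls, t - 1L]
      if (stats::runif(1) > ph) { latent[b, t] <- 6L; next }
      latent[b, t] <- sample.int(5L, 1L, prob = tau[cur, ])
      if (latent[b, t] <= 4L)
        detected[b, t] <- stats::runif(1) <= rho[latent[b, t], t]
    }
  }

  # Unknown-age bears carry NA age in the emitted records; their latent
  # chain above already used the unknown-age mixture survival, matching the
  # model's data-generating assumption for that class.
  first_det <- apply(detected, 1L, function(d) if (any(d)) which(d)[1] else NA)
  obs_rows <- which(detected, arr.ind = TRUE)
  if (nrow(obs_rows) == 0L) {
    warning("degenerate truth: no bear was ever observed")
    observations <- data.frame(bear_id = character(0), year = integer(0),
                               sex = character(0), age = integer(0),
                               type = character(0), state = integer(0))
  } else {
    b <- obs_rows[, 1L]; t <- obs_rows[, 2L]
    observations <- data.frame(
      bear_id = sprintf("B%04d", b),
      year = years[t],
      sex = sex[b],
      age = ifelse(hide[b], NA_integer_, age0[b] + (t - entry[b])),
      type = ifelse(hide[b], "B", "C"),
      state = latent[cbind(b, t)],
      stringsAsFactors = FALSE)
    observations <- observations[order(observations$bear_id,
                                       observations$year), ]
  }

  # telemetry bears: state sequences only, known alive
  tel <- NULL
  if (des$telemetry_per_year > 0) {
    rows <- list()
    id <- 0L
    for (y in seq_len(K - 1L)) {
      for (r in seq_len(des$telemetry_per_year)) {
        id <- id + 1L
        span <- min(des$telemetry_span, K - y + 1L)
        if (span < 2L) next
        st <- integer(span)
        st[1L] <- sample.int(4L, 1L, prob = des$entry_state_probs)
        for (j in 2:span)
          st[j] <- sample.int(5L, 1L, prob = tau[st[j - 1L], ])
        rows[[length(rows) + 1L]] <-
          data.frame(bear_id = sprintf("T%03d", id),
                     year = years[y + seq_len(span) - 1L], state = st,
                     stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) tel <- do.call(rbind, rows)
  }

  occupancy <- sapply(seq_len(K), function(t) tabulate(latent[, t], nbins = 5L))
  dimnames(occupancy) <- list(state = 1:5, year = years)
  capture_counts <- sapply(seq_len(K), function(t) {
    cap <- detected[, t]
    tabulate(latent[cap, t], nbins = 4L)
  })
  dimnames(capture_counts) <- list(state = 1:4, year = years)

  data <- if (nrow(observations) > 0L)
    mscjs_data(observations, telemetry = tel, effort = truth$effort,
               years = years) else NULL

  structure(list(data = data, observations = observations, telemetry = tel,
                 effort = truth$effort, latent = latent,
                 detected = detected, entry_year = years[entry],
                 occupancy = occupancy, capture_counts = capture_counts,
                 truth = truth, seed = seed),
            class = "mscjs_sim")
}

#' @export
print.mscjs_sim <- function(x, ...) {
  cat("Synthetic multistate CJS data set (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$data)) print(x$data)
  invisible(x)
}

#' Save the truth parameters of a simulation as a sidecar file
#'
#' @param truth An [mscjs_truth()].
#' @param path File path (CSV: name, value).
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(data.frame(name = names(truth$params),
                              value = unname(truth$params)),
                   path, row.names = FALSE)
  invisible(path)
}
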