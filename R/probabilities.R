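#' Annual survival probabilities implied by a parameter vector
#'
#' Survival probabilities are inverse-logit expressions anchored on adult
#' (ages 5-19) males: a shared annual effect, a female effect, and
#' non-negative age-class increments whose uniform(0, 5) priors impose the
#' orderings cub <= yearling <= adult, age-2 <= subadult <= adult, and
#' old-adult <= adult within every sex and year.  Survival of unknown-age
#' bears is a mixture of the three adult-class survivals with stick-breaking
#' weights.  The probability labelled with year k covers the one-year period
#' from the spring of year k to the spring of year k + 1, so the last study
#' year has no survival parameter.
#'
#' @param params Named numeric vector of model parameters (see
#'   [param_info()]).
#' @param sex `"M"` or `"F"` (vectorized).
#' @param age_class Age-class label as in [age_class()] (vectorized).
#' @param year Survival year (vectorized).
#' @param spec An [mscjs_spec()].
#' @param years Integer vector of study years.
#' @return Numeric vector of survival probabilities.
#' @export
survival_prob <- function(params, sex, age_class, year, spec, years) {
  K <- length(years)
  surv_years <- years[-K]
  if (!all(year %in% surv_years))
    stop("survival is defined for years ", surv_years[1], "..",
         surv_years[K - 1L])
  tab <- phi_table(params, spec, years)
  si <- ifelse(sex == "F", 2L, 1L)
  ci <- match(age_class, mscjs_age_classes())
  if (anyNA(ci)) stop("unknown age-class label")
  ki <- match(year, surv_years)
  tab[cbind(si, ci, ki)]
}

# phi array [sex 1=M,2=F; class A0,A1,A2,A3_4,A5_19,A20plus,Unknown; year]
phi_table <- function(params, spec, years) {
  K <- length(years)
  surv_years <- years[-K]
  aT5 <- params[paste0("alphaT5_", surv_years)]
  aF <- params[["alphaF"]]
  aA1 <- params[["alphaA1"]]
  aA3 <- params[["alphaA3"]]
  aA20 <- params[["alphaA20"]]
  inv <- function(x) 1 / (1 + exp(x))
  tab <- array(NA_real_, c(2L, 7L, K - 1L))
  if (spec$survival == "additive") {
    e0 <- params[["alphaA0"]] + aA1
    e2 <- params[["alphaA2"]] + aA3
  } else {
    e0 <- params[paste0("alphaT0_", surv_years)] + aA1
    e2 <- params[paste0("alphaT2_", surv_years)] + aA3
  }
  for (s in 1:2) {
    base <- aT5 + if (s == 2L) aF else 0
    tab[s, 1L, ] <- inv(base + e0)
    tab[s, 2L, ] <- inv(base + aA1)
    tab[s, 3L, ] <- inv(base + e2)
    tab[s, 4L, ] <- inv(base + aA3)
    tab[s, 5L, ] <- inv(base)
    tab[s, 6L, ] <- inv(base + aA20)
  }
  w1 <- params[["alphaW1"]]; w2 <- params[["alphaW2"]]
  tab[, 7L, ] <- w1 * tab[, 4L, ] + (1 - w1) * w2 * tab[, 5L, ] +
    (1 - w1) * (1 - w2) * tab[, 6L, ]
  tab
}

#' State-transition matrix from stick-breaking parameters
#'
#' Each origin state m has four parameters in (0, 1); the transition
#' probabilities to destination states 1..5 are their stick-breaking
#' expansion, so every row is a proper probability vector with all entries
#' in (0, 1) and the residual stick going to state 5, "Elsewhere".
#'
#' @param upsilon A 5 x 4 matrix of stick-breaking parameters in (0, 1)
#'   (rows = origin state), or a named parameter vector containing
#'   `upsilon_m_n` entries.
#' @return A 5 x 5 row-stochastic matrix `tau`.
#' @examples
#' transition_matrix(matrix(0.5, 5, 4))[1, ]  # 0.5 0.25 0.125 0.0625 0.0625
#' @export
transition_matrix <- function(upsilon) {
  if (!is.matrix(upsilon)) {
    nm <- as.vector(t(outer(1:5, 1:4, function(m, n)
      sprintf("upsilon_%d_%d", m, n))))
    upsilon <- matrix(upsilon[nm], 5L, 4L, byrow = TRUE)
  }
  stopifnot(all(dim(upsilon) == c(5L, 4L)), all(upsilon > 0 & upsilon < 1))
  tau <- matrix(0, 5L, 5L, dimnames = list(from = 1:5, to = 1:5))
  rem <- rep(1, 5L)
  for (n in 1:4) {
    tau[, n] <- rem * upsilon[, n]
    rem <- rem * (1 - upsilon[, n])
  }
  tau[, 5L] <- rem
  tau
}

#' Annual recapture probabilities implied by a parameter vector
#'
#' In the State + Time submodel, recapture probability is an inverse-logit of
#' a free annual effect plus state effects; the non-negative offshore effects
#' impose nearshore >= offshore within each east/west region
#' (rho1 >= rho3, rho2 >= rho4).  In the State + Distance submodel the annual
#' effect is replaced (by default) by a time-constant baseline plus
#' state-specific coefficients on the distance flown searching in that
#' state-year, and a ceiling parameter `omega` bounds recapture probability
#' away from 1.  Bears in state 5 ("Elsewhere") or dead are unobservable;
#' recapture is defined for states 1-4 and for every occasion after the
#' first.
#'
#' @inheritParams survival_prob
#' @param state Spatial state 1..4 (vectorized).
#' @param year Recapture year (vectorized).
#' @param effort An [effort_table()]; required by `"state_distance"`.
#' @return Numeric vector of recapture probabilities.
#' @export
recapture_prob <- function(params, state, year, spec, years, effort = NULL) {
  recap_years <- years[-1L]
  if (!all(state %in% 1:4)) stop("state must be in 1..4")
  if (!all(year %in% recap_years))
    stop("recapture is defined for years ", recap_years[1], "..",
         max(recap_years))
  tab <- rho_table(params, spec, years, effort)
  tab[cbind(state, match(year, years))]
}

# rho matrix 4 x K; column 1 (first occasion) is NA, never used
rho_table <- function(params, spec, years, effort = NULL) {
  K <- length(years)
  recap_years <- years[-1L]
  b2 <- params[["beta2"]]; b3 <- params[["beta3"]]; b4 <- params[["beta4"]]
  state_eff <- c(0, b2, b3, b2 + b4)
  tab <- matrix(NA_real_, 4L, K, dimnames = list(state = 1:4, year = years))
  if (spec$recapture == "state_time") {
    b1 <- params[paste0("beta1_", recap_years)]
    for (m in 1:4) tab[m, -1L] <- 1 / (1 + exp(b1 + state_eff[m]))
  } else {
    if (is.null(effort))
      stop("the State + Distance submodel requires an effort table")
    eff_years <- as.integer(colnames(effort))
    if (!all(recap_years %in% eff_years))
      stop("effort table does not cover the recapture years")
    d <- unclass(effort)[, match(recap_years, eff_years), drop = FALSE] /
      spec$effort_scale
    b1 <- if (spec$time_varying_beta1)
      params[paste0("beta1_", recap_years)] else params[["beta1"]]
    om <- params[["omega"]]
    th <- params[paste0("theta_", 1:4)]
    for (m in 1:4)
      tab[m, -1L] <- om / (1 + exp(b1 + state_eff[m] + th[m] * d[m, ]))
  }
  tab
}
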