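#' MCMC configuration
#'
#' Defaults mirror the full analysis configuration: 5 chains, 200,000
#' burn-in iterations, 100,000 further iterations storing every 25th, for
#' 20,000 stored draws in total.  [mcmc_config_reduced()] gives the much
#' smaller configuration used for desk-scale testing and examples
#' (3 chains, 2,000 + 2,000, no thinning).
#'
#' @param chains Number of Markov chains.
#' @param burn_in Burn-in iterations per chain (discarded; proposal scales
#'   adapt only during this phase).
#' @param iterations Post-burn-in iterations per chain.
#' @param thin Store every `thin`-th post-burn-in iteration.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 5L, burn_in = 200000L, iterations = 100000L,
                        thin = 25L) {
  stopifnot(chains >= 1L, burn_in >= 0L, iterations >= thin, thin >= 1L,
            iterations %% thin == 0L)
  structure(list(chains = as.integer(chains), burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations), thin = as.integer(thin),
                 stored_per_chain = as.integer(iterations / thin)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
mcmc_config_reduced <- function(chains = 3L, burn_in = 2000L,
                                iterations = 2000L, thin = 1L) {
  mcmc_config(chains, burn_in, iterations, thin)
}

# fast parameter-vector -> probability-table builders using precomputed
# integer indices (the name-based phi_table/rho_table are the reference
# implementations; equivalence is covered by tests)
make_builders <- function(spec, years, pinfo, effort) {
  K <- length(years)
  surv_years <- years[-K]
  recap_years <- years[-1L]
  ix <- function(nm) {
    i <- match(nm, pinfo$name)
    if (anyNA(i)) stop("internal: missing parameter ", nm[which(is.na(i))[1]])
    i
  }
  i_aF <- ix("alphaF"); i_aA1 <- ix("alphaA1"); i_aA3 <- ix("alphaA3")
  i_aA20 <- ix("alphaA20")
  i_aT5 <- ix(paste0("alphaT5_", surv_years))
  additive <- spec$survival == "additive"
  if (additive) {
    i_aA0 <- ix("alphaA0"); i_aA2 <- ix("alphaA2")
  } else {
    i_aT0 <- ix(paste0("alphaT0_", surv_years))
    i_aT2 <- ix(paste0("alphaT2_", surv_years))
  }
  i_w <- ix(c("alphaW1", "alphaW2"))
  phi_fun <- function(theta) {
    aT5 <- theta[i_aT5]
    aA1 <- theta[i_aA1]; aA3 <- theta[i_aA3]
    e0 <- if (additive) theta[i_aA0] + aA1 else theta[i_aT0] + aA1
    e2 <- if (additive) theta[i_aA2] + aA3 else theta[i_aT2] + aA3
    tab <- array(NA_real_, c(2L, 7L, K - 1L))
    for (s in 1:2) {
      base <- aT5 + if (s == 2L) theta[i_aF] else 0
      tab[s, 1L, ] <- 1 / (1 + exp(base + e0))
      tab[s, 2L, ] <- 1 / (1 + exp(base + aA1))
      tab[s, 3L, ] <- 1 / (1 + exp(base + e2))
      tab[s, 4L, ] <- 1 / (1 + exp(base + aA3))
      tab[s, 5L, ] <- 1 / (1 + exp(base))
      tab[s, 6L, ] <- 1 / (1 + exp(base + theta[i_aA20]))
    }
    w1 <- theta[i_w[1]]; w2 <- theta[i_w[2]]
    tab[, 7L, ] <- w1 * tab[, 4L, ] + (1 - w1) * w2 * tab[, 5L, ] +
      (1 - w1) * (1 - w2) * tab[, 6L, ]
    tab
  }

  i_ups <- matrix(ix(as.vector(t(outer(1:5, 1:4, function(m, n)
    sprintf("upsilon_%d_%d", m, n))))), 5L, 4L, byrow = TRUE)
  tau_fun <- function(theta) {
    u <- matrix(theta[t(i_ups)], 5L, 4L, byrow = TRUE)
    tau <- matrix(0, 5L, 5L)
    rem <- rep(1, 5L)
    for (n in 1:4) {
      tau[, n] <- rem * u[, n]
      rem <- rem * (1 - u[, n])
    }
    tau[, 5L] <- rem
    tau
  }

  i_b234 <- ix(c("beta2", "beta3", "beta4"))
  state_time_like <- spec$recapture == "state_time" || spec$time_varying_beta1
  if (state_time_like) {
    i_b1 <- ix(paste0("beta1_", recap_years))
  } else {
    i_b1 <- ix("beta1")
  }
  if (spec$recapture == "state_distance") {
    if (is.null(effort))
      stop("the State + Distance submodel requires an effort table")
    eff_years <- as.integer(colnames(effort))
    d_scaled <- unclass(effort)[, match(recap_years, eff_years),
                                drop = FALSE] / spec$effort_scale
    i_om <- ix("omega"); i_th <- ix(paste0("theta_", 1:4))
  }
  rho_fun <- function(theta) {
    se <- c(0, theta[i_b234[1]], theta[i_b234[2]],
            theta[i_b234[1]] + theta[i_b234[3]])
    tab <- matrix(0, 4L, K)
    b1 <- theta[i_b1]
    if (spec$recapture == "state_time") {
      for (m in 1:4) tab[m, -1L] <- 1 / (1 + exp(b1 + se[m]))
    } else {
      om <- theta[i_om]; th <- theta[i_th]
      for (m in 1:4)
        tab[m, -1L] <- om / (1 + exp(b1 + se[m] + th[m] * d_scaled[m, ]))
    }
    tab
  }
  list(phi = phi_fun, tau = tau_fun, rho = rho_fun)
}

#' Sample the posterior of a multistate CJS model
#'
#' Adaptive Metropolis-within-Gibbs sampling of the joint posterior of all
#' model parameters.  The target density is the product of the uniform
#' priors, the marginalized capture-history likelihood
#' ([history_loglik()]), and the telemetry transition likelihood
#' ([telemetry_loglik()]).  Each scalar parameter is updated in turn with a
#' Gaussian random-walk proposal (proposals outside the prior support are
#' rejected); proposal scales adapt toward a 44% acceptance rate in batches
#' of 50 iterations during burn-in only, so the post-burn-in kernel is fixed
#' and the chain targets the exact posterior.  Chains start from independent
#' draws from the prior and run sequentially from a single seeded RNG
#' stream, so results are exactly reproducible for a given seed.
#'
#' In models where both survival and recapture vary freely through time, the
#' final-year survival and recapture parameters are confounded (only their
#' product is identified); they are sampled like any other parameter but
#' flagged, and default summaries exclude them.
#'
#' @param data An [mscjs_data()] object.
#' @param spec An [mscjs_spec()].
#' @param config An [mcmc_config()]; default [mcmc_config_reduced()].
#' @param seed Integer seed controlling every source of randomness.
#' @param init Optional list of named start vectors, one per chain.
#' @param verbose Print progress.
#' @return An object of class `mscjs_fit`: stored draws and deviances per
#'   chain, acceptance rates, parameter metadata, the spec/config/data.
#' @export
fit_mscjs <- function(data, spec, config = mcmc_config_reduced(), seed = 1L,
                      init = NULL, verbose = FALSE) {
  stopifnot(inherits(data, "mscjs_data"), inherits(spec, "mscjs_spec"))
  pinfo <- param_info(spec, data$years)
  P <- nrow(pinfo)
  builders <- make_builders(spec, data$years, pinfo, data$effort)
  tel_stats <- data$tel_trans
  is_trans <- pinfo$block == "transition"
  is_surv <- pinfo$block == "survival"

  loglik_parts <- function(theta, phi = NULL, tau = NULL, rho = NULL) {
    if (is.null(phi)) phi <- builders$phi(theta)
    if (is.null(tau)) tau <- builders$tau(theta)
    if (is.null(rho)) rho <- builders$rho(theta)
    lh <- cjs_ll(data, phi, tau, rho)
    lt <- if (is.null(tel_stats)) 0 else tel_loglik_stats(tel_stats, tau)
    list(hist = lh, tel = lt, phi = phi, tau = tau, rho = rho)
  }

  # joint translation moves along the model's structural ridges: the annual
  # survival and recapture baselines trade off against the effects added to
  # them, which scalar updates traverse slowly.  Each move shifts a block by
  # a common delta (optionally shifting a companion parameter oppositely);
  # proposals are symmetric, so the target is unchanged.
  trans_moves <- list()
  aT5_idx <- grep("^alphaT5_", pinfo$name)
  b1_idx <- grep("^beta1", pinfo$name)
  b2_idx <- match("beta2", pinfo$name)
  if (length(aT5_idx) > 1L)
    trans_moves <- c(trans_moves,
                     list(list(plus = aT5_idx, minus = integer(0),
                               block = "survival")))
  b3_idx <- match("beta3", pinfo$name)
  b4_idx <- match("beta4", pinfo$name)
  if (length(b1_idx) > 0L)
    trans_moves <- c(trans_moves,
                     list(list(plus = b1_idx, minus = b2_idx,
                               block = "recapture"),
                          list(plus = b1_idx, minus = b3_idx,
                               block = "recapture"),
                          list(plus = b1_idx, minus = c(b2_idx, b4_idx),
                               block = "recapture"),
                          list(plus = b1_idx, minus = integer(0),
                               block = "recapture")))
  n_tm <- length(trans_moves)

  set.seed(seed)
  n_iter <- config$burn_in + config$iterations
  draws <- vector("list", config$chains)
  deviance <- vector("list", config$chains)
  accept_rate <- matrix(NA_real_, config$chains, P,
                        dimnames = list(NULL, pinfo$name))

  for (ch in seq_len(config$chains)) {
    # random start from the prior; bounded retries on a non-finite target
    theta <- NULL
    for (try in 1:100) {
      cand <- stats::runif(P, pinfo$lower, pinfo$upper)
      names(cand) <- pinfo$name
      if (!is.null(init) && length(init) >= ch && !is.null(init[[ch]])) {
        cand[names(init[[ch]])] <- init[[ch]]
      }
      parts <- loglik_parts(cand)
      if (is.finite(parts$hist + parts$tel)) { theta <- cand; break }
    }
    if (is.null(theta)) stop("could not find a finite starting point")
    ll_hist <- parts$hist; ll_tel <- parts$tel
    phi <- parts$phi; tau <- parts$tau; rho <- parts$rho

    sd <- pmin(1, 0.1 * (pinfo$upper - pinfo$lower))
    n_acc <- n_try <- rep(0, P)
    b_acc <- b_try <- rep(0, P)
    tsd <- rep(0.2, n_tm)
    tb_acc <- tb_try <- rep(0, n_tm)
    batch <- 0L
    stored <- matrix(NA_real_, config$stored_per_chain, P,
                     dimnames = list(NULL, pinfo$name))
    dev <- numeric(config$stored_per_chain)
    s_row <- 0L

    for (it in seq_len(n_iter)) {
      for (i in seq_len(P)) {
        b_try[i] <- b_try[i] + 1; n_try[i] <- n_try[i] + 1
        prop <- theta[i] + stats::rnorm(1, 0, sd[i])
        if (prop <= pinfo$lower[i] || prop >= pinfo$upper[i]) next
        old <- theta[i]
        theta[i] <- prop
        if (is_surv[i]) {
          phi_new <- builders$phi(theta)
          lh_new <- sum(cjs_ll(data, phi_new, tau, rho))
          lt_new <- ll_tel
          dl <- lh_new - ll_hist
        } else if (is_trans[i]) {
          tau_new <- builders$tau(theta)
          lh_new <- sum(cjs_ll(data, phi, tau_new, rho))
          lt_new <- if (is.null(tel_stats)) 0 else
            tel_loglik_stats(tel_stats, tau_new)
          dl <- (lh_new + lt_new) - (ll_hist + ll_tel)
        } else {
          rho_new <- builders$rho(theta)
          lh_new <- sum(cjs_ll(data, phi, tau, rho_new))
          lt_new <- ll_tel
          dl <- lh_new - ll_hist
        }
        if (is.finite(dl) && log(stats::runif(1)) < dl) {
          ll_hist <- lh_new; ll_tel <- lt_new
          if (is_surv[i]) phi <- phi_new
          else if (is_trans[i]) tau <- tau_new
          else rho <- rho_new
          b_acc[i] <- b_acc[i] + 1; n_acc[i] <- n_acc[i] + 1
        } else {
          theta[i] <- old
        }
      }
      for (g in seq_len(n_tm)) {
        mv <- trans_moves[[g]]
        tb_try[g] <- tb_try[g] + 1
        delta <- stats::rnorm(1, 0, tsd[g])
        cand <- theta
        cand[mv$plus] <- cand[mv$plus] + delta
        if (length(mv$minus)) cand[mv$minus] <- cand[mv$minus] - delta
        moved <- c(mv$plus, mv$minus)
        if (any(cand[moved] <= pinfo$lower[moved] |
                  cand[moved] >= pinfo$upper[moved])) next
        if (mv$block == "survival") {
          phi_new <- builders$phi(cand)
          lh_new <- cjs_ll(data, phi_new, tau, rho)
        } else {
          rho_new <- builders$rho(cand)
          lh_new <- cjs_ll(data, phi, tau, rho_new)
        }
        dl <- lh_new - ll_hist
        if (is.finite(dl) && log(stats::runif(1)) < dl) {
          theta <- cand
          ll_hist <- lh_new
          if (mv$block == "survival") phi <- phi_new else rho <- rho_new
          tb_acc[g] <- tb_acc[g] + 1
        }
      }
      if (it <= config$burn_in && it %% 50L == 0L) {
        batch <- batch + 1L
        delta <- min(0.1, 1 / sqrt(batch))
        rate <- ifelse(b_try > 0, b_acc / b_try, 0.44)
        sd <- sd * exp(ifelse(rate > 0.44, delta, -delta))
        b_acc <- b_try <- rep(0, P)
        if (n_tm > 0L) {
          trate <- ifelse(tb_try > 0, tb_acc / tb_try, 0.44)
          tsd <- tsd * exp(ifelse(trate > 0.44, delta, -delta))
          tb_acc <- tb_try <- rep(0, n_tm)
        }
      }
      if (it == config$burn_in) n_acc <- n_try <- rep(0, P)
      if (it > config$burn_in &&
          (it - config$burn_in) %% config$thin == 0L) {
        s_row <- s_row + 1L
        stored[s_row, ] <- theta
        dev[s_row] <- -2 * (ll_hist + ll_tel)
      }
      if (verbose && it %% 500L == 0L)
        message(sprintf("chain %d: iteration %d / %d", ch, it, n_iter))
    }
    draws[[ch]] <- stored
    deviance[[ch]] <- dev
    accept_rate[ch, ] <- ifelse(n_try > 0, n_acc / n_try, NA_real_)
  }

  nonid <- character(0)
  K <- length(data$years)
  last_surv <- data$years[K - 1L]
  time_varying_recap <- spec$recapture == "state_time" ||
    spec$time_varying_beta1
  if (time_varying_recap) {
    nonid <- c(paste0("alphaT5_", last_surv),
               if (spec$survival == "interactive")
                 c(paste0("alphaT0_", last_surv), paste0("alphaT2_", last_surv)),
               paste0("beta1_", data$years[K]))
  }

  structure(list(draws = draws, deviance = deviance,
                 accept_rate = accept_rate, param_info = pinfo,
                 nonidentified = nonid, spec = spec, config = config,
                 seed = seed, data = data),
            class = "mscjs_fit")
}

#' @export
print.mscjs_fit <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %d chains x %d stored draws (%d parameters); seed %d\n",
              x$config$chains, x$config$stored_per_chain,
              nrow(x$param_info), x$seed))
  cat(sprintf("  mean acceptance rate %.2f\n", mean(x$accept_rate)))
  if (length(x$nonidentified))
    cat("  non-identified (final-year confounded) parameters excluded from",
        "default summaries:\n   ", paste(x$nonidentified, collapse = ", "),
        "\n")
  invisible(x)
}

# internal shim so the sampler's hot loop reads tersely; weighted total
# over deduplicated profiles
cjs_ll <- function(data, phi, tau, rho) {
  d <- data$dedup
  cpp_cjs_loglik_wt(d$enc_t, d$first, d$sex, d$acl_t, as.vector(phi),
                    tau, rho, d$weight)
}

#' Stacked draws matrix
#'
#' @param fit An `mscjs_fit`.
#' @return Matrix of stored draws from all chains with `chain` and
#'   `iteration` columns prepended.
#' @export
as_draws_matrix <- function(fit) {
  out <- do.call(rbind, fit$draws)
  n <- fit$config$stored_per_chain
  cbind(chain = rep(seq_along(fit$draws), each = n),
        iteration = rep(seq_len(n), times = length(fit$draws)),
        out)
}

#' Posterior summaries of model parameters
#'
#' Mean, SD, central quantiles, and the Gelman-Rubin diagnostic per
#' parameter.  Final-year confounded parameters are dropped by default.
#'
#' @param fit An `mscjs_fit`.
#' @param pars Optional character vector of parameter names.
#' @param include_nonidentified Keep the final-year confounded parameters.
#' @return A data.frame, one row per parameter.
#' @export
posterior_summary <- function(fit, pars = NULL,
                              include_nonidentified = FALSE) {
  nm <- fit$param_info$name
  if (!is.null(pars)) nm <- intersect(nm, pars)
  if (!include_nonidentified) nm <- setdiff(nm, fit$nonidentified)
  all_draws <- do.call(rbind, fit$draws)
  out <- do.call(rbind, lapply(nm, function(p) {
    x <- all_draws[, p]
    q <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
    rc <- gelman_rubin(lapply(fit$draws, function(d) d[, p]))
    data.frame(param = p, mean = mean(x), sd = stats::sd(x),
               q2.5 = q[1], q25 = q[2], median = q[3], q75 = q[4],
               q97.5 = q[5], Rc = rc$Rc)
  }))
  rownames(out) <- NULL
  out
}

#' Posterior draws of derived survival probabilities
#'
#' @param fit An `mscjs_fit`.
#' @param sex `"M"` or `"F"`.
#' @param age_class Age-class label (see [age_class()]).
#' @return Matrix (stored draws x survival years) of survival probabilities.
#' @export
survival_draws <- function(fit, sex = "M", age_class = "A5_19") {
  years <- fit$data$years
  surv_years <- years[-length(years)]
  builders <- make_builders(fit$spec, years, fit$param_info, fit$data$effort)
  si <- if (sex == "F") 2L else 1L
  ci <- match(age_class, mscjs_age_classes())
  all_draws <- do.call(rbind, fit$draws)
  out <- t(apply(all_draws, 1L, function(theta) builders$phi(theta)[si, ci, ]))
  colnames(out) <- surv_years
  out
}

#' Posterior draws of state-transition probabilities
#'
#' @param fit An `mscjs_fit`.
#' @return Matrix (stored draws x 25) of transition probabilities, columns
#'   named `tau_m_n`.
#' @export
transition_draws <- function(fit) {
  builders <- make_builders(fit$spec, fit$data$years, fit$param_info,
                            fit$data$effort)
  all_draws <- do.call(rbind, fit$draws)
  out <- t(apply(all_draws, 1L, function(theta) as.vector(builders$tau(theta))))
  colnames(out) <- as.vector(outer(1:5, 1:5, function(m, n)
    sprintf("tau_%d_%d", m, n)))
  out
}

#' Posterior draws of recapture probabilities
#'
#' @param fit An `mscjs_fit`.
#' @return Array (stored draws x 4 states x occasions); the first occasion
#'   slice is zero (no recapture is defined there).
#' @export
recapture_draws <- function(fit) {
  builders <- make_builders(fit$spec, fit$data$years, fit$param_info,
                            fit$data$effort)
  all_draws <- do.call(rbind, fit$draws)
  K <- length(fit$data$years)
  out <- array(NA_real_, c(nrow(all_draws), 4L, K),
               dimnames = list(NULL, 1:4, fit$data$years))
  for (r in seq_len(nrow(all_draws)))
    out[r, , ] <- builders$rho(all_draws[r, ])
  out
}

#' Write / read stored draws as CSV
#'
#' One column per named scalar parameter plus `chain`, `iteration`, and
#' `deviance` columns.
#'
#' @param fit An `mscjs_fit`.
#' @param path File path.
#' @rdname draws_io
#' @export
write_draws_csv <- function(fit, path) {
  m <- as_draws_matrix(fit)
  df <- as.data.frame(m)
  df$deviance <- unlist(fit$deviance)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
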