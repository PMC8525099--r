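#' Gelman-Rubin potential scale reduction factor
#'
#' The basic between/within-chain variance diagnostic: with m chains of
#' length n, `W` is the mean within-chain variance, `B/n` the variance of
#' the chain means, and `Rc = sqrt(((n-1)/n * W + B/n) / W)`.  Values below
#' 1.1 are conventionally taken to indicate convergence.  Chains with zero
#' within-chain variance (stuck or constant) are flagged degenerate.
#'
#' @param chains A list of numeric vectors (equal length >= 10), one per
#'   chain.
#' @return A list with `Rc`, `W`, `B`, and logical `degenerate`.
#' @export
gelman_rubin <- function(chains) {
  m <- length(chains)
  stopifnot(m >= 2L)
  n <- unique(lengths(chains))
  stopifnot(length(n) == 1L, n >= 10L)
  W <- mean(vapply(chains, stats::var, numeric(1)))
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  if (!is.finite(W) || W <= 0)
    return(list(Rc = NA_real_, W = W, B = B, degenerate = TRUE))
  varplus <- (n - 1) / n * W + B / n
  list(Rc = sqrt(varplus / W), W = W, B = B, degenerate = FALSE)
}

#' Deviance information criterion
#'
#' `pD = mean(deviance) - deviance_at_mean` (effective number of
#' parameters) and `DIC = mean(deviance) + pD`.
#'
#' @param deviance_draws Numeric vector of per-draw deviances.
#' @param deviance_at_mean Deviance evaluated at the posterior mean of the
#'   parameters.
#' @return A list with `DIC`, `pD`, and `mean_deviance`.
#' @examples
#' dic(c(10, 14), 11)  # pD = 1, DIC = 13
#' @export
dic <- function(deviance_draws, deviance_at_mean) {
  stopifnot(all(is.finite(deviance_draws)), is.finite(deviance_at_mean))
  Dbar <- mean(deviance_draws)
  pD <- Dbar - deviance_at_mean
  list(DIC = Dbar + pD, pD = pD, mean_deviance = Dbar)
}

#' Bayesian p-value from per-draw discrepancies
#'
#' The fraction of posterior draws in which the replicated-data discrepancy
#' is at least the observed-data discrepancy (ties count toward the
#' numerator).  Values near 0 or 1 indicate misfit.
#'
#' @param observed_stats,replicated_stats Numeric vectors of equal length,
#'   one discrepancy pair per draw.
#' @return Scalar p-value in `[0, 1]`.
#' @export
freeman_tukey_pvalue <- function(observed_stats, replicated_stats) {
  stopifnot(length(observed_stats) == length(replicated_stats))
  mean(replicated_stats >= observed_stats)
}

# model deviance at an arbitrary parameter vector
model_deviance <- function(data, params, spec) {
  -2 * (history_loglik(data, params, spec) +
          (if (is.null(data$tel_trans)) 0 else
             tel_loglik_stats(data$tel_trans, transition_matrix(params))))
}

#' Freeman-Tukey posterior predictive check
#'
#' For each stored draw, the observed data and one replicated data set
#' (simulated from the draw's parameters conditional on each bear's first
#' observation) are each compared against the draw's expected values with
#' the Freeman-Tukey discrepancy `sum((sqrt(count) - sqrt(expected))^2)`.
#' The data partition is annual detection counts by spatial state (4 states
#' x recapture occasions); expected counts come from each draw's survival,
#' transition, and recapture probabilities by forward recursion over the
#' marked bears.  The Bayesian p-value is the fraction of draws whose
#' replicated discrepancy is at least the observed one.
#'
#' @param fit An `mscjs_fit`.
#' @param n_draws Use at most this many stored draws (evenly thinned);
#'   `NULL` for all.
#' @param seed Seed for the replicated data sets.
#' @return A list with `p_B` and the per-draw discrepancies `T_obs`,
#'   `T_rep`.
#' @export
freeman_tukey_check <- function(fit, n_draws = NULL, seed = 1L) {
  data <- fit$data
  K <- length(data$years)
  builders <- make_builders(fit$spec, data$years, fit$param_info,
                            data$effort)
  all_draws <- do.call(rbind, fit$draws)
  if (!is.null(n_draws) && n_draws < nrow(all_draws)) {
    idx <- unique(round(seq(1L, nrow(all_draws), length.out = n_draws)))
    all_draws <- all_draws[idx, , drop = FALSE]
  }
  # observed detection counts exclude each bear's first (conditioned-on)
  # observation
  obs_counts <- matrix(0, 4L, K)
  enc <- data$encounter
  for (b in seq_len(nrow(enc))) {
    f <- data$first_idx[b]
    if (f < K) for (t in (f + 1L):K) {
      o <- enc[b, t]
      if (o >= 1L) obs_counts[o, t] <- obs_counts[o, t] + 1
    }
  }
  D <- nrow(all_draws)
  T_obs <- T_rep <- numeric(D)
  set.seed(seed)
  for (d in seq_len(D)) {
    theta <- all_draws[d, ]
    phi <- as.vector(builders$phi(theta))
    tau <- builders$tau(theta)
    rho <- builders$rho(theta)
    expd <- cpp_expected_counts(enc, data$first_idx, data$sex_idx,
                                data$age_class_idx, phi, tau, rho)
    repc <- cpp_simulate_counts(enc, data$first_idx, data$sex_idx,
                                data$age_class_idx, phi, tau, rho)
    T_obs[d] <- sum((sqrt(obs_counts) - sqrt(expd))^2)
    T_rep[d] <- sum((sqrt(repc) - sqrt(expd))^2)
  }
  list(p_B = freeman_tukey_pvalue(T_obs, T_rep), T_obs = T_obs,
       T_rep = T_rep)
}

#' Assess a fitted model
#'
#' Convergence (max Gelman-Rubin Rc over parameters, with and without the
#' final-year confounded parameters), DIC, and the Freeman-Tukey Bayesian
#' p-value.
#'
#' @param fit An `mscjs_fit`.
#' @param gof_draws Number of draws for the posterior predictive check.
#' @param seed Seed for the replicated data sets.
#' @return An object of class `mscjs_assessment` (a list with `NP`, `DIC`,
#'   `pD`, `p_B`, `max_Rc`, `max_Rc_identified`, `Rc` per parameter).
#' @export
assess_model <- function(fit, gof_draws = 500L, seed = 1L) {
  pinfo <- fit$param_info
  Rc <- vapply(pinfo$name, function(p) {
    gelman_rubin(lapply(fit$draws, function(d) d[, p]))$Rc
  }, numeric(1))
  dev_draws <- unlist(fit$deviance)
  theta_bar <- colMeans(do.call(rbind, fit$draws))
  d <- dic(dev_draws, model_deviance(fit$data, theta_bar, fit$spec))
  ft <- freeman_tukey_check(fit, n_draws = gof_draws, seed = seed)
  ident <- setdiff(pinfo$name, fit$nonidentified)
  structure(list(NP = nrow(pinfo), DIC = d$DIC, pD = d$pD,
                 mean_deviance = d$mean_deviance, p_B = ft$p_B,
                 max_Rc = max(Rc, na.rm = TRUE),
                 max_Rc_identified = max(Rc[ident], na.rm = TRUE),
                 Rc = Rc),
            class = "mscjs_assessment")
}

#' @export
print.mscjs_assessment <- function(x, ...) {
  cat(sprintf(paste0("Model assessment: NP %d, DIC %.1f (pD %.1f), ",
                     "p_B %.3f, max Rc %.3f (%.3f excl. confounded)\n"),
              x$NP, x$DIC, x$pD, x$p_B, x$max_Rc, x$max_Rc_identified))
  invisible(x)
}

#' Compare fitted models
#'
#' @param fits A named list of `mscjs_fit` objects.
#' @param ... Passed to [assess_model()].
#' @return A data.frame with one row per model (NP, p_B, DIC, deltaDIC),
#'   ordered by DIC.
#' @export
compare_models <- function(fits, ...) {
  rows <- lapply(fits, function(f) {
    a <- assess_model(f, ...)
    data.frame(survival = f$spec$survival, recapture = f$spec$recapture,
               NP = a$NP, p_B = a$p_B, DIC = a$DIC, max_Rc = a$max_Rc)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$DIC), ]
  out$deltaDIC <- out$DIC - out$DIC[1L]
  out
}
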