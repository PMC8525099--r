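#' Marginalized log-likelihood of the capture histories
#'
#' The capture-history component of the likelihood, marginalized over the
#' latent state process with the hidden-Markov forward algorithm.  Each
#' bear's likelihood conditions on its first observation; thereafter the
#' 6-state latent chain (spatial states 1-5 plus an absorbing dead state)
#' propagates with survival-times-transition probabilities, and each
#' occasion contributes an observation factor: the recapture probability of
#' the observed state, or the appropriate non-detection probability (1 for
#' state 5 and for dead bears, which are unobservable).
#'
#' @param data An [mscjs_data()] object.
#' @param params Named numeric parameter vector (see [param_info()]).
#' @param spec An [mscjs_spec()].
#' @param per_bear If `TRUE`, return the per-bear log-likelihood vector.
#' @return Total log-likelihood (or per-bear vector).
#' @export
history_loglik <- function(data, params, spec, per_bear = FALSE) {
  phi <- phi_table(params, spec, data$years)
  tau <- transition_matrix(params)
  rho <- rho_table(params, spec, data$years, data$effort)
  ll <- cjs_loglik_tables(data, phi, tau, rho)
  if (per_bear) ll else sum(ll)
}

# table-level entry point shared with the sampler; rho NAs (first occasion)
# are replaced by 0 before crossing into C++
cjs_loglik_tables <- function(data, phi, tau, rho) {
  rho[is.na(rho)] <- 0
  cpp_cjs_loglik(data$encounter, data$first_idx, data$sex_idx,
                 data$age_class_idx, as.vector(phi), tau, rho)
}

#' Log-likelihood of the telemetry state sequences
#'
#' Telemetry-instrumented bears are known alive over their span, so they
#' inform only the state-transition probabilities: each pair of successive
#' annual assignments contributes the corresponding transition probability,
#' and a gap of g years contributes the (from, to) entry of the g-step
#' Chapman-Kolmogorov product of the 5-state transition matrix.
#'
#' @param telemetry A data.frame with columns `bear_id`, `year`, `state`
#'   (each bear sorted by year), or an [mscjs_data()] object.
#' @param tau A 5 x 5 transition matrix (see [transition_matrix()]), or a
#'   named parameter vector with `upsilon_m_n` entries.
#' @return Total log-likelihood.
#' @export
telemetry_loglik <- function(telemetry, tau) {
  if (!is.matrix(tau)) tau <- transition_matrix(tau)
  tt <- if (inherits(telemetry, "mscjs_data")) telemetry$tel_trans
        else build_tel_trans(telemetry)
  if (is.null(tt) || nrow(tt) == 0L) return(0)
  tel_loglik_stats(tt, tau)
}

build_tel_trans <- function(tel) {
  tel <- tel[order(tel$bear_id, tel$year), , drop = FALSE]
  if (nrow(tel) < 2L) return(NULL)
  i <- seq_len(nrow(tel) - 1L)
  same <- tel$bear_id[i] == tel$bear_id[i + 1L]
  tt <- data.frame(from = tel$state[i][same], to = tel$state[i + 1L][same],
                   gap = tel$year[i + 1L][same] - tel$year[i][same])
  stats::aggregate(list(count = rep(1L, nrow(tt))), by = tt, FUN = sum)
}

tel_loglik_stats <- function(tt, tau) {
  idx <- tt$from + 5L * (tt$to - 1L)
  max_gap <- max(tt$gap)
  out <- 0
  P <- tau
  for (g in seq_len(max_gap)) {
    sel <- tt$gap == g
    if (any(sel)) out <- out + sum(tt$count[sel] * log(P[idx[sel]]))
    if (g < max_gap) P <- P %*% tau
  }
  out
}
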