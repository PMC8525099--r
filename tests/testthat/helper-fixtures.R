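# Shared test helpers: printed-table expansion, an independent enumeration
# oracle for the marginalized likelihood, and a memoized synthetic fit that
# several test files share.

extdata <- function(f) {
  system.file("extdata", f, package = "mscjs", mustWork = TRUE)
}

# Expand the published annual observation/recapture tallies into a concrete
# set of encounter records realizing them exactly: each year, R recaptures
# reuse previously marked bears and C - R rows introduce new bears.  States
# are dealt from a fixed per-state total so the combined mark-recapture +
# telemetry state tallies can also be realized exactly.
expand_observation_table <- function(tab,
                                     mr_state_totals = c(300, 520, 70, 334)) {
  pool <- character(0)   # bears marked in earlier years
  rows <- list()
  next_id <- 0L
  for (r in seq_len(nrow(tab))) {
    yr <- tab$year[r]
    used <- character(0)
    take <- function(n, type) {
      ids <- character(0)
      if (n > 0) {
        avail <- setdiff(pool, used)
        stopifnot(length(avail) >= n)
        ids <- avail[seq_len(n)]
      }
      ids
    }
    for (type in c("C", "B")) {
      nC <- tab[[if (type == "C") "capture_C" else "biopsy_C"]][r]
      nR <- tab[[if (type == "C") "capture_R" else "biopsy_R"]][r]
      rec <- take(nR, type)
      used <- c(used, rec)
      n_new <- nC - nR
      new_ids <- if (n_new > 0) sprintf("bear%04d", next_id + seq_len(n_new))
                 else character(0)
      next_id <- next_id + n_new
      ids <- c(rec, new_ids)
      if (length(ids) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          bear_id = ids, year = yr,
          type = type, stringsAsFactors = FALSE)
      }
      pool <- c(pool, new_ids)
      used <- c(used, new_ids)
    }
  }
  obs <- do.call(rbind, rows)
  # deal states from the fixed totals, sexes alternating, ages consistent
  stopifnot(sum(mr_state_totals) == nrow(obs))
  obs$state <- rep(1:4, times = mr_state_totals)
  first_year <- ave(obs$year, obs$bear_id, FUN = min)
  obs$sex <- ifelse(as.integer(factor(obs$bear_id)) %% 2L == 0L, "F", "M")
  first_type <- ave(obs$type, obs$bear_id, FUN = function(x) x[1])
  obs$age <- ifelse(first_type == "B", NA_integer_,
                    6L + obs$year - first_year)
  obs[c("bear_id", "year", "sex", "age", "type", "state")]
}

# Telemetry fixture: two-year series dealing out given per-state totals.
expand_telemetry_counts <- function(state_totals, years = 2001:2016) {
  states <- rep(1:5, times = state_totals)
  n_bear <- length(states) / 2L
  stopifnot(n_bear == floor(n_bear))
  y0 <- years[1L + (seq_len(n_bear) - 1L) %% (length(years) - 1L)]
  data.frame(bear_id = rep(sprintf("tel%03d", seq_len(n_bear)), each = 2L),
             year = as.vector(rbind(y0, y0 + 1L)),
             state = states, stringsAsFactors = FALSE)
}

# Independent oracle: brute-force enumeration of all latent-state sequences
# for one bear (feasible for <= 4 occasions).  Deliberately shares no code
# with the forward-algorithm implementation.
enumerate_history_loglik <- function(data, b, phi, tau, rho) {
  rho[is.na(rho)] <- 0
  enc <- data$encounter[b, ]
  f <- data$first_idx[b]
  s <- data$sex_idx[b]
  acl <- data$age_class_idx[b, ]
  K <- length(enc)
  if (f == K) return(0)
  seqs <- expand.grid(rep(list(1:6), K - f))
  tot <- 0
  for (r in seq_len(nrow(seqs))) {
    path <- c(enc[f], unlist(seqs[r, ]))
    p <- 1
    for (t in (f + 1):K) {
      cur <- path[t - f]; nxt <- path[t - f + 1]
      ph <- phi[s, acl[t - 1], t - 1]
      ptr <- if (cur == 6) (if (nxt == 6) 1 else 0)
             else if (nxt == 6) 1 - ph else ph * tau[cur, nxt]
      o <- enc[t]
      pobs <- if (o >= 1) (if (nxt == o) rho[o, t] else 0)
              else if (nxt <= 4) 1 - rho[nxt, t] else 1
      p <- p * ptr * pobs
      if (p == 0) break
    }
    tot <- tot + p
  }
  log(tot)
}

# Random short-history data set + parameter draw for oracle comparisons.
random_oracle_case <- function(seed, n_bears = 8, n_occasions = 4) {
  set.seed(seed)
  years <- 2001:(2000 + n_occasions)
  rows <- list()
  for (b in seq_len(n_bears)) {
    f <- sample.int(n_occasions, 1L)
    obs_years <- f
    if (f < n_occasions) {
      later <- (f + 1):n_occasions
      obs_years <- c(f, later[runif(length(later)) < 0.5])
    }
    rows[[b]] <- data.frame(
      bear_id = sprintf("b%02d", b),
      year = years[obs_years],
      sex = sample(c("M", "F"), 1L),
      age = if (runif(1) < 0.2) NA_integer_ else sample(0:24, 1L),
      type = "C",
      state = sample(1:4, length(obs_years), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, rows)
  spec <- mscjs_spec()
  data <- mscjs_data(obs, years = years,
                     effort = effort_table(matrix(3000, 4, n_occasions),
                                           years))
  pinfo <- param_info(spec, years)
  params <- setNames(runif(nrow(pinfo), pinfo$lower, pinfo$upper),
                     pinfo$name)
  list(data = data, params = params, spec = spec, years = years)
}

# Memoized synthetic data set + converged reduced fit shared across test
# files (constraint invariants, convergence, goodness of fit, abundance).
.fixture <- new.env(parent = emptyenv())

fixture_sim <- function() {
  if (is.null(.fixture$sim)) {
    .fixture$truth <- mscjs_truth(years = 2001:2008, cohort_size = 38,
                                  telemetry_per_year = 5)
    .fixture$sim <- simulate_dataset(.fixture$truth, seed = 2024)
  }
  list(truth = .fixture$truth, sim = .fixture$sim)
}

fixture_fit <- function() {
  if (is.null(.fixture$fit)) {
    fs <- fixture_sim()
    .fixture$fit <- fit_mscjs(fs$sim$data, mscjs_spec(),
                              mcmc_config(chains = 3, burn_in = 2500,
                                          iterations = 2000, thin = 1),
                              seed = 99)
  }
  .fixture$fit
}
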