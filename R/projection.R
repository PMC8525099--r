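#' Configuration of the population projection
#'
#' The projection is an individual-based consistency check between the
#' estimated survival probabilities and the abundance trend: an initial
#' population of family groups of randomized composition is projected
#' forward with Bernoulli survival per individual per year (using one
#' posterior draw of the survival probabilities per trajectory) and a
#' simple, configurable reproduction mechanism: adult females in the
#' breeding age range without dependent cubs produce a litter with a fixed
#' probability; litter sizes are drawn from a small categorical
#' distribution; cubs stay dependent until the weaning age, making their
#' mother unavailable for breeding.  The reproduction rules are an explicit
#' approximation and every piece is configurable.
#'
#' @param n_family_groups Number of initial family groups (each an adult
#'   female plus a litter of random size and age).
#' @param years Years to project forward.
#' @param litter_size_probs Probabilities of litter sizes 1, 2, 3.
#' @param litter_prob Annual probability an available female produces a
#'   litter.
#' @param breeding_age Two-element range of female breeding ages.
#' @param weaning_age Age at which cubs become independent.
#' @return A list of class `projection_config`.
#' @export
projection_config <- function(n_family_groups = 50L, years = 14L,
                              litter_size_probs = c(0.25, 0.60, 0.15),
                              litter_prob = 0.35,
                              breeding_age = c(5L, 24L),
                              weaning_age = 2L) {
  stopifnot(years >= 1L, n_family_groups >= 1L,
            abs(sum(litter_size_probs) - 1) < 1e-8,
            litter_prob >= 0, litter_prob <= 1)
  structure(list(n_family_groups = n_family_groups, years = years,
                 litter_size_probs = litter_size_probs,
                 litter_prob = litter_prob, breeding_age = breeding_age,
                 weaning_age = weaning_age),
            class = "projection_config")
}

# one trajectory under a fixed survival table phi [2 x 7 x n_phi_years];
# year indices beyond n_phi_years reuse the last year
project_one <- function(phi, cfg) {
  n_phi <- dim(phi)[3L]
  # initial composition: one adult female per family group plus a litter
  n0 <- cfg$n_family_groups
  litters <- sample.int(3L, n0, replace = TRUE,
                        prob = cfg$litter_size_probs)
  cub_age <- sample.int(cfg$weaning_age, n0, replace = TRUE) - 1L
  age <- c(sample(seq(cfg$breeding_age[1], 15L), n0, replace = TRUE),
           rep(cub_age, litters))
  sex <- c(rep(2L, n0),
           sample(1:2, sum(litters), replace = TRUE))
  mother <- c(rep(NA_integer_, n0), rep(seq_len(n0), litters))
  alive <- rep(TRUE, length(age))
  size <- integer(cfg$years + 1L)
  size[1L] <- sum(alive)
  next_id <- length(age)
  for (y in seq_len(cfg$years)) {
    t <- min(y, n_phi)
    if (!any(alive)) { size[y + 1L] <- 0L; next }
    cls <- age_class_index(age)
    p <- phi[cbind(sex, cls, t)]
    surv <- alive & (stats::runif(length(age)) <= p)
    age[surv] <- age[surv] + 1L
    alive <- surv
    # reproduction: available females breed, cubs arrive next spring
    has_dep <- unique(mother[alive & age < cfg$weaning_age &
                               !is.na(mother)])
    fem <- which(alive & sex == 2L & age >= cfg$breeding_age[1] &
                   age <= cfg$breeding_age[2] &
                   !(seq_along(alive) %in% has_dep))
    if (length(fem) > 0L && cfg$litter_prob > 0) {
      breeds <- fem[stats::runif(length(fem)) <= cfg$litter_prob]
      if (length(breeds) > 0L) {
        ls <- sample.int(3L, length(breeds), replace = TRUE,
                         prob = cfg$litter_size_probs)
        n_new <- sum(ls)
        age <- c(age, rep(0L, n_new))
        sex <- c(sex, sample(1:2, n_new, replace = TRUE))
        mother <- c(mother, rep(breeds, ls))
        alive <- c(alive, rep(TRUE, n_new))
        next_id <- next_id + n_new
      }
    }
    size[y + 1L] <- sum(alive)
  }
  size
}

#' Project the population forward with posterior survival draws
#'
#' Runs one individual-based trajectory per survival draw (see
#' [projection_config()]) and returns population size by projected year.
#' The comparison of interest is the trend of the trajectory means against
#' the trend of the posterior abundance series.
#'
#' @param survival Either an `mscjs_fit` (one trajectory per stored draw,
#'   thinned to `n_draws`) or a single survival array `[2 x 7 x years]`
#'   (sex x age class x year) reused for all trajectories.
#' @param config A [projection_config()].
#' @param n_draws Number of trajectories.
#' @param seed Integer seed.
#' @return Matrix (trajectories x years + 1) of population sizes, first
#'   column the initial population.
#' @export
project_population <- function(survival, config = projection_config(),
                               n_draws = 200L, seed = 1L) {
  set.seed(seed)
  if (inherits(survival, "mscjs_fit")) {
    fit <- survival
    builders <- make_builders(fit$spec, fit$data$years, fit$param_info,
                              fit$data$effort)
    all_draws <- do.call(rbind, fit$draws)
    idx <- unique(round(seq(1L, nrow(all_draws),
                            length.out = min(n_draws, nrow(all_draws)))))
    traj <- t(vapply(idx, function(d)
      project_one(builders$phi(all_draws[d, ]), config),
      numeric(config$years + 1L)))
  } else {
    stopifnot(is.array(survival), length(dim(survival)) == 3L,
              dim(survival)[1] == 2L, dim(survival)[2] == 7L)
    traj <- t(vapply(seq_len(n_draws), function(d)
      project_one(survival, config), numeric(config$years + 1L)))
  }
  colnames(traj) <- paste0("year", 0:config$years)
  traj
}

#' Compare projection and abundance trends
#'
#' @param traj Trajectory matrix from [project_population()].
#' @param abundance An `mscjs_abundance` (or a numeric vector of abundance
#'   means).  Compared over the overlapping years.
#' @return A list with the Pearson correlation of the two mean trends and
#'   their mean ratio.
#' @export
projection_trend <- function(traj, abundance) {
  proj_mean <- colMeans(traj)[-1L]
  ab_mean <- if (inherits(abundance, "mscjs_abundance"))
    abundance$summary$N_mean else as.numeric(abundance)
  n <- min(length(proj_mean), length(ab_mean))
  pm <- proj_mean[seq_len(n)]; am <- ab_mean[seq_len(n)]
  list(correlation = stats::cor(pm, am), mean_ratio = mean(pm / am))
}
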