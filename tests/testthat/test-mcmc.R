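# A bear first observed on the final occasion contributes nothing to the
# conditional CJS likelihood, so a data set containing only such bears has a
# posterior identical to the prior.
zero_information_data <- function() {
  obs <- data.frame(bear_id = c("a", "b", "c"), year = 2004,
                    sex = c("M", "F", "M"), age = c(5L, 7L, NA),
                    type = c("C", "C", "B"), state = c(1L, 2L, 4L))
  mscjs_data(obs, years = 2001:2004)
}

test_that("with no informative data the sampler recovers the priors", {
  fit <- fit_mscjs(zero_information_data(), mscjs_spec(),
                   mcmc_config(chains = 2, burn_in = 500, iterations = 3000,
                               thin = 1), seed = 31)
  draws <- do.call(rbind, fit$draws)
  # uniform(0, 5) age effects: mean 2.5, quartiles 1.25 / 3.75
  for (p in c("alphaA0", "alphaA3")) {
    expect_lt(abs(mean(draws[, p]) - 2.5), 0.2)
    q <- quantile(draws[, p], c(0.25, 0.75))
    expect_lt(abs(q[[1]] - 1.25), 0.3)
    expect_lt(abs(q[[2]] - 3.75), 0.3)
  }
  # uniform(-5, 5) year effect and uniform(0, 1) stick parameter
  expect_lt(abs(mean(draws[, "alphaT5_2002"])), 0.4)
  expect_lt(abs(mean(draws[, "upsilon_3_2"]) - 0.5), 0.05)
  expect_gt(min(draws[, "alphaF"]), -5)
  expect_lt(max(draws[, "alphaF"]), 5)
})

test_that("sampling is exactly reproducible for a given seed", {
  d <- zero_information_data()
  cfg <- mcmc_config(chains = 2, burn_in = 100, iterations = 100, thin = 1)
  f1 <- fit_mscjs(d, mscjs_spec(), cfg, seed = 7)
  f2 <- fit_mscjs(d, mscjs_spec(), cfg, seed = 7)
  f3 <- fit_mscjs(d, mscjs_spec(), cfg, seed = 8)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("stored draw counts and bookkeeping match the configuration", {
  cfg <- mcmc_config(chains = 2, burn_in = 200, iterations = 300, thin = 3)
  expect_identical(cfg$stored_per_chain, 100L)
  fit <- fit_mscjs(zero_information_data(), mscjs_spec(), cfg, seed = 1)
  expect_length(fit$draws, 2L)
  expect_identical(nrow(fit$draws[[1]]), 100L)
  # 4-occasion additive/state-time: 11 survival + 20 transition + 6 recapture
  expect_identical(ncol(fit$draws[[1]]), 37L)
  m <- as_draws_matrix(fit)
  expect_identical(nrow(m), 200L)
  expect_identical(sort(unique(m[, "chain"])), c(1, 2))
  # full-analysis defaults are encoded but not run here
  full <- mcmc_config()
  expect_identical(full$chains, 5L)
  expect_identical(full$stored_per_chain * full$chains, 20000L)
})

test_that("every stored draw respects the survival and recapture orderings", {
  fit <- fixture_fit()
  years <- fit$data$years
  draws <- do.call(rbind, fit$draws)
  pinfo <- fit$param_info
  expect_true(all(draws >= matrix(pinfo$lower, nrow(draws),
                                  ncol(draws), byrow = TRUE)))
  expect_true(all(draws <= matrix(pinfo$upper, nrow(draws),
                                  ncol(draws), byrow = TRUE)))
  b <- mscjs:::make_builders(fit$spec, years, pinfo, fit$data$effort)
  step <- max(1L, nrow(draws) %/% 500L)
  for (r in seq(1L, nrow(draws), by = step)) {
    phi <- b$phi(draws[r, ])
    expect_true(all(phi[, 1, ] <= phi[, 2, ] & phi[, 2, ] <= phi[, 5, ]))
    expect_true(all(phi[, 3, ] <= phi[, 4, ] & phi[, 4, ] <= phi[, 5, ]))
    expect_true(all(phi[, 6, ] <= phi[, 5, ]))
    tau <- b$tau(draws[r, ])
    expect_true(all(abs(rowSums(tau) - 1) < 1e-12))
    rho <- b$rho(draws[r, ])
    expect_true(all(rho[1, -1] >= rho[3, -1] & rho[2, -1] >= rho[4, -1]))
  }
})

test_that("posterior summaries drop the final-year confounded parameters", {
  fit <- fixture_fit()
  expect_setequal(fit$nonidentified, c("alphaT5_2007", "beta1_2008"))
  s <- posterior_summary(fit)
  expect_false(any(fit$nonidentified %in% s$param))
  s_all <- posterior_summary(fit, include_nonidentified = TRUE)
  expect_true(all(fit$nonidentified %in% s_all$param))
  expect_true(all(is.finite(s$mean)))
})

test_that("doubling the sample size contracts adult-survival intervals", {
  cfg <- mcmc_config(chains = 2, burn_in = 1000, iterations = 600, thin = 1)
  widths <- sapply(c(19, 75), function(cs) {
    tr <- mscjs_truth(years = 2001:2008, cohort_size = cs,
                      telemetry_per_year = 4)
    sim <- simulate_dataset(tr, seed = 123)
    fit <- fit_mscjs(sim$data, mscjs_spec(), cfg, seed = 55)
    sd_draws <- survival_draws(fit, "M", "A5_19")[, 1:6]
    mean(apply(sd_draws, 2, function(x)
      diff(quantile(x, c(0.025, 0.975)))))
  })
  expect_lt(widths[2], widths[1])
})
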