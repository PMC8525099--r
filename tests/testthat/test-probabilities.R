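zero_params <- function(spec, years) {
  pinfo <- param_info(spec, years)
  p <- setNames(rep(0, nrow(pinfo)), pinfo$name)
  p["omega"] <- if ("omega" %in% pinfo$name) 0.9 else NA
  p <- p[pinfo$name]
  p
}

test_that("survival expressions evaluate the inverse-logit forms", {
  spec <- mscjs_spec()
  years <- 2001:2016
  p <- zero_params(spec, years)
  # all parameters zero: adult male survival is the logistic at zero
  expect_equal(survival_prob(p, "M", "A5_19", 2005, spec, years), 0.5)
  # hand-evaluated cases
  p["alphaT5_2005"] <- -2; p["alphaA1"] <- 1
  expect_equal(survival_prob(p, "M", "A5_19", 2005, spec, years),
               1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(round(survival_prob(p, "M", "A5_19", 2005, spec, years), 4),
               0.8808)
  expect_equal(round(survival_prob(p, "M", "A1", 2005, spec, years), 4),
               0.7311)
  p["alphaA0"] <- 1
  expect_equal(survival_prob(p, "M", "A0", 2005, spec, years), 0.5)
  # female adds the sex effect on the logit scale
  p["alphaF"] <- 0.5
  expect_equal(survival_prob(p, "F", "A5_19", 2005, spec, years),
               1 / (1 + exp(0.5 - 2)))
  expect_error(survival_prob(p, "M", "A5_19", 2016, spec, years), "years")
})

test_that("unknown-age survival is the stated three-class mixture", {
  spec <- mscjs_spec()
  years <- 2001:2010
  pinfo <- param_info(spec, years)
  set.seed(42)
  p <- setNames(runif(nrow(pinfo), pinfo$lower, pinfo$upper), pinfo$name)
  p3 <- survival_prob(p, "F", "A3_4", 2004, spec, years)
  p5 <- survival_prob(p, "F", "A5_19", 2004, spec, years)
  p20 <- survival_prob(p, "F", "A20plus", 2004, spec, years)
  w1 <- p[["alphaW1"]]; w2 <- p[["alphaW2"]]
  expect_equal(survival_prob(p, "F", "Unknown", 2004, spec, years),
               w1 * p3 + (1 - w1) * w2 * p5 + (1 - w1) * (1 - w2) * p20)
  # degenerate weight: unknown collapses to the subadult class
  p["alphaW1"] <- 1 - 1e-12
  expect_equal(survival_prob(p, "F", "Unknown", 2004, spec, years), p3,
               tolerance = 1e-9)
})

test_that("prior support implies the survival orderings in every draw", {
  spec_a <- mscjs_spec("additive")
  spec_i <- mscjs_spec("interactive")
  years <- 2001:2008
  for (spec in list(spec_a, spec_i)) {
    pinfo <- param_info(spec, years)
    set.seed(7)
    for (r in 1:25) {
      p <- setNames(runif(nrow(pinfo), pinfo$lower, pinfo$upper), pinfo$name)
      tab <- mscjs:::phi_table(p, spec, years)
      # A0 <= A1 <= A5_19, A2 <= A3_4 <= A5_19, A20plus <= A5_19
      expect_true(all(tab[, 1, ] <= tab[, 2, ] + 1e-12))
      expect_true(all(tab[, 2, ] <= tab[, 5, ] + 1e-12))
      expect_true(all(tab[, 3, ] <= tab[, 4, ] + 1e-12))
      expect_true(all(tab[, 4, ] <= tab[, 5, ] + 1e-12))
      expect_true(all(tab[, 6, ] <= tab[, 5, ] + 1e-12))
      expect_true(all(tab > 0 & tab < 1))
    }
  }
})

test_that("stick-breaking rows expand correctly and sum to one", {
  tau <- transition_matrix(matrix(0.5, 5, 4))
  expect_equal(unname(tau[1, ]), c(0.5, 0.25, 0.125, 0.0625, 0.0625))
  # upsilon_m1 -> 1 forces all mass into the first state
  tau1 <- transition_matrix(matrix(c(1 - 1e-12, 0.5, 0.5, 0.5), 5, 4,
                                   byrow = TRUE))
  expect_equal(unname(tau1[2, ]), c(1, 0, 0, 0, 0), tolerance = 1e-9)
  set.seed(11)
  for (r in 1:50) {
    u <- matrix(runif(20), 5, 4)
    tt <- transition_matrix(u)
    expect_true(all(abs(rowSums(tt) - 1) < 1e-12))
    expect_true(all(tt > 0 & tt < 1))
  }
  # named-vector form matches the matrix form
  nm <- as.vector(t(outer(1:5, 1:4, function(m, n)
    sprintf("upsilon_%d_%d", m, n))))
  u <- matrix(runif(20, 0.1, 0.9), 5, 4)
  expect_equal(transition_matrix(setNames(as.vector(t(u)), nm)),
               transition_matrix(u))
})

test_that("stick-breaking inversion is exact", {
  set.seed(3)
  u <- matrix(runif(20, 0.05, 0.95), 5, 4)
  tau <- transition_matrix(u)
  expect_equal(upsilon_from_tau(tau), u, tolerance = 1e-12)
})

test_that("state+time recapture evaluates the logit forms with orderings", {
  spec <- mscjs_spec()
  years <- 2001:2016
  p <- zero_params(spec, years)
  p["beta3"] <- 1
  expect_equal(recapture_prob(p, 1, 2005, spec, years), 0.5)
  expect_equal(round(recapture_prob(p, 3, 2005, spec, years), 4), 0.2689)
  # beta3, beta4 >= 0 impose rho1 >= rho3 and rho2 >= rho4 for any draw
  pinfo <- param_info(spec, years)
  set.seed(5)
  for (r in 1:25) {
    pr <- setNames(runif(nrow(pinfo), pinfo$lower, pinfo$upper), pinfo$name)
    tab <- mscjs:::rho_table(pr, spec, years)
    expect_true(all(tab[1, -1] >= tab[3, -1]))
    expect_true(all(tab[2, -1] >= tab[4, -1]))
  }
  expect_error(recapture_prob(p, 5, 2005, spec, years), "1..4")
  expect_error(recapture_prob(p, 1, 2001, spec, years), "years")
})

test_that("state+distance recapture nests the baseline form", {
  years <- 2001:2010
  eff <- effort_table(matrix(3000, 4, 10), years)
  spec_d <- mscjs_spec("additive", "state_distance")
  pinfo <- param_info(spec_d, years)
  p <- setNames(rep(0, nrow(pinfo)), pinfo$name)
  p["beta1"] <- 0.4; p["beta2"] <- 0.15; p["beta3"] <- 1; p["beta4"] <- 0.3
  # theta = 0 and omega = 1 reduce to the beta-only expression
  p["omega"] <- 1 - 1e-12
  expect_equal(recapture_prob(p, 2, 2005, spec_d, years, eff),
               1 / (1 + exp(0.4 + 0.15)), tolerance = 1e-9)
  # omega is a ceiling: as theta d drives the exponent far negative,
  # recapture tends to omega
  p["omega"] <- 0.5
  p["theta_1"] <- -49.9
  big <- effort_table(matrix(1e6, 4, 10), years)
  expect_equal(recapture_prob(p, 1, 2005, spec_d, years, big), 0.5,
               tolerance = 1e-9)
  expect_error(recapture_prob(p, 1, 2005, spec_d, years, NULL), "effort")
})

test_that("the sampler's indexed builders match the reference tables", {
  years <- 2001:2009
  eff <- effort_table(matrix(runif(4 * 9, 1000, 6000), 4, 9), years)
  for (spec in list(mscjs_spec("additive", "state_time"),
                    mscjs_spec("interactive", "state_time"),
                    mscjs_spec("additive", "state_distance"),
                    mscjs_spec("interactive", "state_distance",
                               time_varying_beta1 = TRUE))) {
    pinfo <- param_info(spec, years)
    set.seed(8)
    p <- setNames(runif(nrow(pinfo), pinfo$lower, pinfo$upper), pinfo$name)
    b <- mscjs:::make_builders(spec, years, pinfo, eff)
    expect_equal(b$phi(p), mscjs:::phi_table(p, spec, years))
    expect_equal(b$tau(p), unname(transition_matrix(p)))
    ref <- mscjs:::rho_table(p, spec, years, eff)
    ref[is.na(ref)] <- 0
    expect_equal(b$rho(p), unname(ref))
  }
})
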