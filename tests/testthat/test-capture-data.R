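test_that("age classes map ages as defined", {
  expect_identical(age_class(c(0, 1, 2, 3, 4, 5, 19, 20, 31)),
                   c("A0", "A1", "A2", "A3_4", "A3_4", "A5_19", "A5_19",
                     "A20plus", "A20plus"))
  expect_identical(age_class(NA_integer_), "Unknown")
  expect_error(age_class(-1), "non-negative")
})

test_that("the data constructor validates and derives per-bear structure", {
  obs <- data.frame(bear_id = c("a", "a", "b"), year = c(2001, 2003, 2002),
                    sex = c("M", "M", "F"), age = c(4L, 6L, NA),
                    type = c("C", "C", "B"), state = c(1L, 2L, 4L))
  d <- mscjs_data(obs, years = 2001:2004)
  expect_identical(nrow(d$bears), 2L)
  expect_identical(d$first_idx, c(1L, 2L))
  expect_identical(d$sex_idx, c(1L, 2L))
  # bear a: age 4 (A3_4) in 2001, ages across the class boundary to A5_19
  expect_identical(d$age_class_idx[1, ], c(4L, 5L, 5L, 5L))
  # unknown age stays unknown
  expect_identical(d$age_class_idx[2, ], rep(7L, 4L))
  expect_identical(unname(d$encounter[1, ]), c(1L, 0L, 2L, 0L))

  bad <- obs; bad$state[1] <- 5L
  expect_error(mscjs_data(bad, years = 2001:2004), "1..4")
  dup <- rbind(obs, obs[1, ])
  expect_error(mscjs_data(dup, years = 2001:2004), "one observation")
  swap <- obs; swap$sex[2] <- "F"
  expect_error(mscjs_data(swap, years = 2001:2004), "inconsistent sex")
})

test_that("telemetry series are validated and reduced to transition counts", {
  obs <- data.frame(bear_id = "a", year = 2001, sex = "M", age = 5L,
                    type = "C", state = 1L)
  tel <- data.frame(bear_id = c("t1", "t1", "t1", "t2", "t2"),
                    year = c(2001, 2002, 2004, 2002, 2003),
                    state = c(1L, 4L, 5L, 2L, 2L))
  d <- mscjs_data(obs, telemetry = tel, years = 2001:2004)
  tt <- d$tel_trans
  expect_identical(sum(tt$count), 3L)
  expect_equal(tt$gap[tt$from == 4 & tt$to == 5], 2)
  single <- data.frame(bear_id = "t3", year = 2001, state = 1L)
  expect_error(mscjs_data(obs, telemetry = single, years = 2001:2004),
               ">= 2 years")
})

test_that("observation summaries count recaptures and individuals", {
  # a single bear seen once
  one <- data.frame(bear_id = "x", year = 2005, sex = "F", age = 7L,
                    type = "C", state = 2L)
  s1 <- summarize_observations(one)
  expect_identical(c(s1$observations, s1$recaptures, s1$individuals),
                   c(1L, 0L, 1L))
  # two bears each seen in 3 years: 6 observations, 4 recaptures
  two <- data.frame(bear_id = rep(c("x", "y"), each = 3),
                    year = rep(2001:2003, 2), sex = "M", age = 5L,
                    type = "C", state = 1L)
  s2 <- summarize_observations(two)
  expect_identical(c(s2$observations, s2$recaptures, s2$individuals),
                   c(6L, 4L, 2L))
  expect_identical(s2$individuals + s2$recaptures, s2$observations)
})

test_that("summaries are invariant to bear ordering and satisfy the identity", {
  fs <- fixture_sim()
  obs <- fs$sim$observations
  s <- summarize_observations(obs)
  expect_identical(s$individuals + s$recaptures, s$observations)
  set.seed(4)
  s2 <- summarize_observations(obs[sample(nrow(obs)), ])
  expect_identical(s, s2)
})

test_that("state tabulation counts assignments and known transitions", {
  obs <- data.frame(bear_id = c("a", "a", "b"), year = c(2003, 2004, 2003),
                    sex = "M", age = 5L, type = "C", state = c(1L, 2L, 4L))
  tel <- data.frame(bear_id = c("t", "t", "t"), year = c(2003, 2004, 2005),
                    state = c(5L, 5L, 1L))
  d <- mscjs_data(obs, telemetry = tel, years = 2001:2016)
  ts <- tabulate_states(d)
  expect_identical(unname(ts$state_counts),
                   c(2L, 1L, 0L, 1L, 2L))
  expect_identical(ts$total, 6L)
  # bear a 2003->2004 plus telemetry 2003->2004->2005
  expect_identical(ts$known_transitions, 3L)
  # disjoint years contribute no known transition
  gap <- data.frame(bear_id = c("g", "g"), year = c(2003, 2007),
                    sex = "M", age = 5L, type = "C", state = c(1L, 1L))
  expect_identical(tabulate_states(mscjs_data(gap, years = 2001:2016)
                                   )$known_transitions, 0L)
})

test_that("observation and telemetry CSVs round-trip exactly", {
  fs <- fixture_sim()
  obs <- fs$sim$observations
  tel <- fs$sim$telemetry
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_observations_csv(obs, p1)
  write_telemetry_csv(tel, p2)
  obs2 <- read_observations_csv(p1)
  tel2 <- read_telemetry_csv(p2)
  rownames(obs) <- rownames(obs2) <- NULL
  rownames(tel) <- rownames(tel2) <- NULL
  expect_identical(obs2$bear_id, obs$bear_id)
  expect_equal(obs2$age, obs$age)
  expect_identical(obs2$state, as.integer(obs$state))
  expect_identical(tel2, tel[names(tel2)])
})
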