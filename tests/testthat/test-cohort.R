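# Synthetic cohort generator: zero-noise identities, determinism, noise
# calibration, axis alignment and the cohort-mean summaries.

test_that("zero-noise generation reproduces the generative curves exactly", {
  cfg <- zero_noise_config(instar_duration_sd = 0.8)
  tab <- generate_cohort(cfg)
  truth <- cohort_truth(cfg)
  expect_equal(
    tab$ecdysteroid_titer, truth$ecdysteroid(tab$days_prior_to_ecdysis)
  )
  expect_equal(tab$weight, truth$weight(tab$day_of_instar))
  expect_equal(
    tab$inter_wing_distance, truth$inter_wing(tab$days_prior_to_ecdysis)
  )
})

test_that("study-like cohort has 14 nymphs first sampled on day 4", {
  tab <- generate_cohort(study_config(seed = 3))
  expect_length(unique(tab$nymph_id), 14)
  first <- tapply(tab$day_of_instar, tab$nymph_id, min)
  expect_true(all(first == 4))
  # one record per nymph and day, contiguous to the ecdysis day
  expect_equal(anyDuplicated(tab[, c("nymph_id", "day_of_instar")]), 0L)
  expect_equal(tab$days_prior_to_ecdysis, tab$ecdysis_day - tab$day_of_instar)
  last <- tapply(tab$day_of_instar, tab$nymph_id, max)
  ecd <- tapply(tab$ecdysis_day, tab$nymph_id, unique)
  expect_equal(unname(last), unname(ecd))
})

test_that("generation is seed-deterministic", {
  a <- generate_cohort(study_config(seed = 5))
  b <- generate_cohort(study_config(seed = 5))
  expect_identical(a, b)
  c <- generate_cohort(study_config(seed = 6))
  expect_false(isTRUE(all.equal(a$weight, c$weight)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_cohort(study_config(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("empirical noise SD matches the configured SD within 5%", {
  cfg <- cohort_config(
    n_nymphs = 2000, instar_duration_sd = 0, seed = 8,
    # large-area pulse keeps every mean far above 0, so zero-truncation
    # cannot bite and the raw noise SD is observable
    ecdysteroid_peak = list(A = 10000, mu = 2.9, sigma = 0.7),
    noise_sd = list(weight = 0.05, iw = 0.1, ecdysteroid = 20)
  )
  tab <- generate_cohort(cfg)
  expect_gt(nrow(tab), 1e4)
  truth <- cohort_truth(cfg)
  res_w <- tab$weight - truth$weight(tab$day_of_instar)
  expect_equal(sd(res_w), 0.05, tolerance = 0.05)
  res_i <- tab$inter_wing_distance - truth$inter_wing(tab$days_prior_to_ecdysis)
  expect_equal(sd(res_i), 0.1, tolerance = 0.05)
  res_e <- tab$ecdysteroid_titer - truth$ecdysteroid(tab$days_prior_to_ecdysis)
  expect_equal(sd(res_e), 20, tolerance = 0.05)
})

test_that("noised values are truncated at zero, never negative", {
  cfg <- cohort_config(
    n_nymphs = 200, seed = 9,
    noise_sd = list(weight = 2, iw = 2, ecdysteroid = 50)
  )
  tab <- generate_cohort(cfg)
  expect_true(all(tab$weight >= 0))
  expect_true(all(tab$inter_wing_distance >= 0))
  expect_true(all(tab$ecdysteroid_titer >= 0))
})

test_that("record-wise missingness appears at the configured rate", {
  cfg <- cohort_config(n_nymphs = 1000, missing_rate = 0.2, seed = 10)
  tab <- generate_cohort(cfg)
  for (v in c("weight", "inter_wing_distance", "ecdysteroid_titer")) {
    expect_equal(mean(is.na(tab[[v]])), 0.2, tolerance = 0.1)
  }
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(cohort_config(n_nymphs = 0), "n_nymphs")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(
    cohort_config(instar_duration_mean = 3, sampling_start_day = 4),
    "instar_duration_mean"
  )
  expect_error(
    cohort_config(ecdysteroid_peak = list(A = 1, mu = 1, sigma = 0)),
    "ecdysteroid_peak"
  )
  expect_error(
    cohort_config(noise_sd = list(weight = -1, iw = 0.1, ecdysteroid = 1)),
    "noise_sd"
  )
})

test_that("cohort means and SEMs follow their definitions", {
  # single nymph: mean equals the values, sem undefined
  one <- data.frame(
    nymph_id = "N01", day_of_instar = 4:6, ecdysis_day = 8,
    days_prior_to_ecdysis = 8 - (4:6),
    weight = c(1, 2, 3), inter_wing_distance = 1, ecdysteroid_titer = 1
  )
  m1 <- cohort_means(one, "day_of_instar", variables = "weight")
  expect_equal(m1$mean, c(1, 2, 3))
  expect_true(all(is.na(m1$sem)))
  expect_true(all(m1$n == 1))

  # two nymphs with values 1 and 3 at one time point: mean 2, sem 1
  two <- data.frame(
    nymph_id = c("N01", "N02"), day_of_instar = 4, ecdysis_day = 8,
    days_prior_to_ecdysis = 4, weight = c(1, 3),
    inter_wing_distance = NA_real_, ecdysteroid_titer = NA_real_
  )
  m2 <- cohort_means(two, "day_of_instar", variables = "weight")
  expect_equal(m2$mean, 2)
  expect_equal(m2$sem, 1)
  expect_equal(m2$n, 2L)

  # zero-noise cohort with identical ecdysis days: sem 0 everywhere
  tab <- generate_cohort(zero_noise_config())
  m3 <- cohort_means(tab, "day_of_instar")
  expect_true(all(m3$sem[m3$n >= 2] == 0))

  expect_error(cohort_means(tab[0, ]), "empty")
})

test_that("days-prior alignment removes ecdysis-day jitter for zero noise", {
  cfg <- zero_noise_config(instar_duration_sd = 1.2, seed = 21)
  tab <- generate_cohort(cfg)
  expect_gt(length(unique(tab$ecdysis_day)), 1) # jitter actually present
  truth <- cohort_truth(cfg)
  m <- cohort_means(tab, "days_prior_to_ecdysis",
    variables = c("inter_wing_distance", "ecdysteroid_titer")
  )
  ec <- m[m$variable == "ecdysteroid_titer", ]
  expect_equal(ec$mean, truth$ecdysteroid(ec$time))
  iw <- m[m$variable == "inter_wing_distance", ]
  expect_equal(iw$mean, truth$inter_wing(iw$time))
  expect_true(all(m$sem[m$n >= 2] == 0))
})

test_that("cohort tables round-trip through tidy CSV", {
  tab <- generate_cohort(study_config(seed = 12, missing_rate = 0.1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, path)
  back <- read_cohort(path)
  for (v in c(
    "nymph_id", "day_of_instar", "ecdysis_day", "days_prior_to_ecdysis",
    "weight", "inter_wing_distance", "ecdysteroid_titer"
  )) {
    expect_equal(back[[v]], tab[[v]], info = v)
  }
  expect_error(read_cohort(file.path(tempdir(), "no-such.csv")), "cannot read")
})
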