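# Shared fixtures: study-like and noise-free cohort configurations.

study_config <- function(seed = 1L, ...) {
  cohort_config(seed = seed, ...)
}

# All stochastic elements off: deterministic curves, common ecdysis day.
zero_noise_config <- function(seed = 1L, instar_duration_sd = 0, ...) {
  cohort_config(
    seed = seed,
    instar_duration_sd = instar_duration_sd,
    noise_sd = list(weight = 0, iw = 0, ecdysteroid = 0),
    missing_rate = 0,
    ...
  )
}

# Independent reimplementations of the three model curves, used as oracles:
# the Lorentzian is an area-scaled Cauchy density, the lognormal curve an
# area-scaled lognormal density, and the linked model is rebuilt on plogis.
oracle_lorentzian <- function(x, A, mu, sigma) A * stats::dcauchy(x, mu, sigma)
oracle_lognorm <- function(x, A, mu, sigma) A * stats::dlnorm(x, mu, sigma)
oracle_linked <- function(x, A, b0, b1, mu, sigma_link) {
  L <- stats::plogis(x, location = mu, scale = sigma_link)
  (b0 + b1 * x) * (1 - L) + A * L
}
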