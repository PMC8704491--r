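#' Configuration of a synthetic fifth-instar cohort
#'
#' Collects the generative truths and sampling design for
#' [generate_cohort()]. Defaults emulate the study design the package
#' targets: 14 female nymphs followed daily from day 4 of the fifth instar
#' (N5D4) until the adult molt, with an ecdysteroid pulse peaking about 2.9
#' days before ecdysis, body weight rising to a peak about 1.8 days before
#' ecdysis and then falling, and the inter-wing distance growing linearly
#' before plateauing about 3.1 days prior to ecdysis.
#'
#' Two time axes coexist. The ecdysteroid and inter-wing truths are defined
#' on the *days prior to ecdysis* axis (positive before the molt), which
#' aligns nymphs on their molt date; the weight truth is a lognormal on the
#' *day of instar* axis, whose positive domain the lognormal density
#' requires. With the defaults the weight mode
#' \eqn{\exp(\mu - \sigma^2) = 7.2} days of instar, i.e. 1.8 days prior to
#' ecdysis at the mean instar duration of 9 days.
#'
#' @param n_nymphs Number of nymphs (>= 1).
#' @param instar_duration_mean,instar_duration_sd Mean and SD (days) of the
#'   fifth-instar duration; each nymph's ecdysis day is drawn from this
#'   normal, rounded to the nearest whole day (observations are daily) and
#'   floored at `sampling_start_day + 2` so every series has >= 3 points.
#' @param sampling_start_day First sampled day of the instar (default 4).
#' @param ecdysteroid_peak List `A` (pg·days/µL), `mu` (days prior to
#'   ecdysis), `sigma` (days): Lorentzian truth for the titer.
#' @param weight_curve List `A` (g·days), `mu` (log-days), `sigma`
#'   (log-days), `baseline` (g): lognormal gain truth on the day-of-instar
#'   axis, added to a constant baseline weight.
#' @param iw_curve List `slope` (mm/day, on real time), `intercept` (mm,
#'   linear-branch value extrapolated to ecdysis), `mu` (days prior to
#'   ecdysis of the linear-to-plateau shift), `sigma_link` (days),
#'   `plateau` (mm).
#' @param noise_sd List `weight` (g), `iw` (mm), `ecdysteroid` (pg/µL):
#'   SDs of independent additive Gaussian measurement noise; values are
#'   truncated at zero after noising.
#' @param missing_rate Probability that any one measurement field of a
#'   record is missing, in `[0, 1)`.
#' @param seed Integer RNG seed; generation is fully deterministic given
#'   the config.
#' @return An object of class `"molt_cohort_config"`.
#' @seealso [generate_cohort()], [cohort_truth()]
#' @export
cohort_config <- function(n_nymphs = 14,
                          instar_duration_mean = 9,
                          instar_duration_sd = 0.8,
                          sampling_start_day = 4,
                          ecdysteroid_peak = list(A = 130, mu = 2.9, sigma = 0.7),
                          weight_curve = list(
                            A = 3.5, mu = log(7.2) + 0.2^2, sigma = 0.2,
                            baseline = 1.3
                          ),
                          iw_curve = list(
                            slope = 0.25, intercept = 2.775, mu = 3.1,
                            sigma_link = 0.25, plateau = 2.0
                          ),
                          noise_sd = list(weight = 0.05, iw = 0.1, ecdysteroid = 4),
                          missing_rate = 0,
                          seed = 1L) {
  cfg <- structure(
    list(
      n_nymphs = n_nymphs,
      instar_duration_mean = instar_duration_mean,
      instar_duration_sd = instar_duration_sd,
      sampling_start_day = sampling_start_day,
      ecdysteroid_peak = ecdysteroid_peak,
      weight_curve = weight_curve,
      iw_curve = iw_curve,
      noise_sd = noise_sd,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "molt_cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid cohort config: field '", field, "' ", why, call. = FALSE)
  }
  num1 <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v)
  if (!num1(cfg$n_nymphs) || cfg$n_nymphs < 1) fail("n_nymphs", "must be >= 1")
  if (!num1(cfg$instar_duration_sd) || cfg$instar_duration_sd < 0) {
    fail("instar_duration_sd", "must be >= 0")
  }
  if (!num1(cfg$instar_duration_mean) ||
    cfg$instar_duration_mean <= cfg$sampling_start_day) {
    fail("instar_duration_mean", "must exceed sampling_start_day")
  }
  if (!num1(cfg$sampling_start_day) || cfg$sampling_start_day < 0) {
    fail("sampling_start_day", "must be >= 0")
  }
  for (nm in c("ecdysteroid_peak", "weight_curve")) {
    if (!num1(cfg[[nm]]$sigma) || cfg[[nm]]$sigma <= 0) {
      fail(nm, "must have sigma > 0")
    }
  }
  if (!num1(cfg$iw_curve$sigma_link) || cfg$iw_curve$sigma_link <= 0) {
    fail("iw_curve", "must have sigma_link > 0")
  }
  for (nm in c("weight", "iw", "ecdysteroid")) {
    v <- cfg$noise_sd[[nm]]
    if (!num1(v) || v < 0) fail("noise_sd", paste0("$", nm, " must be >= 0"))
  }
  if (!num1(cfg$missing_rate) || cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    fail("missing_rate", "must be in [0, 1)")
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) fail("seed", "must be an integer")
  invisible(cfg)
}

#' Noiseless generative curves of a cohort configuration
#'
#' Returns the three mean trajectories implied by a [cohort_config()], each
#' as a function on its natural axis: `ecdysteroid(days_prior)` and
#' `inter_wing(days_prior)` on the days-prior-to-ecdysis axis,
#' `weight(day_of_instar)` (baseline plus lognormal gain) and
#' `weight_increase(day_of_instar)` on the day-of-instar axis. Useful as an
#' oracle when validating fits and staging on synthetic data.
#'
#' @param config A [cohort_config()].
#' @return Named list of vectorized functions.
#' @export
cohort_truth <- function(config) {
  ec <- config$ecdysteroid_peak
  wc <- config$weight_curve
  ic <- config$iw_curve
  list(
    ecdysteroid = function(days_prior) {
      lorentzian_model(days_prior, ec$A, ec$mu, ec$sigma)
    },
    weight = function(day_of_instar) {
      wc$baseline + lognorm_model(day_of_instar, wc$A, wc$mu, wc$sigma)
    },
    weight_increase = function(day_of_instar) {
      lognorm_model(day_of_instar, wc$A, wc$mu, wc$sigma)
    },
    inter_wing = function(days_prior) {
      # linear rise then plateau in real time = evaluate the linked model on
      # t = -days_prior with the shift at t = -mu
      linked_linear_constant_model(
        -days_prior, ic$plateau, ic$intercept, ic$slope, -ic$mu, ic$sigma_link
      )
    }
  )
}

#' Generate a synthetic fifth-instar cohort
#'
#' Simulates per-nymph daily measurement records with the parametric
#' structure the downstream fits assume. Each nymph receives an integer
#' ecdysis day drawn around `instar_duration_mean`, daily records from
#' `sampling_start_day` through its ecdysis day, noiseless means given by
#' [cohort_truth()] on each measurement's own axis, independent additive
#' Gaussian noise, truncation at zero, and record-wise missingness.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` of class `"molt_cohort"` with columns `nymph_id`,
#'   `sex`, `day_of_instar`, `ecdysis_day`, `days_prior_to_ecdysis`,
#'   `weight`, `inter_wing_distance`, `ecdysteroid_titer`; one row per
#'   (nymph, day). The config is attached as attribute `"config"`.
#' @examples
#' tab <- generate_cohort(cohort_config(seed = 17))
#' head(tab)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  truth <- cohort_truth(config)
  with_seed(config$seed, {
    n <- config$n_nymphs
    e_day <- pmax(
      round(stats::rnorm(n, config$instar_duration_mean,
        config$instar_duration_sd)),
      config$sampling_start_day + 2
    )
    recs <- lapply(seq_len(n), function(i) {
      days <- seq(config$sampling_start_day, e_day[i])
      data.frame(
        nymph_id = sprintf("N%02d", i),
        sex = "F",
        day_of_instar = days,
        ecdysis_day = e_day[i],
        days_prior_to_ecdysis = e_day[i] - days,
        stringsAsFactors = FALSE
      )
    })
    tab <- do.call(rbind, recs)
    m <- nrow(tab)
    noisy <- function(mu, sd) {
      if (sd > 0) pmax(mu + stats::rnorm(m, 0, sd), 0) else pmax(mu, 0)
    }
    tab$weight <- noisy(truth$weight(tab$day_of_instar), config$noise_sd$weight)
    tab$inter_wing_distance <- noisy(
      truth$inter_wing(tab$days_prior_to_ecdysis), config$noise_sd$iw
    )
    tab$ecdysteroid_titer <- noisy(
      truth$ecdysteroid(tab$days_prior_to_ecdysis),
      config$noise_sd$ecdysteroid
    )
    if (config$missing_rate > 0) {
      for (col in c("weight", "inter_wing_distance", "ecdysteroid_titer")) {
        drop <- stats::runif(m) < config$missing_rate
        tab[[col]][drop] <- NA_real_
      }
    }
    rownames(tab) <- NULL
    structure(tab, config = config, class = c("molt_cohort", "data.frame"))
  })
}

#' Per-time-point cohort means
#'
#' Averages each measurement over nymphs at every point of the chosen time
#' axis. The standard error of the mean is reported where at least two
#' nymphs contribute and is `NA` (undefined) otherwise.
#'
#' @param table A cohort table ([generate_cohort()] / [read_cohort()]), or
#'   any data frame with the same columns.
#' @param axis `"day_of_instar"` (measurement axis) or
#'   `"days_prior_to_ecdysis"` (analysis axis, which removes between-nymph
#'   jitter in molt date for curves defined relative to ecdysis).
#' @param variables Which measurement columns to summarize.
#' @return Data frame with columns `variable`, `time`, `mean`, `sem`, `n`,
#'   sorted by variable then time.
#' @export
cohort_means <- function(table,
                         axis = c("day_of_instar", "days_prior_to_ecdysis"),
                         variables = c(
                           "weight", "inter_wing_distance",
                           "ecdysteroid_titer"
                         )) {
  axis <- match.arg(axis)
  if (is.null(table) || nrow(table) == 0) {
    stop("cohort_means: empty cohort table", call. = FALSE)
  }
  missing_cols <- setdiff(variables, names(table))
  if (length(missing_cols)) {
    stop("cohort_means: no such column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- lapply(variables, function(v) {
    vals <- table[[v]]
    tim <- table[[axis]]
    ok <- !is.na(vals) & !is.na(tim)
    if (!any(ok)) {
      return(data.frame(
        variable = character(0), time = numeric(0), mean = numeric(0),
        sem = numeric(0), n = integer(0)
      ))
    }
    sp <- split(vals[ok], tim[ok])
    data.frame(
      variable = v,
      time = as.numeric(names(sp)),
      mean = vapply(sp, mean, numeric(1)),
      sem = vapply(sp, function(z) {
        if (length(z) < 2) NA_real_ else stats::sd(z) / sqrt(length(z))
      }, numeric(1)),
      n = vapply(sp, length, integer(1)),
      row.names = NULL
    )
  })
  out <- do.call(rbind, out)
  out[order(out$variable, out$time), , drop = FALSE]
}

#' @export
print.molt_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Synthetic molt-cycle cohort: %d nymphs, %d records (seed %d)\n",
    length(unique(x$nymph_id)), nrow(x), cfg$seed
  ))
  NextMethod()
}
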