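#' Construct a developmental milestone estimate
#'
#' A milestone is a named developmental time point on the days-prior-to-
#' ecdysis axis (positive before the molt) with a standard error. Usually
#' produced by [ecdysteroid_peak_time()], [weight_peak_time()] or
#' [iw_midpoint_time()]; the constructor is exported so that published
#' point estimates can also enter offset arithmetic directly.
#'
#' @param name Milestone name, e.g. `"ecdysteroid_peak"`.
#' @param time Days prior to ecdysis (signed; finite).
#' @param se Standard error in days, >= 0 (may be `NA` if unknown).
#' @param fit Optional source [fit_model()] result.
#' @return Object of class `"molt_milestone"`.
#' @export
milestone <- function(name, time, se = NA_real_, fit = NULL) {
  if (!is.finite(time)) stop("milestone: time must be finite", call. = FALSE)
  if (is.finite(se) && se < 0) stop("milestone: se must be >= 0", call. = FALSE)
  structure(
    list(name = name, time = time, se = se, axis = "days_prior_to_ecdysis",
      fit = fit),
    class = "molt_milestone"
  )
}

#' @export
print.molt_milestone <- function(x, ...) {
  cat(x$name, ":", format_milestone(x), "\n")
  invisible(x)
}

#' Format a milestone as reported text
#'
#' Renders a milestone at one-decimal precision as
#' `"X.X ± X.X days prior to ecdysis"`; an unknown standard error is
#' rendered as `"n/a"`.
#'
#' @param m A [milestone()].
#' @return A character scalar.
#' @export
format_milestone <- function(m) {
  se_txt <- if (is.finite(m$se)) sprintf("%.1f", m$se) else "n/a"
  sprintf("%.1f ± %s days prior to ecdysis", m$time, se_txt)
}

stop_unconverged <- function(fit, what) {
  if (!isTRUE(fit$converged)) {
    stop("inference error: ", what, " requires a converged fit", call. = FALSE)
  }
}

#' Ecdysteroid peak time from a Lorentzian fit
#'
#' The hormone-peak milestone is the fitted Lorentzian location `mu` on the
#' days-prior-to-ecdysis axis; its standard error is the fit standard error
#' of `mu`.
#'
#' @param fit A converged [fit_model()] result for a `"lorentzian"` spec
#'   fitted on the days-prior axis.
#' @return A [milestone()] named `"ecdysteroid_peak"`.
#' @export
ecdysteroid_peak_time <- function(fit) {
  stopifnot(inherits(fit, "molt_fit"), fit$model$name == "lorentzian")
  stop_unconverged(fit, "ecdysteroid_peak_time")
  milestone("ecdysteroid_peak", unname(fit$params[["mu"]]),
    unname(fit$standard_errors[["mu"]]),
    fit = fit
  )
}

#' Weight peak time from a lognormal fit
#'
#' The body-weight gain curve peaks at the lognormal mode
#' \eqn{m = \exp(\mu - \sigma^2)} on the day-of-instar axis; the milestone
#' is `ecdysis_day - m` days prior to ecdysis. Its standard error follows
#' from the fit covariance of \eqn{(\mu, \sigma)} by the delta method with
#' gradient \eqn{(\partial m/\partial\mu, \partial m/\partial\sigma) =
#' (m, -2\sigma m)}; the ecdysis day is treated as exactly observed.
#'
#' @param fit A converged [fit_model()] result for a `"lognorm"` spec
#'   fitted on the day-of-instar axis.
#' @param ecdysis_day Day of instar of the adult molt (for a cohort-mean
#'   fit, the mean ecdysis day).
#' @return A [milestone()] named `"weight_peak"`, with the mode on the
#'   day-of-instar axis attached as `$peak_day_of_instar`.
#' @export
weight_peak_time <- function(fit, ecdysis_day) {
  stopifnot(inherits(fit, "molt_fit"), fit$model$name == "lognorm")
  stop_unconverged(fit, "weight_peak_time")
  if (missing(ecdysis_day) || !is.finite(ecdysis_day)) {
    stop("weight_peak_time: ecdysis_day must be given and finite",
      call. = FALSE
    )
  }
  mu <- unname(fit$params[["mu"]])
  sigma <- unname(fit$params[["sigma"]])
  m <- exp(mu - sigma^2)
  free <- intersect(c("mu", "sigma"), fit$free_params)
  g <- c(mu = m, sigma = -2 * sigma * m)[free]
  V <- fit$covariance[free, free, drop = FALSE]
  se <- sqrt(max(drop(t(g) %*% V %*% g), 0))
  out <- milestone("weight_peak", ecdysis_day - m, se, fit = fit)
  out$peak_day_of_instar <- m
  out
}

#' Inter-wing shift midpoint from a linked linear-constant fit
#'
#' The milestone is the fitted sigmoid midpoint `mu`, the time point of the
#' shift between the linear growth and the constant plateau of the
#' inter-wing distance; its standard error is the fit standard error of
#' `mu`. When the fit was performed on signed time relative to ecdysis
#' (negative before the molt, so the plateau follows the linear rise), set
#' `axis = "days_relative_to_ecdysis"` and the milestone is `-mu` on the
#' days-prior axis.
#'
#' @param fit A converged [fit_model()] result for a
#'   `"linked_linear_constant"` spec.
#' @param axis Axis on which the fit's `x` lived.
#' @return A [milestone()] named `"iw_midpoint"`.
#' @export
iw_midpoint_time <- function(fit,
                             axis = c(
                               "days_prior_to_ecdysis",
                               "days_relative_to_ecdysis"
                             )) {
  stopifnot(inherits(fit, "molt_fit"),
    fit$model$name == "linked_linear_constant")
  axis <- match.arg(axis)
  stop_unconverged(fit, "iw_midpoint_time")
  mu <- unname(fit$params[["mu"]])
  if (axis == "days_relative_to_ecdysis") mu <- -mu
  milestone("iw_midpoint", mu, unname(fit$standard_errors[["mu"]]), fit = fit)
}

#' Offset between two milestones
#'
#' Correlates two milestones by subtraction of their estimated time points:
#' `delta = a$time - b$time` in days (positive when `a` precedes `b`, i.e.
#' lies more days prior to ecdysis). The fits behind different milestones
#' use disjoint response variables, so their uncertainties combine in
#' quadrature: `se = sqrt(a$se^2 + b$se^2)`. No rounding is applied here;
#' one-decimal rounding happens only at report time
#' ([format_offset()]).
#'
#' @param a,b [milestone()] objects on the days-prior-to-ecdysis axis.
#' @return Object of class `"molt_offset"` with fields `from_milestone`,
#'   `to_milestone`, `delta`, `se`.
#' @examples
#' wp <- milestone("weight_peak", 1.8, 0.4)
#' ep <- milestone("ecdysteroid_peak", 2.9, 0.1)
#' milestone_offset(wp, ep) # -1.1 days: weight peak after the hormone peak
#' @export
milestone_offset <- function(a, b) {
  stopifnot(inherits(a, "molt_milestone"), inherits(b, "molt_milestone"))
  if (!identical(a$axis, b$axis)) {
    stop("milestone_offset: milestones on different time axes", call. = FALSE)
  }
  structure(
    list(
      from_milestone = a$name, to_milestone = b$name,
      delta = a$time - b$time,
      se = sqrt(sum(c(a$se, b$se)^2))
    ),
    class = "molt_offset"
  )
}

#' Format a milestone offset as reported text
#'
#' Positive `delta` means the first milestone occurs *before* the second
#' (more days prior to ecdysis); it is rendered with explicit before/after
#' language at one-decimal precision, e.g. a delta of -1.1 days between the
#' weight peak and the ecdysteroid peak reads
#' `"weight_peak 1.1 ± 0.4 days after ecdysteroid_peak"`.
#'
#' @param o A [milestone_offset()].
#' @return A character scalar.
#' @export
format_offset <- function(o) {
  se_txt <- if (is.finite(o$se)) sprintf("%.1f", o$se) else "n/a"
  mag <- sprintf("%.1f", abs(o$delta))
  rel <- if (round(o$delta, 1) > 0) {
    "days before"
  } else if (round(o$delta, 1) < 0) {
    "days after"
  } else {
    "days from"
  }
  sprintf(
    "%s %s ± %s %s %s", o$from_milestone, mag, se_txt, rel,
    o$to_milestone
  )
}

#' @export
print.molt_offset <- function(x, ...) {
  cat(format_offset(x), "\n")
  invisible(x)
}
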