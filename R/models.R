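#' Lognormal trajectory model
#'
#' Area-scaled lognormal density used to describe the body-weight gain of a
#' fifth-instar nymph over the instar:
#' \deqn{f(x; A, \mu, \sigma) = \frac{A}{\sigma\sqrt{2\pi}}
#'   \frac{\exp\left(-\frac{(\ln x - \mu)^2}{2\sigma^2}\right)}{x}}
#' The curve rises from 0, peaks at the lognormal mode
#' \eqn{\exp(\mu - \sigma^2)}, and decays back to 0; \code{A} is the total
#' area under the curve.
#'
#' @param x Time since the start of the instar, in days; must be strictly
#'   positive (the lognormal density is only defined for positive argument).
#' @param A Area scale (g·days for a weight curve).
#' @param mu Log-location parameter (log-days).
#' @param sigma Log-scale parameter (log-days), > 0.
#' @return Model value at each \code{x}.
#' @seealso [lorentzian_model()], [linked_linear_constant_model()],
#'   [fit_model()]
#' @examples
#' x <- seq(0.5, 12, by = 0.5)
#' plot(x, lognorm_model(x, A = 3.5, mu = log(7.2) + 0.04, sigma = 0.2),
#'   type = "l", ylab = "weight increase (g)", xlab = "day of instar"
#' )
#' @export
lognorm_model <- function(x, A, mu, sigma) {
  if (any(sigma <= 0)) stop("lognorm_model: sigma must be > 0", call. = FALSE)
  if (any(x <= 0)) {
    stop("lognorm_model: domain error, x must be > 0", call. = FALSE)
  }
  A / (sigma * sqrt(2 * pi)) * exp(-(log(x) - mu)^2 / (2 * sigma^2)) / x
}

#' Linear-to-constant model with a logistic link
#'
#' Describes a quantity that grows linearly and then plateaus, such as the
#' inter-wing distance of a nymph approaching ecdysis. A linear branch
#' \eqn{b_0 + b_1 x} and a constant plateau \eqn{A} are blended by a
#' logistic weight \eqn{L(x) = 1/(1 + e^{-a})}, \eqn{a = (x - \mu)/\sigma}:
#' \deqn{f(x) = (b_0 + b_1 x)\,(1 - L(x)) + A\,L(x)}
#' so \eqn{f \to b_0 + b_1 x} as \eqn{x \to -\infty} and \eqn{f \to A} as
#' \eqn{x \to +\infty}. \eqn{\mu} is the midpoint of the shift between the
#' two regimes (blend weight exactly 1/2) and \code{sigma_link} its width,
#' conventionally held fixed during fitting. Setting \eqn{b_0 = b_1 = 0}
#' reduces the blend to the pure logistic step \eqn{A\,L(x)}.
#'
#' The logistic weight is evaluated through a branch that never
#' exponentiates a positive argument, so extreme \eqn{|a|} cannot overflow.
#'
#' @param x Time, in days (any real axis).
#' @param A Plateau level (mm for an inter-wing series).
#' @param b0 Intercept of the linear branch (mm).
#' @param b1 Slope of the linear branch (mm/day).
#' @param mu Midpoint of the shift between linear and constant regimes (days).
#' @param sigma_link Width of the link regime (days), > 0.
#' @return Model value at each \code{x}.
#' @examples
#' linked_linear_constant_model(0, A = 2, b0 = 1, b1 = 0.5, mu = 0,
#'   sigma_link = 0.25) # midpoint: (b0 + A)/2
#' @export
linked_linear_constant_model <- function(x, A, b0, b1, mu, sigma_link) {
  if (any(sigma_link <= 0)) {
    stop("linked_linear_constant_model: sigma_link must be > 0", call. = FALSE)
  }
  L <- stable_logistic((x - mu) / sigma_link)
  (b0 + b1 * x) * (1 - L) + A * L
}

# Overflow-safe logistic 1/(1 + exp(-a)): for a < 0 use exp(a)/(1 + exp(a))
# so exp() is never called on a positive argument.
stable_logistic <- function(a) {
  out <- numeric(length(a))
  pos <- !is.na(a) & a >= 0
  out[pos] <- 1 / (1 + exp(-a[pos]))
  ea <- exp(a[!pos])
  out[!pos] <- ea / (1 + ea)
  out[is.na(a)] <- NA_real_
  out
}

#' Lorentzian peak model
#'
#' Cauchy-shaped pulse used to describe the hemolymph ecdysteroid titer over
#' the molt cycle:
#' \deqn{f(x; A, \mu, \sigma) = \frac{A}{\pi}
#'   \frac{\sigma}{(x - \mu)^2 + \sigma^2}}
#' The peak value \eqn{A/(\pi\sigma)} is attained at \eqn{x = \mu}; the
#' curve falls to half that value at \eqn{x = \mu \pm \sigma} (half width at
#' half maximum), and \code{A} is the total area under the curve.
#'
#' @param x Time, in days (typically days prior to ecdysis).
#' @param A Area scale (pg·days/µL for an ecdysteroid titer).
#' @param mu Peak location (days).
#' @param sigma Half width at half maximum (days), > 0.
#' @return Model value at each \code{x} (pg/µL for a titer series).
#' @examples
#' lorentzian_model(0, A = pi, mu = 0, sigma = 1) # peak value 1
#' @export
lorentzian_model <- function(x, A, mu, sigma) {
  if (any(sigma <= 0)) stop("lorentzian_model: sigma must be > 0", call. = FALSE)
  (A / pi) * sigma / ((x - mu)^2 + sigma^2)
}
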