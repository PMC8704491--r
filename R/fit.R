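# Model registry: symbols, optional fixed-only symbols, default fixed values
# and default lower/upper bounds per parameter.
.model_registry <- list(
  lognorm = list(
    symbols = c("A", "mu", "sigma"),
    optional_fixed = "x0",
    default_fixed = c(x0 = 0),
    lower = c(A = -Inf, mu = -Inf, sigma = 1e-8),
    upper = c(A = Inf, mu = Inf, sigma = Inf)
  ),
  linked_linear_constant = list(
    symbols = c("A", "b0", "b1", "mu", "sigma_link"),
    optional_fixed = character(0),
    default_fixed = c(sigma_link = 0.25),
    lower = c(A = -Inf, b0 = -Inf, b1 = -Inf, mu = -Inf, sigma_link = 1e-8),
    upper = c(A = Inf, b0 = Inf, b1 = Inf, mu = Inf, sigma_link = Inf)
  ),
  lorentzian = list(
    symbols = c("A", "mu", "sigma"),
    optional_fixed = character(0),
    default_fixed = NULL,
    lower = c(A = -Inf, mu = -Inf, sigma = 1e-8),
    upper = c(A = Inf, mu = Inf, sigma = Inf)
  )
)

#' Describe one of the three trajectory models for fitting
#'
#' Builds a model specification naming which parameters are free, which are
#' held fixed at given values, the box bounds on the free parameters, and
#' any initial-value overrides. The three models are the ones used for
#' molt-cycle series: `"lognorm"` (weight gain), `"linked_linear_constant"`
#' (inter-wing distance) and `"lorentzian"` (ecdysteroid titer).
#'
#' For `"linked_linear_constant"` the link width `sigma_link` is fixed by
#' default at 0.25 days: it defines the width of the shift regime between
#' the linear and constant branches and is conventionally not fitted, only
#' configured. For `"lognorm"` an optional fixed anchor `x0` may be given;
#' when `x0 > 0` the fitted mean function becomes
#' `f(x) - f(x0)`, the model for a series recorded as *increase since day
#' x0* rather than as an absolute level.
#'
#' @param name One of `"lognorm"`, `"linked_linear_constant"`,
#'   `"lorentzian"`.
#' @param fixed Named numeric vector of parameters to hold fixed (merged
#'   over the model's defaults).
#' @param bounds Named list of `c(lower, upper)` pairs overriding the
#'   default bounds of free parameters.
#' @param init Named numeric vector of starting-value overrides; parameters
#'   not named here are initialized from the data by [fit_model()].
#' @return An object of class `"molt_model_spec"`.
#' @examples
#' model_spec("lorentzian")
#' model_spec("linked_linear_constant", fixed = c(sigma_link = 0.5))
#' model_spec("lognorm", fixed = c(x0 = 4))
#' @export
model_spec <- function(name = c("lognorm", "linked_linear_constant", "lorentzian"),
                       fixed = NULL, bounds = NULL, init = NULL) {
  name <- match.arg(name)
  reg <- .model_registry[[name]]
  all_fixed <- reg$default_fixed
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || any(!nzchar(names(fixed)))) {
      stop("model_spec: 'fixed' must be a named numeric vector", call. = FALSE)
    }
    bad <- setdiff(names(fixed), c(reg$symbols, reg$optional_fixed))
    if (length(bad)) {
      stop("model_spec: unknown parameter(s) for ", name, ": ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    all_fixed[names(fixed)] <- fixed
    all_fixed <- all_fixed[!is.na(all_fixed)]
  }
  free <- setdiff(reg$symbols, names(all_fixed))
  if (!length(free)) stop("model_spec: no free parameters left", call. = FALSE)
  sig <- intersect(c("sigma", "sigma_link"), names(all_fixed))
  if (length(sig) && any(all_fixed[sig] <= 0)) {
    stop("model_spec: ", paste(sig[all_fixed[sig] <= 0], collapse = ", "),
      " must be > 0",
      call. = FALSE
    )
  }
  lower <- reg$lower[free]
  upper <- reg$upper[free]
  if (!is.null(bounds)) {
    for (p in names(bounds)) {
      if (!p %in% free) next
      lower[p] <- bounds[[p]][1]
      upper[p] <- bounds[[p]][2]
    }
  }
  structure(
    list(
      name = name, free_params = free, fixed_params = all_fixed,
      lower = lower, upper = upper, init = init
    ),
    class = "molt_model_spec"
  )
}

#' @export
print.molt_model_spec <- function(x, ...) {
  cat("Model spec:", x$name, "\n")
  cat("  free:  ", paste(x$free_params, collapse = ", "), "\n")
  if (length(x$fixed_params)) {
    cat(
      "  fixed: ",
      paste(sprintf("%s = %g", names(x$fixed_params), x$fixed_params),
        collapse = ", "
      ), "\n"
    )
  }
  invisible(x)
}

# Evaluate a model spec at x for a full (free + fixed) parameter vector.
model_eval <- function(spec, x, params) {
  p <- as.list(params)
  switch(spec$name,
    lognorm = {
      val <- lognorm_model(x, p$A, p$mu, p$sigma)
      x0 <- if (!is.null(p$x0)) p$x0 else 0
      if (x0 > 0) val <- val - lognorm_model(x0, p$A, p$mu, p$sigma)
      val
    },
    linked_linear_constant = linked_linear_constant_model(
      x, p$A, p$b0, p$b1, p$mu, p$sigma_link
    ),
    lorentzian = lorentzian_model(x, p$A, p$mu, p$sigma)
  )
}

# Data-driven starting values. Tie-breaks: earliest time wins (which.max /
# which.min return the first index).
default_init <- function(spec, x, y, err = rep(1, length(x))) {
  o <- order(x)
  xs <- x[o]
  ys <- y[o]
  ws <- err[o]
  init <- switch(spec$name,
    lorentzian = {
      ipk <- which.max(ys)
      pk <- ys[ipk]
      above <- ys >= pk / 2
      sigma0 <- max(
        diff(range(xs[above])) / 2, diff(range(xs)) / 20, 1e-3
      )
      c(A = pk * pi * sigma0, mu = xs[ipk], sigma = sigma0)
    },
    lognorm = {
      # method of moments on the curve treated as a density over x
      w <- pmax(ys, 0)
      if (sum(w) <= 0) w <- rep(1, length(ys))
      w <- w / sum(w)
      lx <- log(xs)
      mu0 <- sum(w * lx)
      sigma0 <- sqrt(max(sum(w * (lx - mu0)^2), 1e-4))
      dx <- if (length(xs) > 1) mean(diff(xs)) else 1
      c(A = max(sum(pmax(ys, 0)) * dx, 1e-6), mu = mu0, sigma = sigma0)
    },
    linked_linear_constant = {
      # given mu (and the fixed link width) the model is linear in
      # (A, b0, b1): profile mu over the observation window with exact
      # weighted linear solves and start from the global profile optimum
      sl <- if ("sigma_link" %in% names(spec$fixed_params)) {
        spec$fixed_params[["sigma_link"]]
      } else {
        0.25
      }
      mus <- seq(min(xs), max(xs), length.out = 201)
      best <- NULL
      for (m in mus) {
        L <- stable_logistic((xs - m) / sl)
        X <- cbind(A = L, b0 = 1 - L, b1 = xs * (1 - L)) / ws
        sol <- stats::lm.fit(X, ys / ws)
        ssr <- sum(sol$residuals^2)
        if (is.null(best) || ssr < best$ssr) {
          best <- list(ssr = ssr, mu = m, cf = sol$coefficients)
        }
      }
      cf <- ifelse(is.na(best$cf), 0, best$cf)
      c(A = unname(cf[1]), b0 = unname(cf[2]), b1 = unname(cf[3]),
        mu = best$mu, sigma_link = sl)
    }
  )
  if (!is.null(spec$init)) init[names(spec$init)] <- spec$init
  init[spec$free_params]
}

#' Fit a trajectory model by weighted nonlinear least squares
#'
#' Minimizes \eqn{\sum_i ((y_i - f(x_i; \theta)) / \epsilon_i)^2} with the
#' Levenberg–Marquardt algorithm ([minpack.lm::nls.lm()]); unit weights are
#' used when `y_err` is absent. The parameter covariance is obtained from a
#' central-difference Jacobian of the weighted residuals at the optimum,
#' \eqn{(J^\top J)^{-1}}, scaled by the reduced chi-square when `y_err` is
#' absent (so the noise scale is estimated from the residuals) and unscaled
#' when measurement errors are supplied.
#'
#' Starting values are data-driven: peak location and width from the
#' observed maximum and half-maximum span (Lorentzian), method of moments
#' on the curve treated as a density (lognormal), and, for the linked
#' linear-constant model, a profile of the shift point over the
#' observation window — the model is linear in `(A, b0, b1)` once `mu` and
#' the link width are given, so each candidate shift point is scored by an
#' exact weighted linear solve and optimization starts from the global
#' profile optimum. The shift point of the linked model is also bounded to
#' the observation window by default, since a breakpoint outside the
#' sampled days is not estimable.
#'
#' @param spec A [model_spec()].
#' @param x,y Numeric vectors of equal length (at least one more point than
#'   free parameters).
#' @param y_err Optional per-point measurement standard errors, all > 0.
#' @param init Optional named starting-value overrides (take precedence over
#'   both data-driven defaults and `spec$init`).
#' @param control A [minpack.lm::nls.lm.control()] list.
#' @return An object of class `"molt_fit"`: list with `model` (the spec),
#'   `params` (free and fixed estimates), `covariance` and
#'   `standard_errors` over the free parameters, `chi2_red`, `dof`,
#'   `residuals` (raw, \eqn{y - \hat f}), `fitted`, `converged`,
#'   `n_points`, `weighted` and the data.
#'   Non-convergence is reported through `converged = FALSE`, not an error.
#' @examples
#' x <- seq(0, 10, by = 0.5)
#' y <- lorentzian_model(x, A = 100, mu = 3, sigma = 0.8)
#' fit <- fit_model(model_spec("lorentzian"), x, y)
#' coef(fit)
#' @export
fit_model <- function(spec, x, y, y_err = NULL, init = NULL,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 1000, maxfev = 5000, ftol = 1e-12,
                        ptol = 1e-12
                      )) {
  stopifnot(inherits(spec, "molt_model_spec"))
  if (length(x) != length(y)) {
    stop("fit_model: x and y must have equal length", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(y_err)) {
    if (length(y_err) != length(y)) {
      stop("fit_model: y_err must match y in length", call. = FALSE)
    }
    keep <- keep & is.finite(y_err)
  }
  x <- x[keep]
  y <- y[keep]
  if (!is.null(y_err)) {
    y_err <- y_err[keep]
    if (any(y_err <= 0)) {
      stop("fit_model: y_err must be > 0 everywhere", call. = FALSE)
    }
  }
  n <- length(x)
  k <- length(spec$free_params)
  dof <- n - k
  if (dof <= 0) {
    stop("fit_model: need more points than free parameters (dof > 0)",
      call. = FALSE
    )
  }
  err <- if (is.null(y_err)) rep(1, n) else y_err

  resid_fn <- function(p) {
    names(p) <- spec$free_params
    (y - model_eval(spec, x, c(p, spec$fixed_params))) / err
  }
  # the shift point of the linked model is only estimable inside the
  # observation window; keep its default bounds there
  lower <- spec$lower
  upper <- spec$upper
  if (spec$name == "linked_linear_constant" && "mu" %in% spec$free_params &&
    is.infinite(lower[["mu"]]) && is.infinite(upper[["mu"]])) {
    lower[["mu"]] <- min(x)
    upper[["mu"]] <- max(x)
  }

  p0 <- default_init(spec, x, y, err)
  if (!is.null(init)) p0[intersect(names(init), names(p0))] <-
      init[intersect(names(init), names(p0))]
  p0 <- pmin(pmax(p0, lower), upper)

  res <- tryCatch(
    minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper,
      fn = resid_fn, control = control
    ),
    error = function(e) NULL
  )
  if (is.null(res)) {
    est <- p0
    converged <- FALSE
  } else {
    est <- stats::setNames(unname(res$par), spec$free_params)
    converged <- res$info %in% 1:4
  }
  params <- c(est, spec$fixed_params)
  fitted <- model_eval(spec, x, params)
  wres <- (y - fitted) / err
  chi2_red <- sum(wres^2) / dof

  J <- num_jacobian(resid_fn, est)
  jtj <- crossprod(J)
  cov <- tryCatch(solve(jtj), error = function(e) MASS::ginv(jtj))
  if (is.null(y_err)) cov <- cov * chi2_red
  dimnames(cov) <- list(spec$free_params, spec$free_params)
  se <- sqrt(pmax(diag(cov), 0))

  structure(
    list(
      model = spec,
      params = params,
      free_params = spec$free_params,
      covariance = cov,
      standard_errors = se,
      chi2_red = chi2_red,
      dof = dof,
      residuals = y - fitted,
      fitted = fitted,
      converged = converged,
      n_points = n,
      weighted = !is.null(y_err),
      x = x, y = y, y_err = y_err
    ),
    class = "molt_fit"
  )
}

# Central-difference Jacobian of a vector-valued function at p.
num_jacobian <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1)
    pp <- p
    pm <- p
    pp[j] <- p[j] + h
    pm[j] <- p[j] - h
    J[, j] <- (f(pm) - f(pp)) / (2 * h) # resid = (y - f)/err, d/dp flips sign
  }
  J
}

#' @export
coef.molt_fit <- function(object, ...) object$params

#' @export
vcov.molt_fit <- function(object, ...) object$covariance

#' @export
print.molt_fit <- function(x, ...) {
  cat(sprintf(
    "Weighted NLS fit: %s (%s)\n", x$model$name,
    if (x$converged) "converged" else "NOT converged"
  ))
  for (p in x$free_params) {
    cat(sprintf("  %-10s %10.5g ± %.3g\n", p, x$params[[p]],
      x$standard_errors[[p]]))
  }
  if (length(x$model$fixed_params)) {
    cat(
      "  fixed:",
      paste(sprintf("%s = %g", names(x$model$fixed_params),
        x$model$fixed_params), collapse = ", "), "\n"
    )
  }
  cat(sprintf(
    "  chi2_red = %.4g on %d dof (%d points, %s weights)\n",
    x$chi2_red, x$dof, x$n_points,
    if (x$weighted) "measurement-error" else "unit"
  ))
  invisible(x)
}
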