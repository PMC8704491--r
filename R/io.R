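#' Read and write cohort tables as tidy CSV
#'
#' Cohort tables round-trip as plain CSV with a header row and empty fields
#' for missing values. `read_cohort` validates the required columns,
#' recomputes `days_prior_to_ecdysis = ecdysis_day - day_of_instar` and
#' checks basic record invariants (non-negative days and measurements, one
#' record per nymph and day).
#'
#' @param table A cohort data frame.
#' @param path File path.
#' @return `read_cohort`: a `data.frame` of class `"molt_cohort"`;
#'   `write_cohort`: the path, invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("read_cohort: cannot read cohort table at '", path, "'",
      call. = FALSE
    )
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  req <- c(
    "nymph_id", "day_of_instar", "ecdysis_day", "weight",
    "inter_wing_distance", "ecdysteroid_titer"
  )
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("read_cohort: '", path, "' lacks column(s): ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  tab$days_prior_to_ecdysis <- tab$ecdysis_day - tab$day_of_instar
  if (any(tab$day_of_instar < 0)) {
    stop("read_cohort: day_of_instar must be >= 0", call. = FALSE)
  }
  for (v in c("weight", "inter_wing_distance", "ecdysteroid_titer")) {
    if (any(tab[[v]] < 0, na.rm = TRUE)) {
      stop("read_cohort: ", v, " must be >= 0 where present", call. = FALSE)
    }
  }
  if (anyDuplicated(tab[, c("nymph_id", "day_of_instar")])) {
    stop("read_cohort: duplicate (nymph_id, day_of_instar) records",
      call. = FALSE
    )
  }
  structure(tab, class = c("molt_cohort", "data.frame"))
}

#' Serialize a fit result to JSON
#'
#' Writes parameters, standard errors, covariance, reduced chi-square,
#' degrees of freedom and the convergence flag; `read_fit_json` restores
#' the numeric content (as a plain list, not a refittable object).
#'
#' @param fit A [fit_model()] result.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    model = fit$model$name,
    params = as.list(fit$params),
    fixed = as.list(fit$model$fixed_params),
    standard_errors = as.list(fit$standard_errors),
    covariance = unname(apply(fit$covariance, 1, as.list)),
    covariance_params = fit$free_params,
    chi2_red = fit$chi2_red,
    dof = fit$dof,
    n_points = fit$n_points,
    converged = fit$converged
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a pipeline run configuration from YAML
#'
#' Maps a YAML document onto [run_config()]: a top-level `data:` path
#' selects measured-data mode, otherwise the `cohort:` block (fields of
#' [cohort_config()]) configures the simulator; `rules:` carries
#' [staging_rules()] fields, `fit:` may set `sigma_link` and
#' `weight_mode`, and `seed:`/`out_dir:` are passed through.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("read_run_config: cannot read config at '", path, "'", call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  cohort <- NULL
  if (is.null(y$data)) {
    cohort <- do.call(cohort_config, y$cohort %||% list())
  }
  rules <- do.call(staging_rules, y$rules %||% list())
  run_config(
    cohort = cohort,
    data = y$data,
    sigma_link = y$fit$sigma_link,
    weight_mode = y$fit$weight_mode %||% "increase",
    rules = rules,
    out_dir = y$out_dir,
    seed = y$seed
  )
}
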