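#' Configuration of a full pipeline run
#'
#' Exactly one input source must be given: a [cohort_config()] for
#' simulated data, or `data`, a path to a measured cohort CSV
#' ([read_cohort()]); measured-data mode never invokes the simulator.
#'
#' @param cohort A [cohort_config()], or `NULL` in measured-data mode.
#' @param data Path to a cohort CSV, or `NULL` in simulation mode.
#' @param sigma_link Fixed link width (days) for the inter-wing fit;
#'   default `NULL` takes the simulator's own `iw_curve$sigma_link` in
#'   simulation mode and 0.25 days in measured-data mode.
#' @param weight_mode `"increase"` (default): the weight channel is fitted
#'   as gain relative to the first sampled day, with the lognormal
#'   anchored there (see [model_spec()]'s `x0`); `"absolute"`: the raw
#'   weight is fitted directly (sensible only when the baseline weight is
#'   negligible against the gain).
#' @param rules A [staging_rules()].
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes cohort, means, fits, milestones, offsets, staging and a text
#'   report there.
#' @param seed Optional integer overriding the cohort config's seed; the
#'   single source of randomness for the run.
#' @return Object of class `"molt_run_config"`.
#' @export
run_config <- function(cohort = cohort_config(), data = NULL,
                       sigma_link = NULL,
                       weight_mode = c("increase", "absolute"),
                       rules = staging_rules(), out_dir = NULL, seed = NULL) {
  weight_mode <- match.arg(weight_mode)
  if (is.null(data) == is.null(cohort)) {
    stop("run_config: give exactly one of 'cohort' (simulate) or 'data' (path)",
      call. = FALSE
    )
  }
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "molt_cohort_config"))
    if (!is.null(seed)) cohort$seed <- as.integer(seed)
    seed <- cohort$seed
  }
  structure(
    list(
      cohort = cohort, data = data, sigma_link = sigma_link,
      weight_mode = weight_mode, rules = rules, out_dir = out_dir,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "molt_run_config"
  )
}

# Cohort means for one variable on one axis, as a fit-ready frame; points
# with fewer than 2 nymphs carry an undefined sem and are unusable as
# weights, so weighting falls back to unit weights unless every point has
# a positive sem.
fit_channel <- function(means, variable, spec, flip_x = FALSE, drop_time = NULL,
                        verbose = FALSE) {
  sub <- means[means$variable == variable, , drop = FALSE]
  if (!is.null(drop_time)) sub <- sub[sub$time != drop_time, , drop = FALSE]
  x <- if (flip_x) -sub$time else sub$time
  y_err <- if (all(is.finite(sub$sem)) && all(sub$sem > 0)) sub$sem else NULL
  fit <- fit_model(spec, x, sub$mean, y_err = y_err)
  if (verbose) {
    message(sprintf(
      "  %s fit (%s): chi2_red = %.3g, dof = %d, %s", variable,
      spec$name, fit$chi2_red, fit$dof,
      if (fit$converged) "converged" else "NOT converged"
    ))
  }
  fit
}

#' Run the complete milestone pipeline
#'
#' Orchestrates cohort acquisition (simulate or load), cohort means on both
#' time axes, the three model fits (Lorentzian for the ecdysteroid titer on
#' the days-prior axis; linked linear-constant for the inter-wing distance
#' on signed time relative to ecdysis; anchored lognormal for the weight
#' gain on the day-of-instar axis), milestone extraction with delta-method
#' uncertainties, all pairwise milestone offsets, and rule-based staging.
#' An unconverged fit is reported and its milestone (and the offsets
#' involving it) are left absent rather than raising an error.
#'
#' @param config A [run_config()] (or a path understood by
#'   [read_run_config()]).
#' @param verbose Log stage-by-stage progress and per-fit convergence.
#' @return Object of class `"molt_run"`: list with `cohort`, `means`
#'   (per-axis), `fits`, `milestones`, `offsets`, `staging` and
#'   `provenance` (seed, config hash, package version, input mode). The
#'   report is byte-reproducible from config + seed ([report_hash()]).
#' @examples
#' run <- run_pipeline(run_config(cohort_config(seed = 17)))
#' cat(render_report(run), sep = "\n")
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "molt_run_config"))

  simulated <- is.null(config$data)
  if (simulated) {
    if (verbose) message("simulating cohort (seed ", config$seed, ") ...")
    cohort <- generate_cohort(config$cohort)
  } else {
    if (verbose) message("reading cohort from ", config$data, " ...")
    cohort <- read_cohort(config$data)
  }

  # weight gain relative to each nymph's first sampled day with a present
  # weight; the anchor day itself carries an identically zero gain and is
  # excluded from the weight fit
  cohort$weight_increase <- NA_real_
  anchors <- numeric(0)
  for (id in unique(cohort$nymph_id)) {
    idx <- which(cohort$nymph_id == id)
    idx <- idx[order(cohort$day_of_instar[idx])]
    pres <- idx[!is.na(cohort$weight[idx])]
    if (!length(pres)) next
    anchors <- c(anchors, cohort$day_of_instar[pres[1]])
    cohort$weight_increase[idx] <- cohort$weight[idx] - cohort$weight[pres[1]]
  }
  anchor_day <- if (length(anchors)) min(anchors) else NA_real_

  means_day <- cohort_means(cohort, "day_of_instar",
    variables = c("weight", "weight_increase")
  )
  means_prior <- cohort_means(cohort, "days_prior_to_ecdysis",
    variables = c("inter_wing_distance", "ecdysteroid_titer")
  )

  sigma_link <- config$sigma_link %||%
    (if (simulated) config$cohort$iw_curve$sigma_link else 0.25)

  if (verbose) message("fitting trajectory models ...")
  fits <- list(
    ecdysteroid = fit_channel(
      means_prior, "ecdysteroid_titer", model_spec("lorentzian"),
      verbose = verbose
    ),
    inter_wing = fit_channel(
      means_prior, "inter_wing_distance",
      model_spec("linked_linear_constant", fixed = c(sigma_link = sigma_link)),
      flip_x = TRUE, verbose = verbose
    ),
    weight = if (config$weight_mode == "increase") {
      fit_channel(
        means_day, "weight_increase",
        model_spec("lognorm", fixed = c(x0 = anchor_day)),
        drop_time = anchor_day, verbose = verbose
      )
    } else {
      fit_channel(means_day, "weight", model_spec("lognorm"),
        verbose = verbose
      )
    }
  )

  mean_ecdysis <- mean(cohort$ecdysis_day[!duplicated(cohort$nymph_id)])
  milestones <- list(
    ecdysteroid_peak = if (fits$ecdysteroid$converged) {
      ecdysteroid_peak_time(fits$ecdysteroid)
    },
    weight_peak = if (fits$weight$converged) {
      weight_peak_time(fits$weight, ecdysis_day = mean_ecdysis)
    },
    iw_midpoint = if (fits$inter_wing$converged) {
      iw_midpoint_time(fits$inter_wing, axis = "days_relative_to_ecdysis")
    }
  )

  pairs <- list(
    c("ecdysteroid_peak", "weight_peak"),
    c("iw_midpoint", "ecdysteroid_peak"),
    c("iw_midpoint", "weight_peak")
  )
  offsets <- list()
  for (p in pairs) {
    a <- milestones[[p[1]]]
    b <- milestones[[p[2]]]
    if (!is.null(a) && !is.null(b)) {
      offsets[[paste(p[1], "vs", p[2])]] <- milestone_offset(a, b)
    }
  }

  if (verbose) message("staging nymphs ...")
  staging <- stage_cohort(cohort, config$rules)

  cfg_hash <- object_md5(unclass(config)[c(
    "cohort", "data", "sigma_link", "weight_mode", "rules", "seed"
  )])
  report <- structure(
    list(
      cohort = cohort,
      means = list(day_of_instar = means_day, days_prior = means_prior),
      fits = fits,
      milestones = milestones,
      offsets = offsets,
      staging = staging,
      mean_ecdysis_day = mean_ecdysis,
      provenance = list(
        seed = config$seed,
        config_hash = cfg_hash,
        mode = if (simulated) "simulated" else "measured",
        package_version = as.character(utils::packageVersion("moltstage"))
      ),
      config = config
    ),
    class = "molt_run"
  )
  if (!is.null(config$out_dir)) write_run_outputs(report, config$out_dir)
  report
}

#' Hash of the scientific content of a run report
#'
#' md5 over the cohort, fit parameters, milestones, offsets and staging --
#' everything except the config object itself -- so two runs from the same
#' config and seed hash identically.
#'
#' @param report A [run_pipeline()] result.
#' @return md5 string.
#' @export
report_hash <- function(report) {
  stopifnot(inherits(report, "molt_run"))
  strip <- function(f) f[c("params", "standard_errors", "chi2_red", "dof",
    "converged")]
  object_md5(list(
    cohort = as.data.frame(report$cohort),
    fits = lapply(report$fits, strip),
    milestones = lapply(report$milestones, function(m) {
      if (is.null(m)) NULL else m[c("name", "time", "se")]
    }),
    offsets = lapply(report$offsets, unclass),
    staging = report$staging$results,
    summary = report$staging$summary
  ))
}

#' Render a run report as human-readable text
#'
#' One line per fit, milestone (one-decimal `"X.X ± X.X days prior to
#' ecdysis"`), offset (explicit before/after language) and staging summary
#' row.
#'
#' @param report A [run_pipeline()] result.
#' @return Character vector of report lines.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "molt_run"))
  pv <- report$provenance
  lines <- c(
    "Molt-cycle milestone report",
    sprintf(
      "  mode: %s | seed: %s | config: %s | moltstage %s", pv$mode,
      pv$seed, substr(pv$config_hash, 1, 8), pv$package_version
    ),
    "",
    "Fits:"
  )
  for (nm in names(report$fits)) {
    f <- report$fits[[nm]]
    lines <- c(lines, sprintf(
      "  %-12s %-22s chi2_red = %.3g, dof = %d%s", nm, f$model$name,
      f$chi2_red, f$dof, if (f$converged) "" else "  [NOT converged]"
    ))
  }
  lines <- c(lines, "", "Milestones (days prior to ecdysis):")
  for (nm in names(report$milestones)) {
    m <- report$milestones[[nm]]
    lines <- c(lines, sprintf(
      "  %-17s %s", nm,
      if (is.null(m)) "n/a (fit did not converge)" else format_milestone(m)
    ))
  }
  lines <- c(lines, "", "Offsets:")
  if (!length(report$offsets)) lines <- c(lines, "  none available")
  for (o in report$offsets) {
    lines <- c(lines, paste0("  ", format_offset(o)))
  }
  lines <- c(lines, "", "Staging summary (rule-based, per nymph):")
  s <- report$staging$summary
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "  %-5s n = %2d  %s", s$milestone[i], s$n[i],
      if (s$n[i] == 0) {
        "never fired"
      } else {
        sprintf(
          "%.1f ± %s days prior to ecdysis", s$mean_days_prior[i],
          if (is.finite(s$sem_days_prior[i])) {
            sprintf("%.1f", s$sem_days_prior[i])
          } else {
            "n/a"
          }
        )
      }
    ))
  }
  lines
}

#' @export
print.molt_run <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

# Write all pipeline artifacts to a directory: tidy CSV/TSV plus JSON for
# fits and milestones, and the rendered text report.
write_run_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_cohort(report$cohort, p("cohort.csv"))
  utils::write.csv(report$means$day_of_instar, p("means_day.csv"),
    row.names = FALSE, na = ""
  )
  utils::write.csv(report$means$days_prior, p("means_prior.csv"),
    row.names = FALSE, na = ""
  )
  for (nm in names(report$fits)) {
    write_fit_json(report$fits[[nm]], p(sprintf("fit_%s.json", nm)))
  }
  ms <- lapply(report$milestones, function(m) {
    if (is.null(m)) NULL else list(time_days_prior = m$time, se = m$se)
  })
  jsonlite::write_json(
    list(milestones = ms, provenance = report$provenance),
    p("milestones.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  off <- do.call(rbind, lapply(report$offsets, function(o) {
    data.frame(
      from = o$from_milestone, to = o$to_milestone, delta_days = o$delta,
      se_days = o$se
    )
  }))
  if (is.null(off)) {
    off <- data.frame(
      from = character(0), to = character(0),
      delta_days = numeric(0), se_days = numeric(0)
    )
  }
  utils::write.table(off, p("offsets.tsv"),
    sep = "\t", row.names = FALSE,
    quote = FALSE
  )
  utils::write.table(report$staging$results, p("staging.tsv"),
    sep = "\t",
    row.names = FALSE, quote = FALSE
  )
  writeLines(render_report(report), p("report.txt"))
  invisible(out_dir)
}
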