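#' Rules for non-invasive molt-stage classification
#'
#' Thresholds for the three observable milestones of the fifth-instar molt
#' cycle: N5IW fires on the first day the inter-wing distance reaches
#' `iw_threshold` (default 1.8 mm); N5WD fires on the first day the body
#' weight has dropped by at least `wd_threshold` (default 0.1 g) below the
#' reference weight; N5WP is the day of maximum weight strictly before the
#' N5WD day. The reference for the weight drop is either the running
#' maximum of all earlier weights (default; robust to a single noisy
#' plateau day) or the previous day's weight.
#'
#' @param iw_threshold Inter-wing distance threshold in mm, > 0.
#' @param wd_threshold Weight-decrease threshold in g, > 0.
#' @param reference `"running_max"` or `"previous_day"`.
#' @return Object of class `"molt_staging_rules"`.
#' @export
staging_rules <- function(iw_threshold = 1.8, wd_threshold = 0.1,
                          reference = c("running_max", "previous_day")) {
  reference <- match.arg(reference)
  if (!is.numeric(iw_threshold) || iw_threshold <= 0) {
    stop("staging_rules: iw_threshold must be > 0", call. = FALSE)
  }
  if (!is.numeric(wd_threshold) || wd_threshold <= 0) {
    stop("staging_rules: wd_threshold must be > 0", call. = FALSE)
  }
  structure(
    list(
      iw_threshold = iw_threshold, wd_threshold = wd_threshold,
      reference = reference
    ),
    class = "molt_staging_rules"
  )
}

#' Stage a single nymph from its daily measurements
#'
#' Applies the [staging_rules()] to one nymph's day-sorted series. A day
#' with a missing measurement cannot fire the corresponding rule but does
#' not abort staging; a rule that never fires yields `NA` for that
#' milestone day. When both are present, the weight peak day always
#' precedes the weight decrease day by construction. Ties for the maximum
#' weight are broken by the latest qualifying day (the peak immediately
#' precedes the decrease).
#'
#' @param series Data frame for one nymph with columns `day_of_instar`
#'   (sorted, unique), `weight`, `inter_wing_distance`.
#' @param rules A [staging_rules()].
#' @return One-row data frame with `n5iw_day`, `n5wp_day`, `n5wd_day` and
#'   the triggering values `n5iw_value` (mm), `n5wp_weight` (g),
#'   `n5wd_drop` (g).
#' @examples
#' s <- data.frame(
#'   day_of_instar = 4:7, weight = c(1.00, 1.20, 1.05, 1.00),
#'   inter_wing_distance = c(1.2, 1.5, 1.9, 2.0)
#' )
#' stage_nymph(s, staging_rules())
#' @export
stage_nymph <- function(series, rules = staging_rules()) {
  stopifnot(inherits(rules, "molt_staging_rules"))
  day <- series$day_of_instar
  if (is.unsorted(day, strictly = TRUE)) {
    stop("stage_nymph: input error, days must be sorted and unique",
      call. = FALSE
    )
  }
  iw <- series$inter_wing_distance
  w <- series$weight
  if (sum(!is.na(w)) < 2 || sum(!is.na(iw)) < 2) {
    stop("stage_nymph: need weight and inter-wing distance on >= 2 days",
      call. = FALSE
    )
  }

  hit <- which(!is.na(iw) & iw >= rules$iw_threshold)
  n5iw_day <- if (length(hit)) day[hit[1]] else NA_real_
  n5iw_value <- if (length(hit)) iw[hit[1]] else NA_real_

  present <- which(!is.na(w))
  n5wd_day <- n5wp_day <- n5wp_weight <- n5wd_drop <- NA_real_
  for (j in seq_along(present)[-1]) {
    i <- present[j]
    prev <- present[seq_len(j - 1)]
    ref <- if (rules$reference == "running_max") {
      max(w[prev])
    } else {
      w[prev[length(prev)]]
    }
    if (w[i] <= ref - rules$wd_threshold) {
      n5wd_day <- day[i]
      n5wd_drop <- ref - w[i]
      before <- prev
      mx <- max(w[before])
      cand <- before[w[before] == mx]
      n5wp_day <- day[cand[length(cand)]] # tie: latest day wins
      n5wp_weight <- mx
      break
    }
  }

  data.frame(
    n5iw_day = n5iw_day, n5wp_day = n5wp_day, n5wd_day = n5wd_day,
    n5iw_value = n5iw_value, n5wp_weight = n5wp_weight,
    n5wd_drop = n5wd_drop
  )
}

#' Stage every nymph in a cohort
#'
#' Applies [stage_nymph()] per nymph (records are sorted by day first, so
#' the result is insensitive to row order) and summarizes each milestone
#' over the nymphs where its rule fired, as mean ± SEM in days prior to
#' ecdysis.
#'
#' @param table A cohort table with columns `nymph_id`, `day_of_instar`,
#'   `ecdysis_day`, `weight`, `inter_wing_distance`.
#' @param rules A [staging_rules()].
#' @return Object of class `"molt_staging"`: list with `results` (one row
#'   per nymph, milestone days plus triggering values) and `summary` (one
#'   row per milestone: `n` fired, `mean_days_prior`, `sem_days_prior`).
#' @export
stage_cohort <- function(table, rules = staging_rules()) {
  stopifnot(is.data.frame(table))
  ids <- unique(table$nymph_id)
  rows <- lapply(ids, function(id) {
    s <- table[table$nymph_id == id, , drop = FALSE]
    s <- s[order(s$day_of_instar), , drop = FALSE]
    out <- stage_nymph(s, rules)
    out$nymph_id <- id
    out$ecdysis_day <- s$ecdysis_day[1]
    out
  })
  results <- do.call(rbind, rows)
  results <- results[, c(
    "nymph_id", "ecdysis_day", "n5iw_day", "n5wp_day",
    "n5wd_day", "n5iw_value", "n5wp_weight", "n5wd_drop"
  )]

  summarize <- function(days) {
    dp <- results$ecdysis_day - days
    dp <- dp[!is.na(dp)]
    n <- length(dp)
    data.frame(
      n = n,
      mean_days_prior = if (n) mean(dp) else NA_real_,
      sem_days_prior = if (n >= 2) stats::sd(dp) / sqrt(n) else NA_real_
    )
  }
  summary <- cbind(
    milestone = c("N5IW", "N5WP", "N5WD"),
    rbind(
      summarize(results$n5iw_day),
      summarize(results$n5wp_day),
      summarize(results$n5wd_day)
    )
  )
  structure(list(results = results, summary = summary, rules = rules),
    class = "molt_staging"
  )
}

#' @export
print.molt_staging <- function(x, ...) {
  cat(sprintf(
    "Molt-stage classification of %d nymphs (iw >= %.2g mm, drop >= %.2g g, %s reference)\n",
    nrow(x$results), x$rules$iw_threshold, x$rules$wd_threshold,
    x$rules$reference
  ))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
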