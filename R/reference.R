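#' Detect outlying observations about a fitted growth curve
#'
#' An observation is an outlier when its absolute residual about the modelled
#' mean strictly exceeds three times the age-local standard deviation (a
#' residual of exactly 3 SD is not flagged).
#'
#' @param points data.frame with `age` and `value`.
#' @param model Fitted `growth_model`.
#' @param sd_profile `sd_profile` computed from the same points.
#' @param k SD multiple (default 3).
#' @return Integer indices of outlying rows of `points`.
#' @export
detect_outliers <- function(points, model, sd_profile, k = 3) {
  x <- as.numeric(points$age)
  r <- abs(as.numeric(points$value) - eval_curve(model, x))
  which(r > k * sd_at(sd_profile, x))
}

#' Reference-construction configuration
#'
#' @param criterion Model-selection criterion, `"rss"` (paper-literal minimum
#'   residual sum of squares) or `"aicc"`.
#' @param bandwidth Kernel bandwidth for the age-varying SD, years.
#' @param B Bootstrap replicates for the mean-curve confidence band; `B = 0`
#'   skips the band (useful when only means/SDs are needed).
#' @param max_iter Maximum outlier-removal refit iterations.
#' @param min_stratum_n Minimum usable records per (measurement, sex) stratum.
#' @param outlier_k SD multiple defining an outlier.
#' @return A plain list of settings.
#' @export
reference_config <- function(criterion = "rss", bandwidth = 2, B = 500,
                             max_iter = 5, min_stratum_n = 30, outlier_k = 3) {
  list(criterion = criterion, bandwidth = bandwidth, B = B,
       max_iter = max_iter, min_stratum_n = min_stratum_n,
       outlier_k = outlier_k)
}

#' Build one sex-specific normative reference curve
#'
#' Implements the reference-construction loop for a single (measurement, sex)
#' stratum: select the best growth-curve family, estimate the age-varying SD,
#' flag observations more than three local SDs from the modelled mean, drop
#' them (this package's stand-in for sending outliers back for landmark
#' reappraisal, which a repository cannot do) and refit; iterate until no new
#' outliers appear or `max_iter` is reached. Finally the 95% bootstrap band
#' for the mean curve is attached.
#'
#' @param records Long data.frame of measurement records (columns
#'   `subject_id`, `age_years`, `sex`, `measurement`, `value`, `usable`).
#' @param measurement Measurement name to fit.
#' @param sex `"M"` or `"F"`.
#' @param config See [reference_config()].
#' @return A `reference_curve`: measurement, sex, `model`, `sd_profile`,
#'   `ci` (or `NULL` when `B = 0`), `age_range_sampled`, `n_subjects`,
#'   `outliers_removed`, and `points` (the retained observations).
#' @export
fit_reference <- function(records, measurement, sex,
                          config = reference_config()) {
  sel <- records$measurement == measurement & records$sex == sex &
    records$usable & is.finite(records$value)
  pts <- data.frame(age = records$age_years[sel], value = records$value[sel])
  if (nrow(pts) < config$min_stratum_n) {
    stop(sprintf(
      "stratum (%s, %s) has %d usable records; at least %d are required",
      measurement, sex, nrow(pts), config$min_stratum_n), call. = FALSE)
  }
  removed <- 0L
  for (iter in seq_len(config$max_iter)) {
    model <- select_model(pts, criterion = config$criterion)
    prof <- estimate_sd_profile(pts, model, bandwidth = config$bandwidth)
    out <- detect_outliers(pts, model, prof, k = config$outlier_k)
    if (length(out) == 0L) break
    pts <- pts[-out, , drop = FALSE]
    removed <- removed + length(out)
  }
  if (length(out) > 0L) {  # max_iter exhausted mid-removal: refit once
    model <- select_model(pts, criterion = config$criterion)
    prof <- estimate_sd_profile(pts, model, bandwidth = config$bandwidth)
  }
  ci <- if (config$B > 0) {
    estimate_ci(pts, model$family, B = config$B, ages = prof$ages)
  } else NULL
  structure(
    list(measurement = measurement, sex = sex, model = model,
         sd_profile = prof, ci = ci,
         age_range_sampled = range(pts$age),
         n_subjects = nrow(pts), outliers_removed = removed,
         points = pts),
    class = "reference_curve"
  )
}

#' @export
print.reference_curve <- function(x, ...) {
  cat(sprintf("<reference_curve> %s (%s): %s model, n=%d, %d outlier(s) removed, ages %.1f-%.1f\n",
              x$measurement, x$sex, x$model$family, x$n_subjects,
              x$outliers_removed, x$age_range_sampled[1], x$age_range_sampled[2]))
  invisible(x)
}

#' Build a full reference set over measurements and sexes
#'
#' Runs [fit_reference()] for every (measurement, sex) stratum present in the
#' records with enough usable observations; strata below the configured
#' minimum are skipped with a message.
#'
#' @param records Long measurement data.frame.
#' @param ancestry Label recorded in the reference set.
#' @param measurements Measurement names (default: all present).
#' @param sexes Default `c("F", "M")`.
#' @param config See [reference_config()].
#' @return A `reference_set`: ancestry, named list of `reference_curve`s
#'   (keys `"measurement|sex"`), provenance (creation date, package version,
#'   config hash).
#' @export
fit_reference_set <- function(records, ancestry = "unspecified",
                              measurements = NULL, sexes = c("F", "M"),
                              config = reference_config()) {
  if (is.null(measurements)) measurements <- unique(records$measurement)
  curves <- list()
  for (m in measurements) {
    for (s in sexes) {
      curve <- tryCatch(fit_reference(records, m, s, config),
                        error = function(e) {
                          message("skipping (", m, ", ", s, "): ",
                                  conditionMessage(e))
                          NULL
                        })
      if (!is.null(curve)) curves[[paste(m, s, sep = "|")]] <- curve
    }
  }
  reference_set(ancestry, curves, config)
}

reference_set <- function(ancestry, curves, config = reference_config()) {
  keys <- names(curves)
  if (anyDuplicated(keys) > 0) {
    stop("at most one curve per (measurement, sex)", call. = FALSE)
  }
  structure(
    list(
      ancestry = ancestry,
      curves = curves,
      provenance = list(
        created = format(Sys.Date()),
        pipeline_version = as.character(utils::packageVersion("facenorms")),
        config_hash = rlang::hash(config)
      )
    ),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set>", x$ancestry, "-", length(x$curves), "curves\n")
  for (k in names(x$curves)) {
    c <- x$curves[[k]]
    cat(sprintf("  %-28s %s  %-9s n=%d\n", c$measurement, c$sex,
                c$model$family, c$n_subjects))
  }
  invisible(x)
}

ref_curve_for <- function(refset, measurement, sex) {
  refset$curves[[paste(measurement, sex, sep = "|")]]
}
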