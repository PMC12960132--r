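#' Age-varying residual standard deviation
#'
#' Estimates how the residual SD about a fitted growth curve varies with age:
#' at each point of a 0.5-year grid over the sampled age range, the SD is the
#' square root of the Gaussian-kernel-weighted mean squared residual. Grid
#' points whose effective local sample weight (the sum of kernel weights,
#' i.e. the equivalent number of observations at that age) falls below 3 are
#' still reported but flagged low-confidence.
#'
#' @param points data.frame with `age` and `value`.
#' @param model Fitted `growth_model` for these points.
#' @param bandwidth Gaussian kernel bandwidth in years (default 2).
#' @param grid_step Grid spacing in years (default 0.5).
#' @return An `sd_profile`: list with `ages`, `sd` (mm), `bandwidth`,
#'   `low_confidence` (logical per grid point).
#' @export
estimate_sd_profile <- function(points, model, bandwidth = 2, grid_step = 0.5) {
  x <- as.numeric(points$age)
  r <- as.numeric(points$value) - eval_curve(model, x)
  lo <- floor(min(x) / grid_step) * grid_step
  hi <- ceiling(max(x) / grid_step) * grid_step
  ages <- seq(lo, hi, by = grid_step)
  sd_vals <- numeric(length(ages))
  n_eff <- numeric(length(ages))
  for (i in seq_along(ages)) {
    w <- exp(-0.5 * ((x - ages[i]) / bandwidth)^2)
    sw <- sum(w)
    sd_vals[i] <- sqrt(sum(w * r^2) / sw)
    n_eff[i] <- sw
  }
  structure(
    list(ages = ages, sd = sd_vals, bandwidth = bandwidth,
         low_confidence = n_eff < 3),
    class = "sd_profile"
  )
}

#' @export
print.sd_profile <- function(x, ...) {
  cat("<sd_profile>", length(x$ages), "grid points over ages",
      sprintf("[%.1f, %.1f], bandwidth %.1f y, SD %.2f-%.2f mm\n",
              min(x$ages), max(x$ages), x$bandwidth, min(x$sd), max(x$sd)))
  invisible(x)
}

# SD at arbitrary ages by linear interpolation on the profile grid
# (constant beyond the grid ends).
sd_at <- function(profile, age) {
  stats::approx(profile$ages, profile$sd, xout = age, rule = 2)$y
}

#' Bootstrap confidence band for the regressed mean curve
#'
#' Nonparametric bootstrap over subjects: resample the (age, value) points
#' with replacement, refit the given family, and evaluate the refitted curve
#' on the grid. At each grid age the 95% band is the percentile interval of
#' the bootstrap curve values and the reported half-width is half the
#' distance between the 2.5th and 97.5th percentiles.
#'
#' @param points data.frame with `age` and `value`.
#' @param family Growth-model family to refit in each replicate.
#' @param level Confidence level (default 0.95).
#' @param B Number of bootstrap replicates (>= 100).
#' @param ages Evaluation grid; default a 0.5-year grid over the sampled range.
#' @return A `ci_band`: list with `ages`, `lower`, `upper`, `halfwidth`,
#'   `level`, `B`.
#' @export
estimate_ci <- function(points, family, level = 0.95, B = 500, ages = NULL) {
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  x <- as.numeric(points$age)
  y <- as.numeric(points$value)
  n <- length(y)
  if (is.null(ages)) {
    ages <- seq(floor(min(x) * 2) / 2, ceiling(max(x) * 2) / 2, by = 0.5)
  }
  curves <- matrix(NA_real_, nrow = B, ncol = length(ages))
  failures <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- tryCatch(
      fit_curve(list(age = x[idx], value = y[idx]), family),
      error = function(e) NULL
    )
    if (is.null(fit)) failures <- failures + 1L
    else curves[b, ] <- eval_curve(fit, ages)
  }
  if (failures > 0.10 * B) {
    stop(sprintf("bootstrap refits failed in %d/%d replicates", failures, B),
         call. = FALSE)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(curves[!is.na(curves[, 1L]), , drop = FALSE], 2,
              stats::quantile, probs = probs, names = FALSE)
  structure(
    list(ages = ages, lower = qs[1L, ], upper = qs[2L, ],
         halfwidth = (qs[2L, ] - qs[1L, ]) / 2, level = level, B = B),
    class = "ci_band"
  )
}

#' @export
print.ci_band <- function(x, ...) {
  cat(sprintf("<ci_band> %.0f%% bootstrap band (B=%d), half-width %.3g-%.3g mm\n",
              100 * x$level, x$B, min(x$halfwidth), max(x$halfwidth)))
  invisible(x)
}
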