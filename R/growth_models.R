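#' Growth-curve model families
#'
#' Five candidate functional forms for measurement-vs-age regression:
#' \describe{
#'   \item{expdecay}{`y = a * (c - exp(1 - b*x))`, a three-parameter
#'     exponential-decay form that rises steeply through early childhood and
#'     plateaus at `a*c` in adulthood.}
#'   \item{linear}{`y = a*x + b`}
#'   \item{quadratic}{`y = a*x^2 + b*x + c`}
#'   \item{cubic}{`y = a*x^3 + b*x^2 + c*x + d`}
#'   \item{quartic}{`y = a*x^4 + b*x^3 + c*x^2 + d*x + e`}
#' }
#' Coefficients are always named `a` (highest order) downwards.
#'
#' @name growth_families
NULL

FAMILIES <- c("expdecay", "linear", "quadratic", "cubic", "quartic")

n_coefficients <- function(family) {
  c(expdecay = 3L, linear = 2L, quadratic = 3L, cubic = 4L, quartic = 5L)[[family]]
}

new_growth_model <- function(family, coefficients, rss, n_points) {
  stopifnot(family %in% FAMILIES,
            length(coefficients) == n_coefficients(family))
  structure(
    list(family = family, coefficients = coefficients,
         rss = as.numeric(rss), n_points = as.integer(n_points)),
    class = "growth_model"
  )
}

#' @export
print.growth_model <- function(x, ...) {
  cat("<growth_model>", x$family, "|",
      paste(names(x$coefficients),
            signif(x$coefficients, 5), sep = "=", collapse = " "),
      sprintf("| rss=%.4g n=%d\n", x$rss, x$n_points))
  invisible(x)
}

#' Evaluate a fitted growth model at given ages
#'
#' @param model A `growth_model` (see [fit_curve()]).
#' @param age Numeric vector of ages in decimal years (>= 0).
#' @return Numeric vector of modelled mean values.
#' @export
eval_curve <- function(model, age) {
  cf <- model$coefficients
  if (!all(is.finite(cf))) stop("non-finite model coefficients", call. = FALSE)
  switch(model$family,
    expdecay = cf[["a"]] * (cf[["c"]] - exp(1 - cf[["b"]] * age)),
    linear = cf[["a"]] * age + cf[["b"]],
    quadratic = cf[["a"]] * age^2 + cf[["b"]] * age + cf[["c"]],
    cubic = cf[["a"]] * age^3 + cf[["b"]] * age^2 + cf[["c"]] * age + cf[["d"]],
    quartic = cf[["a"]] * age^4 + cf[["b"]] * age^3 + cf[["c"]] * age^2 +
      cf[["d"]] * age + cf[["e"]]
  )
}

fit_polynomial <- function(x, y, degree) {
  X <- stats::poly(x, degree, raw = TRUE)  # columns x, x^2, ...
  fit <- stats::lm.fit(cbind(X[, degree:1, drop = FALSE], 1), y)
  cf <- unname(fit$coefficients)
  cf[is.na(cf)] <- 0
  names(cf) <- letters[seq_len(degree + 1L)]
  rss <- sum(fit$residuals^2)
  family <- c("linear", "quadratic", "cubic", "quartic")[degree]
  new_growth_model(family, cf, rss, length(y))
}

# Profiled RSS for the expdecay form. For fixed b the model is linear in
# (P, Q) with y = P + Q * exp(1 - b*x), where P = a*c and Q = -a; the 1-D
# profile over b is searched on a log-spaced grid and refined by optimize().
expdecay_profile <- function(x, y, b) {
  e <- exp(1 - b * x)
  n <- length(y)
  se <- sum(e); see <- sum(e * e); sy <- sum(y); sey <- sum(e * y)
  denom <- n * see - se * se
  if (abs(denom) < 1e-12 * max(1, n * see)) {
    return(list(rss = Inf, P = NA_real_, Q = NA_real_))
  }
  Q <- (n * sey - se * sy) / denom
  P <- (sy - Q * se) / n
  list(rss = sum((y - P - Q * e)^2), P = P, Q = Q)
}

fit_expdecay <- function(x, y, b_grid = exp(seq(log(0.02), log(2.5), length.out = 30L))) {
  prof <- vapply(b_grid, function(b) expdecay_profile(x, y, b)$rss, numeric(1))
  if (!any(is.finite(prof))) {
    stop("expdecay fit failed: profile degenerate for all rate values",
         call. = FALSE)
  }
  i <- which.min(prof)
  lo <- b_grid[max(1L, i - 1L)]
  hi <- b_grid[min(length(b_grid), i + 1L)]
  b <- if (lo < hi) {
    stats::optimize(function(b) expdecay_profile(x, y, b)$rss,
                    interval = c(lo, hi), tol = 1e-10)$minimum
  } else {
    b_grid[i]
  }
  sol <- expdecay_profile(x, y, b)
  a <- -sol$Q
  if (!is.finite(a) || abs(a) < 1e-12) {
    stop("expdecay fit failed: degenerate amplitude", call. = FALSE)
  }
  cf <- c(a = a, b = b, c = sol$P / a)
  new_growth_model("expdecay", cf, sol$rss, length(y))
}

#' Fit one growth-curve family by least squares
#'
#' Polynomial families are solved in closed form (QR). The exponential-decay
#' family is fitted by profiled least squares: for every candidate rate `b`
#' the remaining two parameters have a closed-form solution, so a log-spaced
#' grid over `b` (the multi-start) followed by 1-D refinement finds the
#' least-squares optimum robustly without derivative-based iteration.
#'
#' @param points data.frame (or list) with numeric `age` and `value`.
#' @param family One of `"expdecay"`, `"linear"`, `"quadratic"`, `"cubic"`,
#'   `"quartic"`.
#' @return A `growth_model` with fields `family`, `coefficients`, `rss`
#'   (achieved residual sum of squares) and `n_points`.
#' @export
fit_curve <- function(points, family) {
  family <- match.arg(family, FAMILIES)
  x <- as.numeric(points$age)
  y <- as.numeric(points$value)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  k <- n_coefficients(family)
  if (length(y) < k) {  # exact interpolation is the lower limit
    stop(sprintf("fitting %s needs at least %d points, got %d",
                 family, k, length(y)), call. = FALSE)
  }
  if (family == "expdecay") fit_expdecay(x, y)
  else fit_polynomial(x, y, k - 1L)
}

model_aicc <- function(model) {
  n <- model$n_points
  k <- n_coefficients(model$family) + 1L  # + residual variance
  if (n <= k + 1L) return(Inf)
  n * log(max(model$rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Select the best-fitting growth-curve family
#'
#' Fits all candidate families and returns the winner. Criterion `"rss"` is
#' the literal minimum residual sum of squares with ties (within a small
#' numerical tolerance) broken towards the family with fewest coefficients.
#' Criterion `"aicc"` uses the small-sample corrected AIC, which penalizes
#' the extra polynomial coefficients and so can prefer the three-parameter
#' exponential-decay form over a nested quartic.
#'
#' @param points data.frame with `age` and `value`.
#' @param families Character vector of families to consider (default all five).
#' @param criterion `"rss"` or `"aicc"`.
#' @return The winning `growth_model`.
#' @export
select_model <- function(points, families = FAMILIES,
                         criterion = c("rss", "aicc")) {
  criterion <- match.arg(criterion)
  fits <- list()
  for (f in families) {
    fit <- tryCatch(fit_curve(points, f), error = function(e) NULL)
    if (!is.null(fit)) fits[[f]] <- fit
  }
  if (length(fits) == 0L) stop("all candidate family fits failed", call. = FALSE)
  if (criterion == "rss") {
    rss <- vapply(fits, `[[`, numeric(1), "rss")
    tol <- 1e-8 * (1 + min(rss))
    tied <- rss <= min(rss) + tol
    kc <- vapply(names(fits), n_coefficients, integer(1))
    winner <- names(fits)[tied][which.min(kc[tied])]
  } else {
    score <- vapply(fits, model_aicc, numeric(1))
    winner <- names(fits)[which.min(score)]
  }
  fits[[winner]]
}

#' Per-band sample size for a normative reference
#'
#' Normal-approximation sample size for detecting a mean shift of
#' `effect_sd` standard deviations in a one-sample comparison:
#' `n_usable = ceiling(((z_alpha + z_power) / effect_sd)^2)`, with
#' `z_alpha = qnorm(1 - alpha)` one-sided or `qnorm(1 - alpha/2)` two-sided.
#' The recruited size inflates the usable size by the assumed fall-out
#' (image rejection) rate: `ceiling(n_usable / (1 - fallout))`. With the
#' defaults (half-SD effect, 5% significance one-sided, 80% power, 15%
#' fall-out) this gives 30 recruited individuals per age/sex band.
#'
#' @param effect_sd Detectable effect in SD units (> 0).
#' @param alpha Significance level.
#' @param power Target power.
#' @param sided `"one"` or `"two"`.
#' @param fallout Assumed fall-out/rejection rate in `[0, 1)`.
#' @return Integer recruited sample size per band.
#' @export
required_sample_size <- function(effect_sd = 0.5, alpha = 0.05, power = 0.80,
                                 sided = c("one", "two"), fallout = 0.15) {
  sided <- match.arg(sided)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (!(power > 0 && power < 1)) stop("power must be in (0,1)", call. = FALSE)
  if (!(fallout >= 0 && fallout < 1)) stop("fallout must be in [0,1)", call. = FALSE)
  if (effect_sd <= 0) stop("effect_sd must be positive", call. = FALSE)
  z_a <- if (sided == "one") stats::qnorm(1 - alpha) else stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  usable <- ceiling(((z_a + z_b) / effect_sd)^2)
  as.integer(ceiling(usable / (1 - fallout)))
}
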