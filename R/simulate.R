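#' Exact exponential-decay curve through three equally spaced anchors
#'
#' For anchor ages x1 < x2 < x3 with x2 - x1 = x3 - x2 = h, the form
#' `y = a*(c - exp(1 - b*x))` interpolates (x1,y1), (x2,y2), (x3,y3) in
#' closed form: with D1 = y2 - y1 and D2 = y3 - y2, `t = exp(-b*h) = D2/D1`,
#' so `b = -log(D2/D1)/h` and the remaining two parameters solve linearly.
#' Used to build generating curves that hit printed anchor values exactly.
#'
#' @param values Numeric length-3 anchor values.
#' @param ages Numeric length-3 equally spaced anchor ages (default 5, 10, 15).
#' @return A `growth_model` of family `"expdecay"` (rss 0, n_points 3).
#' @export
expdecay_through <- function(values, ages = c(5, 10, 15)) {
  stopifnot(length(values) == 3L, length(ages) == 3L)
  h <- diff(ages)
  if (abs(h[1L] - h[2L]) > 1e-9) stop("anchor ages must be equally spaced", call. = FALSE)
  d1 <- values[2L] - values[1L]
  d2 <- values[3L] - values[2L]
  t <- d2 / d1
  if (!is.finite(t) || t <= 0 || t >= 1) {
    stop("anchors must have decelerating same-sign increments", call. = FALSE)
  }
  b <- -log(t) / h[1L]
  e1 <- exp(1 - b * ages[1L])
  Q <- d1 / (e1 * (t - 1))
  P <- values[1L] - Q * e1
  a <- -Q
  new_growth_model("expdecay", c(a = a, b = b, c = P / a), rss = 0, n_points = 3L)
}

# Anchor tables for the shipped ancestry presets (mm at ages 5/10/15).
# Female values are standard interlandmark magnitudes; where the reference
# publication prints an anchor (bizygomatic sex gap 3.5/5.2/7.2 mm, PFL sex
# gap ~1 mm, bizygomatic SDs), the male anchors are female + that gap.
chinese_anchor_table <- function() {
  list(
    palpebral_fissure_length = list(F = c(24.3, 26.2, 27.3),
                                    M = c(24.3, 26.2, 27.3) + 1),
    innercanthal_width = list(F = c(30.8, 32.0, 32.7),
                              M = c(31.6, 32.8, 33.5)),
    bizygomatic_width = list(F = c(109.9, 118.4, 122.4),
                             M = c(109.9, 118.4, 122.4) + c(3.5, 5.2, 7.2)),
    nasal_protrusion = list(F = c(13.5, 15.0, 16.0),
                            M = c(13.8, 15.6, 16.9)),
    nasal_bridge_length = list(F = c(36.0, 40.0, 42.7),
                               M = c(37.0, 41.5, 44.5)),
    facial_height = list(F = c(97.0, 105.0, 110.0),
                         M = c(98.5, 108.0, 114.5)),
    labial_fissure_width = list(F = c(38.0, 42.0, 44.6),
                                M = c(39.0, 43.5, 46.5)),
    philtral_length = list(F = c(11.5, 12.5, 13.2),
                           M = c(12.0, 13.2, 14.0))
  )
}

# European-style offsets added to the Chinese anchors (mm): negative where
# the Chinese cohort is larger (bizygomatic), positive where smaller (PFL,
# nasal protrusion/bridge, innercanthal), zero where the groups coincide
# (facial height, labial fissure). Philtral length gets its own anchors:
# similar magnitude but a different growth rate.
european_anchor_table <- function(offsets = NULL) {
  off <- list(palpebral_fissure_length = 2.5, innercanthal_width = 3.5,
              bizygomatic_width = -8.0, nasal_protrusion = 3.5,
              nasal_bridge_length = 4.5, facial_height = 0,
              labial_fissure_width = 0)
  if (!is.null(offsets)) off[names(offsets)] <- offsets
  tab <- chinese_anchor_table()
  for (m in names(off)) {
    tab[[m]]$F <- tab[[m]]$F + off[[m]]
    tab[[m]]$M <- tab[[m]]$M + off[[m]]
  }
  tab$philtral_length <- list(F = c(12.4, 12.9, 13.1), M = c(13.0, 13.6, 13.9))
  tab
}

preset_sd_table <- function() {
  list(
    palpebral_fissure_length = 1.4,
    innercanthal_width = 2.2,
    bizygomatic_width = list(F = list(ages = c(5, 10, 15), values = c(6.8, 6.6, 6.7)),
                             M = list(ages = c(5, 10, 15), values = c(7.4, 7.2, 7.6))),
    nasal_protrusion = 2.0,
    nasal_bridge_length = 3.0,
    facial_height = 6.0,
    labial_fissure_width = 3.2,
    philtral_length = 1.8
  )
}

#' Construct a cohort specification from a named preset
#'
#' Presets encode the statistical structure the analysis assumes: per-sex
#' exponential-decay generating curves for the eight registry measurements
#' (built by [expdecay_through()] from anchor values at ages 5/10/15), per
#' measurement SD profiles (age-varying for bizygomatic width, constant
#' otherwise), a pediatric-heavy age mixture (86% uniform on 0-18, the rest
#' uniform on 18-55), balanced sexes, and small default outlier and fall-out
#' rates. `"european"` applies smooth cross-population offsets to the
#' `"chinese"` curves.
#'
#' @param preset `"chinese"` or `"european"`.
#' @param ... Overrides of top-level spec fields (e.g. `n = 50`, `seed = 7`,
#'   `outlier_rate = 0`).
#' @param european_offsets Optional named numeric vector overriding the
#'   European offset magnitudes (mm).
#' @return A `cohort_spec` with fields `ancestry`, `curves`
#'   (measurement -> sex -> `growth_model`), `sd` (measurement -> constant or
#'   age-anchored profile), `age_dist`, `p_male`, `n`, `outlier_rate`,
#'   `outlier_magnitude` (SD units), `fallout`, `seed`.
#' @export
make_cohort_spec <- function(preset = c("chinese", "european"), ...,
                             european_offsets = NULL) {
  preset <- tryCatch(match.arg(preset),
                     error = function(e) stop("unknown preset: ",
                                              preset[1L], call. = FALSE))
  anchors <- if (preset == "chinese") chinese_anchor_table()
             else european_anchor_table(european_offsets)
  curves <- lapply(anchors, function(a) {
    list(F = expdecay_through(a$F), M = expdecay_through(a$M))
  })
  spec <- structure(
    list(
      ancestry = preset,
      curves = curves,
      sd = preset_sd_table(),
      age_dist = list(w_child = 0.86, child_range = c(0, 18),
                      adult_range = c(18, 55)),
      p_male = 0.5,
      n = 760L,
      outlier_rate = 0.005,
      outlier_magnitude = 5,
      fallout = 0.02,
      seed = 1L
    ),
    class = "cohort_spec"
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(spec))
  if (length(bad) > 0) stop("unknown spec field(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  spec[names(overrides)] <- overrides
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  if (spec$n < 1) stop("n must be at least 1", call. = FALSE)
  if (spec$age_dist$w_child < 0 || spec$age_dist$w_child > 1) {
    stop("w_child must be in [0, 1]", call. = FALSE)
  }
  if (spec$outlier_rate < 0 || spec$outlier_rate >= 1 ||
      spec$fallout < 0 || spec$fallout >= 1) {
    stop("outlier_rate and fallout must be in [0, 1)", call. = FALSE)
  }
  for (m in names(spec$sd)) {
    s <- spec$sd[[m]]
    vals <- if (is.list(s)) unlist(lapply(s, `[[`, "values")) else s
    if (any(vals < 0)) stop("SDs must be non-negative (", m, ")", call. = FALSE)
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s: n=%d, %d measurements x 2 sexes, w_child=%.2f, seed=%d\n",
              x$ancestry, x$n, length(x$curves), x$age_dist$w_child, x$seed))
  invisible(x)
}

# generating SD at given ages (constant or linear interpolation of anchors,
# flat beyond the anchor range)
spec_sd_at <- function(spec, measurement, sex, age) {
  s <- spec$sd[[measurement]]
  if (!is.list(s)) return(rep(s, length(age)))
  prof <- if (!is.null(s$ages)) s else s[[sex]]
  stats::approx(prof$ages, prof$values, xout = age, rule = 2)$y
}

# generating mean curve
spec_mean <- function(spec, measurement, sex, age) {
  eval_curve(spec$curves[[measurement]][[sex]], age)
}

#' Simulate a measurement cohort
#'
#' Draws `spec$n` subjects: age from the pediatric-heavy mixture, sex
#' Bernoulli(`p_male`), and for each registry measurement
#' `value = curve(age, sex) + N(0, SD(age))`. Gross outliers are injected at
#' the configured rate by adding `+/- outlier_magnitude * SD(age)`, and
#' fall-out is applied by marking records unusable. Output is byte-identical
#' for identical spec and seed.
#'
#' @param spec A [make_cohort_spec()] specification.
#' @return Long data.frame with columns subject_id, age_years, sex, ancestry,
#'   measurement, value, units, usable.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  child <- stats::runif(n) < spec$age_dist$w_child
  age <- numeric(n)
  age[child] <- stats::runif(sum(child), spec$age_dist$child_range[1L],
                             spec$age_dist$child_range[2L])
  age[!child] <- stats::runif(sum(!child), spec$age_dist$adult_range[1L],
                              spec$age_dist$adult_range[2L])
  sex <- ifelse(stats::runif(n) < spec$p_male, "M", "F")
  ids <- sprintf("S%05d", seq_len(n))
  out <- vector("list", length(spec$curves))
  for (j in seq_along(spec$curves)) {
    m <- names(spec$curves)[j]
    sd_age <- ifelse(sex == "M",
                     spec_sd_at(spec, m, "M", age),
                     spec_sd_at(spec, m, "F", age))
    mu <- ifelse(sex == "M",
                 spec_mean(spec, m, "M", age),
                 spec_mean(spec, m, "F", age))
    value <- mu + stats::rnorm(n, 0, sd_age)
    is_out <- stats::runif(n) < spec$outlier_rate
    sign <- ifelse(stats::runif(n) < 0.5, -1, 1)
    value <- value + is_out * sign * spec$outlier_magnitude * sd_age
    usable <- stats::runif(n) >= spec$fallout
    out[[j]] <- data.frame(
      subject_id = ids, age_years = age, sex = sex, ancestry = spec$ancestry,
      measurement = m, value = value, units = "mm", usable = usable,
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, out)
  records <- records[order(records$subject_id, records$measurement), ]
  rownames(records) <- NULL
  records
}

# fractional positions (x as fraction of bizygomatic half-width, y/z as
# fractions of facial height) for template landmarks that are not anchored
# by one of the eight registry measurements
filler_bilateral_fractions <- function() {
  rbind(
    ps  = c(0.30, 0.00, 0.12), pi  = c(0.30, -0.06, 0.12),
    os  = c(0.30, 0.05, 0.11), or  = c(0.32, -0.10, 0.10),
    sci = c(0.30, 0.08, 0.11), ft  = c(0.55, 0.12, 0.02),
    t   = c(0.95, -0.25, -0.35), al = c(0.16, -0.38, 0.20),
    ac  = c(0.18, -0.36, 0.17), sbal = c(0.12, -0.41, 0.18),
    cph = c(0.06, -0.50, 0.22), go = c(0.70, -0.75, -0.25),
    sa  = c(0.98, -0.20, -0.40), sba = c(0.95, -0.35, -0.38),
    pra = c(0.93, -0.27, -0.36), obs = c(0.97, -0.15, -0.42),
    obi = c(0.96, -0.40, -0.40), mio = c(0.28, -0.14, 0.10),
    chk = c(0.45, -0.40, -0.02), mmb = c(0.40, -0.85, -0.10),
    lc  = c(0.25, -0.55, 0.10)
  )
}

#' Simulate a landmark set realizing drawn measurement values
#'
#' Positions a built-in symmetric template face (19 medial + 25 bilateral
#' landmarks, midline at x = 0) so that the eight registry measurements
#' computed from the landmarks equal the subject's drawn values exactly:
#' anchor landmarks (n, gn, prn, sn, ls, en, ex, zy, ch) are placed by
#' construction and the remaining landmarks are scaled anisotropically with
#' facial height and width. Optional placement noise perturbs every
#' coordinate independently.
#'
#' @param values Named numeric vector of the eight registry measurement
#'   values in mm (names as in [measurement_registry()]).
#' @param subject_id Identifier for the emitted [landmark_set()].
#' @param placement_noise_sd Gaussian coordinate noise in mm (default 0).
#' @param template The landmark template.
#' @return A `landmark_set`, or `NULL` (with a warning naming the subject)
#'   when the target combination is infeasible (any non-positive value), in
#'   which case the subject should be carried as a measurement table only.
#' @export
simulate_landmarks <- function(values, subject_id = "synthetic",
                               placement_noise_sd = 0,
                               template = default_template()) {
  need <- names(measurement_registry())
  if (!all(need %in% names(values))) {
    stop("values must cover all registry measurements", call. = FALSE)
  }
  v <- as.numeric(values[need])
  names(v) <- need
  if (any(!is.finite(v)) || any(v <= 0)) {
    warning("infeasible measurement targets for subject ", subject_id,
            "; emitting no landmarks", call. = FALSE)
    return(NULL)
  }
  fh <- v[["facial_height"]]
  theta <- 35 * pi / 180  # nasal dorsum inclination from vertical

  pts <- list()
  pts[["n"]] <- c(0, 0, 0)
  pts[["gn"]] <- c(0, -fh, 0)
  pts[["prn"]] <- c(0, -v[["nasal_bridge_length"]] * cos(theta),
                    v[["nasal_bridge_length"]] * sin(theta))
  phi <- 20 * pi / 180  # columella drop below the horizontal
  pts[["sn"]] <- pts[["prn"]] + v[["nasal_protrusion"]] * c(0, -sin(phi), -cos(phi))
  pts[["ls"]] <- pts[["sn"]] + c(0, -v[["philtral_length"]], 0)

  y_en <- -0.03 * fh; z_en <- 0.10 * fh
  half_icw <- v[["innercanthal_width"]] / 2
  pts[["en:R"]] <- c(half_icw, y_en, z_en)
  pts[["en:L"]] <- c(-half_icw, y_en, z_en)
  pts[["ex:R"]] <- c(half_icw + v[["palpebral_fissure_length"]], y_en, z_en)
  pts[["ex:L"]] <- c(-(half_icw + v[["palpebral_fissure_length"]]), y_en, z_en)
  pts[["zy:R"]] <- c(v[["bizygomatic_width"]] / 2, -0.15 * fh, -0.05 * fh)
  pts[["zy:L"]] <- c(-v[["bizygomatic_width"]] / 2, -0.15 * fh, -0.05 * fh)
  y_ch <- pts[["ls"]][2L] - 0.02 * fh
  pts[["ch:R"]] <- c(v[["labial_fissure_width"]] / 2, y_ch, 0.5 * pts[["sn"]][3L])
  pts[["ch:L"]] <- c(-v[["labial_fissure_width"]] / 2, y_ch, 0.5 * pts[["sn"]][3L])

  # remaining medial landmarks, proportional to facial height / nose anchors
  pts[["tr"]] <- c(0, 0.45 * fh, 0.02 * fh)
  pts[["fm"]] <- c(0, 0.30 * fh, 0.05 * fh)
  pts[["g"]] <- c(0, 0.08 * fh, 0.06 * fh)
  pts[["se"]] <- c(0, -0.04 * fh, 0.02 * fh)
  for (i in 1:3) {
    pts[[paste0("d", i)]] <- pts[["n"]] + (i / 4) * (pts[["prn"]] - pts[["n"]])
  }
  pts[["cm"]] <- (pts[["prn"]] + pts[["sn"]]) / 2
  pts[["mp"]] <- (pts[["sn"]] + pts[["ls"]]) / 2
  pts[["sto"]] <- pts[["ls"]] + c(0, -0.03 * fh, 0)
  pts[["li"]] <- pts[["ls"]] + c(0, -0.06 * fh, 0)
  pts[["sl"]] <- pts[["ls"]] + c(0, -0.09 * fh, -0.01 * fh)
  pts[["pg"]] <- c(0, -0.94 * fh, 0.02 * fh)
  pts[["me"]] <- c(0, -1.02 * fh, -0.02 * fh)

  half_w <- v[["bizygomatic_width"]] / 2
  fr <- filler_bilateral_fractions()
  for (code in rownames(fr)) {
    x <- fr[code, 1L] * half_w
    y <- fr[code, 2L] * fh
    z <- fr[code, 3L] * fh
    pts[[landmark_key(code, "R")]] <- c(x, y, z)
    pts[[landmark_key(code, "L")]] <- c(-x, y, z)
  }

  mat <- do.call(rbind, pts)
  if (placement_noise_sd > 0) {
    mat <- mat + matrix(stats::rnorm(length(mat), 0, placement_noise_sd),
                        nrow = nrow(mat))
  }
  landmark_set(subject_id, mat, template = template)
}
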