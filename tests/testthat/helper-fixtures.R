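# Shared fixtures, built in code at test time.

# typical adult-ish values for the eight registry measurements (mm)
typical_values <- function() {
  c(palpebral_fissure_length = 25, innercanthal_width = 31,
    bizygomatic_width = 115, nasal_protrusion = 15,
    nasal_bridge_length = 40, facial_height = 105,
    labial_fissure_width = 42, philtral_length = 12.5)
}

typical_face <- function(subject_id = "fixture") {
  simulate_landmarks(typical_values(), subject_id = subject_id)
}

# random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(lms, R, t = c(0, 0, 0)) {
  pts <- lms$points %*% t(R)
  pts <- sweep(pts, 2, -t)
  rownames(pts) <- rownames(lms$points)
  landmark_set(lms$subject_id, pts, excluded = lms$excluded,
               template = lms$template)
}

# hand-built reference curve with a constant SD, for assessment tests
flat_sd_reference <- function(measurement, sex, model, sd = 1,
                              ages = seq(0, 20, by = 0.5)) {
  structure(
    list(
      measurement = measurement, sex = sex, model = model,
      sd_profile = structure(
        list(ages = ages, sd = rep(sd, length(ages)), bandwidth = 2,
             low_confidence = rep(FALSE, length(ages))),
        class = "sd_profile"
      ),
      ci = NULL, age_range_sampled = range(ages),
      n_subjects = 100L, outliers_removed = 0L
    ),
    class = "reference_curve"
  )
}

linear_model <- function(a, b) {
  facenorms:::new_growth_model("linear", c(a = a, b = b), rss = 0, n_points = 10L)
}

# fitted reference sets from large preset cohorts, built once per test run
fitted_refsets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- reference_config(criterion = "aicc", B = 0)
      cache <<- list(
        chinese = fit_reference_set(
          simulate_cohort(make_cohort_spec("chinese", n = 3000, seed = 42)),
          ancestry = "chinese", config = cfg),
        european = fit_reference_set(
          simulate_cohort(make_cohort_spec("european", n = 3000, seed = 43)),
          ancestry = "european", config = cfg)
      )
    }
    cache
  }
})

# records for one subject sitting exactly on given reference means
subject_on_curves <- function(refset, subject_id = "probe", age = 8,
                              sex = "F", offset_sd = NULL) {
  keys <- names(refset$curves)
  keys <- keys[endsWith(keys, paste0("|", sex))]
  rows <- lapply(keys, function(k) {
    cv <- refset$curves[[k]]
    value <- eval_curve(cv$model, age)
    if (!is.null(offset_sd) && cv$measurement %in% names(offset_sd)) {
      value <- value + offset_sd[[cv$measurement]] * facenorms:::sd_at(cv$sd_profile, age)
    }
    data.frame(subject_id = subject_id, age_years = age, sex = sex,
               ancestry = refset$ancestry, measurement = cv$measurement,
               value = value, units = "mm", usable = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
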