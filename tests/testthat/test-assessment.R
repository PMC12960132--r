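test_that("z-scores follow the (value - mean)/SD definition with the display convention", {
  ref <- flat_sd_reference("bizygomatic_width", "F", linear_model(2, 100), sd = 5)
  rec <- function(v, age = 10) list(subject_id = "s", measurement = "bizygomatic_width",
                                    value = v, age_years = age, sex = "F")
  mean10 <- eval_curve(ref$model, 10)
  expect_equal(zscore(rec(mean10), ref)$z, 0)
  expect_equal(zscore(rec(mean10 + 2 * 5), ref)$z, 2)
  z <- zscore(rec(mean10 - 1.2 * 5), ref)
  expect_equal(z$z, -1.2)
  expect_identical(z$display, "-1.2")
  # halves round away from zero on display
  expect_identical(zscore(rec(mean10 - 1.15 * 5), ref)$display, "-1.2")
  expect_identical(zscore(rec(mean10 + 1.15 * 5), ref)$display, "1.2")

  expect_error(zscore(list(subject_id = "s", measurement = "bizygomatic_width",
                           value = 1, age_years = 10, sex = "M"), ref), "sex")
  expect_true(zscore(rec(mean10, age = 30), ref)$extrapolated)
  expect_false(zscore(rec(mean10, age = 10), ref)$extrapolated)
})

test_that("z is invariant under a common unit rescaling", {
  ref_mm <- flat_sd_reference("philtral_length", "M", linear_model(0.2, 10), sd = 1.5)
  ref_cm <- flat_sd_reference("philtral_length", "M", linear_model(0.02, 1), sd = 0.15)
  r_mm <- list(subject_id = "s", measurement = "philtral_length", value = 14,
               age_years = 8, sex = "M")
  r_cm <- r_mm; r_cm$value <- 1.4
  expect_equal(zscore(r_mm, ref_mm)$z, zscore(r_cm, ref_cm)$z, tolerance = 1e-12)
})

test_that("trait flagging is strict at the threshold and labels directions", {
  mk <- function(m, z) structure(list(measurement = m, value = 0, ref_mean = 0,
                                      ref_sd = 1, z = z, display = facenorms:::format_z(z),
                                      extrapolated = FALSE), class = "zscore_result")
  flags <- flag_traits(list(mk("palpebral_fissure_length", -2.5),
                            mk("facial_height", 1.9),
                            mk("bizygomatic_width", 2.0)))
  expect_identical(nrow(flags), 1L)
  expect_identical(flags$direction, "low")
  expect_identical(flags$label, "Short palpebral fissure")

  expect_identical(nrow(flag_traits(list(mk("facial_height", -2), mk("philtral_length", 1)))), 0L)
  # fallback label for measurements outside the shipped map
  f <- flag_traits(list(mk("ear_length", 3.1)))
  expect_identical(f$label, "increased ear length")
})

test_that("flag counts are monotone non-increasing in the threshold", {
  set.seed(5)
  mk <- function(m, z) structure(list(measurement = m, value = 0, ref_mean = 0,
                                      ref_sd = 1, z = z, display = "0",
                                      extrapolated = FALSE), class = "zscore_result")
  for (i in 1:10) {
    zs <- lapply(seq_len(8), function(j) mk(paste0("m", j), rnorm(1, 0, 1.8)))
    counts <- vapply(c(1.5, 2, 2.5, 3), function(th) nrow(flag_traits(zs, threshold = th)),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("subjects on the reference means are unflagged; constructed deviations flag once", {
  refs <- fitted_refsets()
  on_mean <- subject_on_curves(refs$chinese, age = 8, sex = "F")
  rep0 <- assess_subject(on_mean, refs$chinese)
  expect_identical(rep0$n_flags, 0L)
  expect_length(rep0$zscores, 8L)

  shifted <- subject_on_curves(refs$chinese, age = 8, sex = "F",
                               offset_sd = c(bizygomatic_width = 3))
  rep1 <- assess_subject(shifted, refs$chinese)
  expect_identical(rep1$n_flags, 1L)
  expect_identical(rep1$flags$measurement, "bizygomatic_width")
  expect_identical(rep1$flags$direction, "high")
})

test_that("measurements without a covering curve are reported as uncovered", {
  refs <- fitted_refsets()
  recs <- subject_on_curves(refs$chinese, age = 8, sex = "F")
  extra <- recs[1, ]
  extra$measurement <- "ear_length"
  extra$value <- 60
  rep <- assess_subject(rbind(recs, extra), refs$chinese)
  expect_identical(rep$uncovered, "ear_length")
  expect_length(rep$zscores, 8L)
})

test_that("reference comparison computes the printed medians and ranges", {
  counts <- data.frame(subject_id = as.character(1:4),
                       flags_a = c(3L, 9L, 5L, 6L), flags_b = c(0L, 1L, 1L, 3L))
  # medians of even-sized sets are midpoints of the central pair
  expect_equal(stats::median(counts$flags_a), 5.5)
  refs <- fitted_refsets()
  subj <- do.call(rbind, lapply(1:4, function(i) {
    s <- subject_on_curves(refs$chinese, subject_id = paste0("s", i),
                           age = 6 + i, sex = "M")
    s
  }))
  same <- compare_references(subj, refs$chinese, refs$chinese)
  expect_identical(same$median_before, same$median_after)
  expect_identical(same$counts$flags_a, same$counts$flags_b)
})

test_that("population-specific references reduce flagged traits for matched subjects", {
  refs <- fitted_refsets()
  improved <- 0L
  for (s in 1:10) {
    cohort <- simulate_cohort(make_cohort_spec("chinese", n = 8, seed = 600 + s,
                                               outlier_rate = 0, fallout = 0))
    cmp <- compare_references(cohort, refs$european, refs$chinese)
    if (cmp$median_after < cmp$median_before) improved <- improved + 1L
  }
  expect_gte(improved, 9L)
})
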