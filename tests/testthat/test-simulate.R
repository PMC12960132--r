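test_that("preset generating curves hit their printed anchors exactly", {
  sp <- make_cohort_spec("chinese")
  gap <- eval_curve(sp$curves$bizygomatic_width$M, c(5, 10, 15)) -
    eval_curve(sp$curves$bizygomatic_width$F, c(5, 10, 15))
  expect_equal(gap, c(3.5, 5.2, 7.2), tolerance = 1e-9)

  pfl_gap <- eval_curve(sp$curves$palpebral_fissure_length$M, seq(0, 40, by = 1)) -
    eval_curve(sp$curves$palpebral_fissure_length$F, seq(0, 40, by = 1))
  expect_true(all(abs(pfl_gap - 1) < 1e-9))

  expect_equal(facenorms:::spec_sd_at(sp, "bizygomatic_width", "F", c(5, 10, 15)),
               c(6.8, 6.6, 6.7))
  expect_equal(facenorms:::spec_sd_at(sp, "bizygomatic_width", "M", c(5, 10, 15)),
               c(7.4, 7.2, 7.6))
})

test_that("the european preset shifts curves in the documented directions", {
  cn <- make_cohort_spec("chinese")
  eu <- make_cohort_spec("european")
  ages <- c(5, 10, 15, 20)
  for (sex in c("F", "M")) {
    expect_true(all(eval_curve(cn$curves$bizygomatic_width[[sex]], ages) >
                      eval_curve(eu$curves$bizygomatic_width[[sex]], ages)))
    expect_true(all(eval_curve(cn$curves$palpebral_fissure_length[[sex]], ages) <
                      eval_curve(eu$curves$palpebral_fissure_length[[sex]], ages)))
    expect_equal(eval_curve(cn$curves$facial_height[[sex]], ages),
                 eval_curve(eu$curves$facial_height[[sex]], ages), tolerance = 1e-9)
  }
})

test_that("spec overrides apply and unknown presets or fields are refused", {
  sp <- make_cohort_spec("chinese", n = 50, seed = 9)
  expect_identical(sp$n, 50)
  expect_identical(sp$seed, 9)
  expect_identical(sp$ancestry, "chinese")
  expect_error(make_cohort_spec("martian"), "unknown preset")
  expect_error(make_cohort_spec("chinese", bogus = 1), "unknown spec field")
})

test_that("a noiseless spec lands every value exactly on its generating curve", {
  sd0 <- lapply(facenorms:::preset_sd_table(), function(s) 0)
  sp <- make_cohort_spec("chinese", n = 40, seed = 4, sd = sd0,
                         outlier_rate = 0, fallout = 0)
  rec <- simulate_cohort(sp)
  expected <- mapply(function(m, sex, age) {
    eval_curve(sp$curves[[m]][[sex]], age)
  }, rec$measurement, rec$sex, rec$age_years)
  expect_equal(rec$value, unname(expected), tolerance = 1e-12)
  expect_true(all(rec$usable))
})

test_that("simulation is byte-deterministic under a fixed seed", {
  a <- simulate_cohort(make_cohort_spec("chinese", n = 120, seed = 77))
  b <- simulate_cohort(make_cohort_spec("chinese", n = 120, seed = 77))
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_measurements(a, f1); write_measurements(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  c <- simulate_cohort(make_cohort_spec("chinese", n = 120, seed = 78))
  expect_false(identical(a$value, c$value))
})

test_that("fall-out marks the expected fraction unusable", {
  rec <- simulate_cohort(make_cohort_spec("chinese", n = 10000, seed = 2,
                                          fallout = 0.15))
  expect_gt(mean(rec$usable), 0.84)
  expect_lt(mean(rec$usable), 0.86)
})

test_that("simulated cohorts reproduce the preset dimorphism and noise level", {
  rec <- simulate_cohort(make_cohort_spec("chinese", n = 10000, seed = 1,
                                          outlier_rate = 0))
  band <- rec$measurement == "bizygomatic_width" &
    rec$age_years >= 9.5 & rec$age_years <= 10.5
  emp_gap <- mean(rec$value[band & rec$sex == "M"]) -
    mean(rec$value[band & rec$sex == "F"])
  expect_lt(abs(emp_gap - 5.2), 0.5)

  sp <- make_cohort_spec("chinese")
  for (sex in c("F", "M")) {
    i <- band & rec$sex == sex
    resid <- rec$value[i] - eval_curve(sp$curves$bizygomatic_width[[sex]],
                                       rec$age_years[i])
    target <- facenorms:::spec_sd_at(sp, "bizygomatic_width", sex, 10)
    expect_lt(abs(sd(resid) - target) / target, 0.05)
  }
})

test_that("simulated landmarks reproduce the drawn measurements through the measurement module", {
  vals <- typical_values()
  face <- simulate_landmarks(vals, "roundtrip")
  got <- measure_subject(face, metadata = list(age_years = 20, sex = "F"))
  expect_equal(stats::setNames(got$value, got$measurement), vals[got$measurement],
               tolerance = 1e-9)

  asym <- compute_measurement(face, measurement_definition("al_asym", "asymmetry", "al"))
  expect_lt(asym$value, 1e-9)

  expect_identical(nrow(face$points), 19L + 2L * 25L)
})

test_that("placement noise beyond the QC rule is caught", {
  truth <- typical_face()
  noisy_pts <- truth$points
  noisy_pts["zy:L", ] <- noisy_pts["zy:L", ] + c(6, 0, 0)
  expect_false(qc_landmarks(landmark_set("n", noisy_pts), truth)$pass)
})

test_that("infeasible measurement targets are reported, not fitted", {
  vals <- typical_values()
  vals["facial_height"] <- -1
  expect_warning(out <- simulate_landmarks(vals, "bad"), "infeasible")
  expect_null(out)
})
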