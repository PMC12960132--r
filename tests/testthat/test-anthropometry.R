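test_that("midsagittal plane recovers the symmetry plane and its translations", {
  face <- typical_face()
  plane <- fit_midsagittal_plane(face)
  expect_equal(abs(plane$normal), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(plane$point[[1]], 0, tolerance = 1e-9)

  shifted <- apply_rigid(face, diag(3), t = c(5, 0, 0))
  plane5 <- fit_midsagittal_plane(shifted)
  expect_equal(plane5$point[[1]], 5, tolerance = 1e-9)
  expect_equal(abs(plane5$normal), c(1, 0, 0), tolerance = 1e-9)
})

test_that("plane fit matches a brute-force least-squares oracle under noise", {
  set.seed(101)
  face <- typical_face()
  med <- intersect(face$template$medial_codes, rownames(face$points))
  pts <- face$points
  pts[med, 1] <- pts[med, 1] + rnorm(length(med), 0, 0.1)
  noisy <- landmark_set("noisy", pts)
  plane <- fit_midsagittal_plane(noisy)

  # oracle: direct minimization of summed squared point-plane distances
  # over the normal's spherical angles and offset
  obj <- function(p) {
    n <- c(cos(p[1]) * cos(p[2]), cos(p[1]) * sin(p[2]), sin(p[1]))
    sum((pts[med, , drop = FALSE] %*% n - p[3])^2)
  }
  opt <- optim(c(0, 0, 0), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  n_star <- c(cos(opt$par[1]) * cos(opt$par[2]),
              cos(opt$par[1]) * sin(opt$par[2]), sin(opt$par[1]))
  angle_to_oracle <- acos(min(1, abs(sum(plane$normal * n_star)))) * 180 / pi
  expect_lt(angle_to_oracle, 0.05)
  angle_to_x <- acos(min(1, abs(plane$normal[1]))) * 180 / pi
  expect_lt(angle_to_x, 1)
})

test_that("plane fit refuses degenerate medial configurations", {
  face <- typical_face()
  keep <- c("n", setdiff(rownames(face$points), face$template$medial_codes))
  two_medial <- landmark_set("bad", face$points[keep, ])
  expect_error(fit_midsagittal_plane(two_medial), "medial")
})

test_that("distance, bilateral averaging and asymmetry behave geometrically", {
  pts <- rbind("n" = c(0, 0, 0), "prn" = c(3, 4, 0), "se" = c(0, 1, 0),
               "g" = c(0, 2, 1))
  lms <- landmark_set("tri", pts)
  d <- compute_measurement(lms, measurement_definition("np", "distance", c("n", "prn")))
  expect_equal(d$value, 5)

  face <- typical_face()
  pfl <- compute_measurement(
    face, measurement_definition("pfl", "distance", c("ex", "en"), bilateral = TRUE))
  left <- compute_measurement(
    face, measurement_definition("pfl_l", "distance", c("ex:L", "en:L")))
  right <- compute_measurement(
    face, measurement_definition("pfl_r", "distance", c("ex:R", "en:R")))
  expect_equal(left$value, right$value)
  expect_equal(pfl$value, left$value)

  asym <- compute_measurement(
    face, measurement_definition("zy_asym", "asymmetry", "zy"))
  expect_lt(asym$value, 1e-9)
})

test_that("angle and depth measurement kinds evaluate correctly", {
  pts <- rbind("n" = c(0, 1, 0), "prn" = c(0, 0, 0), "sn" = c(0, 0, 1),
               "g" = c(0, 2, 0), "se" = c(0, 1.5, 0.2))
  lms <- landmark_set("angles", pts)
  ang <- compute_measurement(
    lms, measurement_definition("nasolabial", "angle", c("n", "prn", "sn")))
  expect_equal(ang$value, 90)
  expect_identical(ang$units, "degrees")

  face <- typical_face()
  plane <- fit_midsagittal_plane(face)
  dep <- compute_measurement(
    face, measurement_definition("zy_r_depth", "depth", "zy:R"), plane)
  # right-side landmark lies on the +x side of the midsagittal plane
  expect_gt(dep$value, 0)
  expect_equal(abs(dep$value), abs(face$points["zy:R", 1]), tolerance = 1e-9)
})

test_that("measurements are invariant under rigid motion", {
  set.seed(7)
  face <- typical_face()
  base <- measure_subject(face, metadata = list(age_years = 20, sex = "F"))
  for (i in 1:5) {
    moved <- apply_rigid(face, random_rotation(), t = rnorm(3, 0, 40))
    got <- measure_subject(moved, metadata = list(age_years = 20, sex = "F"))
    expect_equal(got$value, base$value, tolerance = 1e-8)
  }
})

test_that("excluded landmarks invalidate only dependent measurements", {
  face <- typical_face()
  base <- measure_subject(face, metadata = list(age_years = 20, sex = "F"))
  expect_equal(nrow(base), 8L)
  expect_true(all(base$usable))

  excl <- landmark_set(face$subject_id, face$points, excluded = "zy:L")
  got <- measure_subject(excl, metadata = list(age_years = 20, sex = "F"))
  expect_false(got$usable[got$measurement == "bizygomatic_width"])
  expect_true(is.na(got$value[got$measurement == "bizygomatic_width"]))
  others <- got$measurement != "bizygomatic_width"
  expect_true(all(got$usable[others]))
  expect_equal(got$value[others], base$value[others])
})

test_that("landmark QC fails strictly beyond 5 mm", {
  face <- typical_face()
  expect_true(qc_landmarks(face, face)$pass)

  off6 <- face$points
  off6["prn", ] <- off6["prn", ] + c(0, 0, 6)
  qc6 <- qc_landmarks(landmark_set("c", off6), face)
  expect_false(qc6$pass)
  expect_identical(qc6$discrepancies$key[qc6$discrepancies$flagged], "prn")

  off5 <- face$points
  off5["prn", ] <- off5["prn", ] + c(0, 0, 5)
  expect_true(qc_landmarks(landmark_set("c", off5), face)$pass)
})
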