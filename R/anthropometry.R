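#' Fit the midsagittal plane through the medial landmarks
#'
#' Least-squares plane through a subject's usable medial landmarks (total
#' least squares: the plane normal is the direction of least variance of the
#' centred medial coordinates). The normal is oriented towards the subject's
#' anatomical right (+x under the package's coordinate convention), so signed
#' point-to-plane distances are positive on the subject's right.
#'
#' @param landmarks A [landmark_set()].
#' @return A list with `point` (a point on the plane, the medial centroid) and
#'   `normal` (unit normal, oriented towards +x).
#' @export
fit_midsagittal_plane <- function(landmarks) {
  med <- intersect(landmarks$template$medial_codes, rownames(landmarks$points))
  med <- setdiff(med, landmarks$excluded)
  if (length(med) < 3L) {
    stop("midsagittal plane needs at least 3 usable medial landmarks",
         call. = FALSE)
  }
  pts <- landmarks$points[med, , drop = FALSE]
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  # collinear medial points leave the plane orientation undetermined
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1)) {
    stop("medial landmarks are collinear; midsagittal plane is undetermined",
         call. = FALSE)
  }
  normal <- sv$v[, 3L]
  if (normal[1L] < 0) normal <- -normal
  list(point = ctr, normal = normal / sqrt(sum(normal^2)))
}

mirror_across_plane <- function(p, plane) {
  d <- sum((p - plane$point) * plane$normal)
  p - 2 * d * plane$normal
}

#' Define a facial measurement
#'
#' @param name Measurement name.
#' @param kind One of `"distance"` (Euclidean distance between two landmarks),
#'   `"angle"` (interior angle at the middle of three landmarks, degrees),
#'   `"depth"` (signed distance of one landmark from a reference plane,
#'   default the midsagittal plane) or `"asymmetry"` (distance between the
#'   left landmark of a bilateral pair and the mirror image of its right
#'   counterpart across the midsagittal plane).
#' @param operands Landmark keys (`"code"` or `"code:L"`). For `bilateral`
#'   definitions give side-free codes; sides are appended per side and the two
#'   side values averaged. `asymmetry` takes a single side-free bilateral code.
#' @param bilateral Compute per side and average (distance/angle/depth only).
#' @param units `"mm"` or `"degrees"`.
#' @return A `measurement_definition`.
#' @export
measurement_definition <- function(name, kind, operands, bilateral = FALSE,
                                   units = if (kind == "angle") "degrees" else "mm") {
  kind <- match.arg(kind, c("distance", "angle", "depth", "asymmetry"))
  need <- c(distance = 2L, angle = 3L, depth = 1L, asymmetry = 1L)[[kind]]
  if (length(operands) != need) {
    stop(sprintf("%s measurement needs %d operand(s), got %d",
                 kind, need, length(operands)), call. = FALSE)
  }
  if (kind == "asymmetry" && grepl(":", operands)) {
    stop("asymmetry operand must be a side-free bilateral code", call. = FALSE)
  }
  structure(
    list(name = name, kind = kind, operands = operands,
         bilateral = isTRUE(bilateral), units = units),
    class = "measurement_definition"
  )
}

#' Default measurement registry
#'
#' The eight standard interlandmark measurements shipped with the package:
#' palpebral fissure length (ex-en, bilateral mean), innercanthal width
#' (enL-enR), bizygomatic width (zyL-zyR), nasal protrusion (sn-prn), nasal
#' bridge length (n-prn), facial height (n-gn), labial fissure width
#' (chL-chR) and philtral length (sn-ls). The registry is an ordinary list of
#' [measurement_definition()] objects and can be extended by the user.
#'
#' @return Named list of `measurement_definition`s.
#' @export
measurement_registry <- function() {
  defs <- list(
    measurement_definition("palpebral_fissure_length", "distance",
                           c("ex", "en"), bilateral = TRUE),
    measurement_definition("innercanthal_width", "distance", c("en:L", "en:R")),
    measurement_definition("bizygomatic_width", "distance", c("zy:L", "zy:R")),
    measurement_definition("nasal_protrusion", "distance", c("sn", "prn")),
    measurement_definition("nasal_bridge_length", "distance", c("n", "prn")),
    measurement_definition("facial_height", "distance", c("n", "gn")),
    measurement_definition("labial_fissure_width", "distance", c("ch:L", "ch:R")),
    measurement_definition("philtral_length", "distance", c("sn", "ls"))
  )
  stats::setNames(defs, vapply(defs, `[[`, character(1), "name"))
}

angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

eval_operands <- function(landmarks, keys) {
  pts <- lapply(keys, landmark_point, lms = landmarks)
  if (any(vapply(pts, is.null, logical(1)))) NULL else pts
}

measure_one_sided <- function(landmarks, defn, keys, plane) {
  pts <- eval_operands(landmarks, keys)
  if (is.null(pts)) return(NA_real_)
  switch(defn$kind,
    distance = sqrt(sum((pts[[1L]] - pts[[2L]])^2)),
    angle = angle_deg(pts[[1L]], pts[[2L]], pts[[3L]]),
    depth = sum((pts[[1L]] - plane$point) * plane$normal)
  )
}

#' Compute one measurement from a landmark set
#'
#' @param landmarks A [landmark_set()].
#' @param defn A [measurement_definition()].
#' @param plane Optional precomputed reference plane (defaults to the fitted
#'   midsagittal plane when the measurement kind needs one).
#' @return List with `value` (numeric, `NA` when unusable), `usable` flag and
#'   `units`. A missing or excluded operand landmark makes the measurement
#'   unusable rather than raising an error.
#' @export
compute_measurement <- function(landmarks, defn, plane = NULL) {
  stopifnot(inherits(defn, "measurement_definition"))
  needs_plane <- defn$kind %in% c("depth", "asymmetry")
  if (needs_plane && is.null(plane)) plane <- fit_midsagittal_plane(landmarks)

  if (defn$kind == "asymmetry") {
    kl <- landmark_key(defn$operands, "L")
    kr <- landmark_key(defn$operands, "R")
    pl <- landmark_point(landmarks, kl)
    pr <- landmark_point(landmarks, kr)
    value <- if (is.null(pl) || is.null(pr)) NA_real_ else
      sqrt(sum((pl - mirror_across_plane(pr, plane))^2))
  } else if (defn$bilateral) {
    vals <- vapply(c("L", "R"), function(s) {
      measure_one_sided(landmarks, defn, landmark_key(defn$operands, s), plane)
    }, numeric(1))
    value <- if (anyNA(vals)) NA_real_ else mean(vals)
  } else {
    value <- measure_one_sided(landmarks, defn, defn$operands, plane)
  }
  list(value = value, usable = !is.na(value), units = defn$units)
}

#' Measure a subject against a registry of measurement definitions
#'
#' Produces one record per definition. Landmarks marked excluded invalidate
#' only the measurements that reference them; all other measurements from the
#' same image remain usable.
#'
#' @param landmarks A [landmark_set()].
#' @param registry List of [measurement_definition()]s
#'   (default [measurement_registry()]).
#' @param metadata List or one-row data.frame with `age_years`, `sex`
#'   (`"M"`/`"F"`) and optionally `ancestry`.
#' @return A data.frame with columns subject_id, age_years, sex, ancestry,
#'   measurement, value, units, usable.
#' @export
measure_subject <- function(landmarks, registry = measurement_registry(),
                            metadata = list()) {
  if (length(registry) == 0L) stop("registry must be non-empty", call. = FALSE)
  needs_plane <- any(vapply(registry, function(d)
    d$kind %in% c("depth", "asymmetry"), logical(1)))
  plane <- if (needs_plane) fit_midsagittal_plane(landmarks) else NULL
  rows <- lapply(registry, function(d) {
    m <- compute_measurement(landmarks, d, plane)
    data.frame(
      subject_id = landmarks$subject_id,
      age_years = as.numeric(metadata$age_years %||% NA_real_),
      sex = as.character(metadata$sex %||% NA_character_),
      ancestry = as.character(metadata$ancestry %||% NA_character_),
      measurement = d$name,
      value = m$value,
      units = m$units,
      usable = m$usable,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Landmark placement quality control
#'
#' Compares candidate landmark placements against ground-truth placements on
#' the same template: per-landmark Euclidean discrepancies in mm, with overall
#' failure when any discrepancy strictly exceeds 5 mm (a discrepancy of
#' exactly 5 mm passes).
#'
#' @param candidate,ground_truth [landmark_set()]s on the same template.
#' @param threshold_mm Failure threshold (strict), default 5.
#' @return List with `discrepancies` (data.frame: key, discrepancy_mm,
#'   flagged) and `pass`.
#' @export
qc_landmarks <- function(candidate, ground_truth, threshold_mm = 5) {
  if (!identical(candidate$template, ground_truth$template)) {
    stop("candidate and ground truth use different templates", call. = FALSE)
  }
  keys <- intersect(rownames(candidate$points), rownames(ground_truth$points))
  d <- sqrt(rowSums((candidate$points[keys, , drop = FALSE] -
                       ground_truth$points[keys, , drop = FALSE])^2))
  flagged <- d > threshold_mm
  list(
    discrepancies = data.frame(key = keys, discrepancy_mm = unname(d),
                               flagged = unname(flagged),
                               stringsAsFactors = FALSE),
    pass = !any(flagged)
  )
}
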