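#' Default facial landmark template
#'
#' The landmark vocabulary the package works with: 19 medial landmarks on the
#' facial midline and 25 bilateral landmarks that occur in left/right pairs.
#' Medial codes include the classical Farkas points (tr trichion, g glabella,
#' n nasion, se sellion, prn pronasale, sn subnasale, ls labiale superius,
#' sto stomion, li labiale inferius, sl sublabiale, pg pogonion, gn gnathion,
#' me menton) plus midline auxiliary points on the nasal dorsum, philtrum and
#' forehead. Bilateral codes include en/ex (endo-/exocanthion), zy (zygion),
#' ch (cheilion), al (alare), go (gonion), t (tragion) and further periorbital,
#' auricular and contour points.
#'
#' @return An object of class `landmark_template` with fields `medial_codes`,
#'   `bilateral_codes`, `count_medial` and `count_bilateral`.
#' @export
default_template <- function() {
  medial <- c("tr", "g", "fm", "n", "se", "d1", "d2", "d3", "prn", "cm",
              "sn", "mp", "ls", "sto", "li", "sl", "pg", "gn", "me")
  bilateral <- c("en", "ex", "ps", "pi", "os", "or", "sci", "ft", "zy", "t",
                 "al", "ac", "sbal", "cph", "ch", "go", "sa", "sba", "pra",
                 "obs", "obi", "mio", "chk", "mmb", "lc")
  new_landmark_template(medial, bilateral)
}

new_landmark_template <- function(medial_codes, bilateral_codes) {
  if (anyDuplicated(c(medial_codes, bilateral_codes)) > 0) {
    stop("landmark codes must be unique across medial and bilateral sets",
         call. = FALSE)
  }
  structure(
    list(
      medial_codes = medial_codes,
      bilateral_codes = bilateral_codes,
      count_medial = length(medial_codes),
      count_bilateral = length(bilateral_codes)
    ),
    class = "landmark_template"
  )
}

#' @export
print.landmark_template <- function(x, ...) {
  cat("<landmark_template>", x$count_medial, "medial +",
      x$count_bilateral, "bilateral landmark codes\n")
  invisible(x)
}

# Canonical landmark key: "code" for medial, "code:L"/"code:R" for bilateral.
landmark_key <- function(code, side = "") {
  n <- max(length(code), length(side))
  code <- rep_len(code, n)
  side <- rep_len(side, n)
  ifelse(side == "" | is.na(side), code, paste(code, side, sep = ":"))
}

split_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  code <- vapply(parts, `[`, character(1), 1L)
  side <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "",
                 character(1))
  data.frame(code = code, side = side, stringsAsFactors = FALSE)
}

template_keys <- function(template) {
  c(template$medial_codes,
    landmark_key(rep(template$bilateral_codes, each = 2L), c("L", "R")))
}

#' Construct a landmark set
#'
#' A landmark set holds one subject's 3D landmark coordinates (in mm) keyed by
#' landmark code and side, plus the set of landmarks marked unusable (e.g.
#' occluded by hair or affected by surface-reconstruction artefacts). Excluded
#' landmarks stay in the table so their dependent measurements can be dropped
#' while all other measurements remain usable.
#'
#' @param subject_id Opaque subject identifier.
#' @param points Numeric matrix with three columns (x, y, z in mm) and row
#'   names giving landmark keys (`"code"` or `"code:L"`/`"code:R"`).
#'   Convention: +x is the subject's anatomical right, +y superior, +z anterior.
#' @param excluded Character vector of landmark keys marked unusable.
#' @param template A `landmark_template`; defaults to [default_template()].
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(subject_id, points, excluded = character(),
                         template = default_template()) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns (x, y, z)", call. = FALSE)
  if (is.null(rownames(points))) stop("points must have landmark-key rownames", call. = FALSE)
  if (!all(is.finite(points))) stop("landmark coordinates must be finite", call. = FALSE)
  keys <- template_keys(template)
  bad <- setdiff(rownames(points), keys)
  if (length(bad) > 0) {
    stop("landmark keys not in template: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(points)) > 0) {
    stop("duplicate landmark keys", call. = FALSE)
  }
  bad_ex <- setdiff(excluded, keys)
  if (length(bad_ex) > 0) {
    stop("excluded keys not in template: ", paste(bad_ex, collapse = ", "),
         call. = FALSE)
  }
  colnames(points) <- c("x", "y", "z")
  structure(
    list(subject_id = as.character(subject_id), points = points,
         excluded = unique(as.character(excluded)), template = template),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>", x$subject_id, "-", nrow(x$points), "landmarks",
      if (length(x$excluded)) paste0("(", length(x$excluded), " excluded)") else "",
      "\n")
  invisible(x)
}

# Usable coordinates of a landmark key, or NULL if absent/excluded.
landmark_point <- function(lms, key) {
  if (key %in% lms$excluded) return(NULL)
  if (!key %in% rownames(lms$points)) return(NULL)
  lms$points[key, ]
}
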