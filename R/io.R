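#' Read landmark coordinate tables
#'
#' Landmark CSV dialect: one row per landmark with header
#' `subject_id,code,side,x_mm,y_mm,z_mm,excluded` (side empty for medial
#' landmarks, `L`/`R` for bilateral; excluded 0/1). UTF-8, decimal point.
#' Malformed rows (non-numeric coordinates) are collected into an error
#' naming their line numbers.
#'
#' @param path CSV file path.
#' @param template Landmark template the sets must conform to.
#' @return Named list of [landmark_set()]s, one per subject_id.
#' @export
read_landmarks <- function(path, template = default_template()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  need <- c("subject_id", "code", "side", "x_mm", "y_mm", "z_mm", "excluded")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("landmark file missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  coords <- suppressWarnings(cbind(as.numeric(raw$x_mm), as.numeric(raw$y_mm),
                                   as.numeric(raw$z_mm)))
  bad <- which(rowSums(is.na(coords)) > 0)
  if (length(bad) > 0) {
    stop("non-numeric coordinates on line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)  # +1 for header
  }
  keys <- landmark_key(raw$code, raw$side)
  dup <- duplicated(paste(raw$subject_id, keys))
  if (any(dup)) {
    stop("duplicate (subject, code, side) on line(s): ",
         paste(which(dup) + 1L, collapse = ", "), call. = FALSE)
  }
  sets <- list()
  for (id in unique(raw$subject_id)) {
    i <- raw$subject_id == id
    mat <- coords[i, , drop = FALSE]
    rownames(mat) <- keys[i]
    excl <- keys[i][raw$excluded[i] %in% c("1", "TRUE", "true")]
    sets[[id]] <- landmark_set(id, mat, excluded = excl, template = template)
  }
  sets
}

#' Write landmark sets to the landmark CSV dialect
#'
#' @param sets A `landmark_set` or list of them.
#' @param path Output CSV path.
#' @export
write_landmarks <- function(sets, path) {
  if (inherits(sets, "landmark_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    ks <- split_key(rownames(s$points))
    data.frame(subject_id = s$subject_id, code = ks$code, side = ks$side,
               x_mm = s$points[, 1L], y_mm = s$points[, 2L],
               z_mm = s$points[, 3L],
               excluded = as.integer(rownames(s$points) %in% s$excluded),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write measurement tables
#'
#' Measurement TSV dialect: `subject_id, age_years, sex, ancestry,
#' measurement, value, units, usable`; ages written with 3 decimals.
#'
#' @param records Long measurement data.frame.
#' @param path TSV path.
#' @return `read_measurements` returns the data.frame with proper column
#'   types; `write_measurements` returns the path invisibly.
#' @export
write_measurements <- function(records, path) {
  out <- records
  out$age_years <- sprintf("%.3f", out$age_years)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # sex must stay character: a column of all "F" would otherwise be
  # type-inferred as logical FALSE
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8",
                           colClasses = c(subject_id = "character",
                                          sex = "character"))
  need <- c("subject_id", "age_years", "sex", "measurement", "value", "usable")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("measurement file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$subject_id <- as.character(tab$subject_id)
  tab$age_years <- as.numeric(tab$age_years)
  tab$value <- as.numeric(tab$value)
  tab$usable <- as.logical(tab$usable)
  tab
}

REFERENCE_SCHEMA_VERSION <- "1.0"

#' Serialize / deserialize a reference set as JSON
#'
#' The portable statistics document: ancestry, per-curve family +
#' coefficients + SD grid + confidence-band grid + sample sizes + sampled age
#' range, plus provenance (creation date, pipeline version, config hash) and
#' a schema version that is checked on read. Numeric values round-trip to
#' full double precision.
#'
#' @param refset A `reference_set`.
#' @param path JSON file path.
#' @return `read_reference` returns the `reference_set`.
#' @export
write_reference <- function(refset, path) {
  doc <- list(
    schema_version = REFERENCE_SCHEMA_VERSION,
    ancestry = refset$ancestry,
    provenance = refset$provenance,
    curves = lapply(refset$curves, function(cv) {
      list(
        measurement = cv$measurement,
        sex = cv$sex,
        model = list(family = cv$model$family,
                     coefficients = as.list(cv$model$coefficients),
                     rss = cv$model$rss, n_points = cv$model$n_points),
        sd_profile = list(ages = cv$sd_profile$ages, sd = cv$sd_profile$sd,
                          bandwidth = cv$sd_profile$bandwidth,
                          low_confidence = cv$sd_profile$low_confidence),
        ci = if (is.null(cv$ci)) NULL else
          list(ages = cv$ci$ages, lower = cv$ci$lower, upper = cv$ci$upper,
               halfwidth = cv$ci$halfwidth, level = cv$ci$level, B = cv$ci$B),
        age_range_sampled = cv$age_range_sampled,
        n_subjects = cv$n_subjects,
        outliers_removed = cv$outliers_removed
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(doc$schema_version) ||
      !identical(doc$schema_version, REFERENCE_SCHEMA_VERSION)) {
    stop(sprintf("incompatible reference schema version %s (expected %s)",
                 doc$schema_version %||% "<missing>",
                 REFERENCE_SCHEMA_VERSION), call. = FALSE)
  }
  curves <- lapply(doc$curves, function(cv) {
    if (is.null(cv$sd_profile) || is.null(cv$sd_profile$sd)) {
      stop("reference file is incompatible: curve ", cv$measurement,
           " has no SD grid", call. = FALSE)
    }
    model <- new_growth_model(cv$model$family, unlist(cv$model$coefficients),
                              cv$model$rss, cv$model$n_points)
    prof <- structure(
      list(ages = as.numeric(cv$sd_profile$ages),
           sd = as.numeric(cv$sd_profile$sd),
           bandwidth = cv$sd_profile$bandwidth,
           low_confidence = as.logical(cv$sd_profile$low_confidence)),
      class = "sd_profile"
    )
    ci <- if (is.null(cv$ci)) NULL else structure(
      list(ages = as.numeric(cv$ci$ages), lower = as.numeric(cv$ci$lower),
           upper = as.numeric(cv$ci$upper),
           halfwidth = as.numeric(cv$ci$halfwidth),
           level = cv$ci$level, B = cv$ci$B),
      class = "ci_band"
    )
    structure(
      list(measurement = cv$measurement, sex = cv$sex, model = model,
           sd_profile = prof, ci = ci,
           age_range_sampled = as.numeric(cv$age_range_sampled),
           n_subjects = cv$n_subjects,
           outliers_removed = cv$outliers_removed),
      class = "reference_curve"
    )
  })
  out <- structure(
    list(ancestry = doc$ancestry, curves = curves,
         provenance = doc$provenance),
    class = "reference_set"
  )
  out
}

#' Read / write run configuration as YAML
#'
#' @param path YAML file path.
#' @param config List of settings (see [reference_config()]; a `seed` field
#'   is carried through as well).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Genetic-ancestry distribution of the source cohort
#'
#' The printed ancestry-by-count distribution of the 1,218 recruited
#' participants, shipped as plain text. Counts sum to 1,218 and the largest
#' group (Chinese, 879) accounts for 72.2%.
#'
#' @return data.frame with columns `ancestry` and `count`.
#' @export
ancestry_distribution <- function() {
  path <- system.file("extdata", "ancestry_counts.tsv", package = "facenorms")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
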