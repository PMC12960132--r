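#' Z-score of one measurement record against a reference curve
#'
#' `z = (value - mean(age)) / SD(age)`, where the mean comes from the fitted
#' growth curve and the SD is linearly interpolated on the reference SD grid.
#' Ages outside the sampled range of the reference still yield a score but
#' carry an extrapolation flag.
#'
#' @param record One measurement record (list or one-row data.frame with
#'   `value`, `age_years`, `sex`, `measurement`).
#' @param ref A `reference_curve` of matching sex.
#' @return A `zscore_result`: measurement, value, ref_mean, ref_sd, z,
#'   `display` (one-decimal string, halves rounded away from zero, matching
#'   the on-screen convention), extrapolated flag.
#' @export
zscore <- function(record, ref) {
  if (!identical(as.character(record$sex), ref$sex)) {
    stop(sprintf("record sex %s does not match reference sex %s",
                 record$sex, ref$sex), call. = FALSE)
  }
  age <- as.numeric(record$age_years)
  mu <- eval_curve(ref$model, age)
  s <- sd_at(ref$sd_profile, age)
  if (!is.finite(s) || s <= 0) {
    stop("reference SD is zero at this age; Z-score undefined", call. = FALSE)
  }
  z <- (as.numeric(record$value) - mu) / s
  structure(
    list(measurement = record$measurement, value = as.numeric(record$value),
         ref_mean = mu, ref_sd = s, z = z, display = format_z(z),
         extrapolated = age < ref$age_range_sampled[1L] ||
           age > ref$age_range_sampled[2L]),
    class = "zscore_result"
  )
}

# one-decimal display, halves rounded away from zero (e.g. -1.15 -> "-1.2")
format_z <- function(z) {
  sprintf("%.1f", sign(z) * floor(abs(z) * 10 + 0.5) / 10)
}

#' Illustrative trait-label map
#'
#' Maps (measurement, direction) to a human-readable phenotype-style label.
#' This table is illustrative and editable; it is not the official Human
#' Phenotype Ontology. Measurements without an entry fall back to
#' "decreased/increased <measurement>".
#'
#' @return data.frame with columns measurement, direction, label.
#' @export
default_term_map <- function() {
  lab <- function(m, low, high) {
    data.frame(measurement = m, direction = c("low", "high"),
               label = c(low, high), stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    lab("palpebral_fissure_length", "Short palpebral fissure", "Long palpebral fissure"),
    lab("innercanthal_width", "Decreased innercanthal distance", "Telecanthus"),
    lab("bizygomatic_width", "Narrow face", "Broad face"),
    lab("nasal_protrusion", "Underprojected nasal tip", "Prominent nasal tip"),
    lab("nasal_bridge_length", "Short nasal bridge", "Long nasal bridge"),
    lab("facial_height", "Short face", "Long face"),
    lab("labial_fissure_width", "Narrow mouth", "Wide mouth"),
    lab("philtral_length", "Short philtrum", "Long philtrum")
  ))
}

term_label <- function(term_map, measurement, direction) {
  hit <- term_map$measurement == measurement & term_map$direction == direction
  if (any(hit)) term_map$label[hit][1L]
  else paste(if (direction == "low") "decreased" else "increased",
             gsub("_", " ", measurement))
}

#' Flag atypical traits from a set of Z-scores
#'
#' Emits one flag per measurement whose |z| strictly exceeds the threshold
#' (default 2, the band containing approximately 95% of individuals);
#' direction is `"low"` for z below the band and `"high"` above it.
#'
#' @param zscores List of `zscore_result`s.
#' @param term_map See [default_term_map()].
#' @param threshold Flagging threshold in SD units (strict), default 2.
#' @return data.frame with columns measurement, direction, label, z
#'   (zero rows when nothing is flagged).
#' @export
flag_traits <- function(zscores, term_map = default_term_map(), threshold = 2) {
  flags <- lapply(zscores, function(zr) {
    if (!is.finite(zr$z) || abs(zr$z) <= threshold) return(NULL)
    dir <- if (zr$z < 0) "low" else "high"
    data.frame(measurement = zr$measurement, direction = dir,
               label = term_label(term_map, zr$measurement, dir),
               z = zr$z, stringsAsFactors = FALSE)
  })
  flags <- flags[!vapply(flags, is.null, logical(1))]
  if (length(flags) == 0L) {
    return(data.frame(measurement = character(), direction = character(),
                      label = character(), z = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Assess one subject against a reference set
#'
#' Computes a Z-score for every usable measurement that has a matching
#' sex-specific curve in the reference set and flags atypical traits beyond
#' the threshold. Measurements without a covering curve are listed as
#' uncovered rather than raising errors.
#'
#' @param records Measurement records for one subject (long data.frame).
#' @param refset A `reference_set`.
#' @param term_map See [default_term_map()].
#' @param threshold Flagging threshold in SD units.
#' @return An `assessment_report`: subject_id, reference ancestry, `zscores`
#'   (list of `zscore_result`), `flags` (data.frame), `n_flags`, `uncovered`.
#' @export
assess_subject <- function(records, refset, term_map = default_term_map(),
                           threshold = 2) {
  stopifnot(length(unique(records$subject_id)) == 1L)
  usable <- records[records$usable & is.finite(records$value), , drop = FALSE]
  zs <- list()
  uncovered <- character()
  for (i in seq_len(nrow(usable))) {
    rec <- usable[i, ]
    ref <- ref_curve_for(refset, rec$measurement, as.character(rec$sex))
    if (is.null(ref)) uncovered <- c(uncovered, rec$measurement)
    else zs[[rec$measurement]] <- zscore(rec, ref)
  }
  if (length(zs) == 0L) {
    warning("no reference curves match this subject; report is empty",
            call. = FALSE)
  }
  flags <- flag_traits(zs, term_map, threshold)
  structure(
    list(subject_id = records$subject_id[1L], ancestry = refset$ancestry,
         zscores = zs, flags = flags, n_flags = nrow(flags),
         uncovered = uncovered),
    class = "assessment_report"
  )
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("<assessment_report>", x$subject_id, "vs", x$ancestry, "reference\n")
  for (zr in x$zscores) {
    cat(sprintf("  %-28s %7.2f mm  z=%s%s\n", zr$measurement, zr$value,
                zr$display, if (zr$extrapolated) " (extrapolated)" else ""))
  }
  if (x$n_flags > 0) {
    cat("  flagged traits:\n")
    for (i in seq_len(nrow(x$flags))) {
      cat(sprintf("    %s (z=%s)\n", x$flags$label[i], format_z(x$flags$z[i])))
    }
  } else cat("  no atypical traits flagged\n")
  invisible(x)
}

#' Compare trait counts under two reference sets
#'
#' The reference-switch experiment: every subject is assessed once against
#' reference set A (e.g. a pre-existing European-derived reference) and once
#' against reference set B (e.g. a newly built population-specific
#' reference), and the per-subject flagged-trait counts are summarized by
#' median and range under each. No significance test is attached.
#'
#' @param records Long measurement data.frame covering one or more subjects.
#' @param refset_a,refset_b `reference_set`s.
#' @param term_map See [default_term_map()].
#' @param threshold Flagging threshold in SD units.
#' @return A `reference_comparison`: `counts` (data.frame subject_id,
#'   flags_a, flags_b), `median_before`/`median_after`,
#'   `range_before`/`range_after` (A = before, B = after).
#' @export
compare_references <- function(records, refset_a, refset_b,
                               term_map = default_term_map(), threshold = 2) {
  ids <- unique(records$subject_id)
  if (length(ids) == 0L) stop("no subjects to compare", call. = FALSE)
  counts <- data.frame(subject_id = ids, flags_a = NA_integer_,
                       flags_b = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    sub <- records[records$subject_id == ids[i], , drop = FALSE]
    counts$flags_a[i] <- assess_subject(sub, refset_a, term_map, threshold)$n_flags
    counts$flags_b[i] <- assess_subject(sub, refset_b, term_map, threshold)$n_flags
  }
  structure(
    list(counts = counts,
         median_before = stats::median(counts$flags_a),
         median_after = stats::median(counts$flags_b),
         range_before = range(counts$flags_a),
         range_after = range(counts$flags_b)),
    class = "reference_comparison"
  )
}

#' @export
print.reference_comparison <- function(x, ...) {
  cat(sprintf(
    "<reference_comparison> %d subjects: median flags %.1f (range %d-%d) -> %.1f (range %d-%d)\n",
    nrow(x$counts), x$median_before, x$range_before[1], x$range_before[2],
    x$median_after, x$range_after[1], x$range_after[2]))
  invisible(x)
}
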