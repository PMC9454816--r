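#' Per-specimen class counts
#'
#' @param n_normal_corrected,n_abnormal_corrected counts after gallery
#'   correction (these feed the diagnosis).
#' @param n_normal_uncorrected,n_abnormal_uncorrected raw automatic counts
#'   (reported for audit; default to the corrected values).
#' @param other named counts of the remaining classes.
#' @return `specimen_counts` list.
#' @export
specimen_counts <- function(n_normal_corrected, n_abnormal_corrected,
                            n_normal_uncorrected = n_normal_corrected,
                            n_abnormal_uncorrected = n_abnormal_corrected,
                            other = integer(0)) {
  vals <- c(n_normal_corrected, n_abnormal_corrected,
            n_normal_uncorrected, n_abnormal_uncorrected, other)
  if (any(vals < 0)) stop("counts must be non-negative")
  if (n_normal_corrected > n_normal_uncorrected ||
      n_abnormal_corrected > n_abnormal_uncorrected)
    stop("corrected counts cannot exceed uncorrected counts")
  structure(list(
    n_normal_corrected = n_normal_corrected,
    n_abnormal_corrected = n_abnormal_corrected,
    n_normal_uncorrected = n_normal_uncorrected,
    n_abnormal_uncorrected = n_abnormal_uncorrected,
    other = other
  ), class = "specimen_counts")
}

#' Percentage of abnormal nuclei
#'
#' The suspicion statistic: abnormal epithelial nuclei as a percentage of
#' the normal (reference) nuclei — the denominator is the normal count,
#' not normal + abnormal. For effusions the field practice relates
#' abnormal to all mesothelial nuclei; select that with
#' `denominator = "all"`.
#'
#' @param counts a [specimen_counts()].
#' @param denominator `"normal"` (default) or `"all"` (normal + abnormal).
#' @return Percentage (0-100 scale).
#' @export
abnormal_fraction <- function(counts, denominator = c("normal", "all")) {
  denominator <- match.arg(denominator)
  den <- counts$n_normal_corrected +
    if (denominator == "all") counts$n_abnormal_corrected else 0
  if (den <= 0) stop("inadequate specimen: no normal reference nuclei")
  100 * counts$n_abnormal_corrected / den
}

default_threshold <- function(specimen_type) {
  switch(specimen_type, oral = 4.0, effusion = 0.75, prostate = 4.0,
         stop("unknown specimen type: ", specimen_type))
}

#' Specimen-level diagnosis
#'
#' The decision algorithm: DNA aneuploidy (single-cell or stemline) in the
#' morphologically abnormal nuclei proves malignancy (`positive`); without
#' aneuploidy, an abnormal-nucleus percentage strictly above the
#' specimen-type threshold raises suspicion (`suspicious`, still
#' test-positive); otherwise the specimen is `negative`. Values exactly at
#' the threshold are negative. Fewer than `adequacy_floor` corrected normal
#' reference nuclei add an adequacy warning (never an error).
#'
#' @param counts a [specimen_counts()].
#' @param histogram_analysis a [analyse_histogram()] result, or `NULL` when
#'   no DNA measurement is available.
#' @param specimen_type `"oral"`, `"effusion"` or `"prostate"`; sets the
#'   default threshold (oral 4%, effusion 0.75%) and, for effusions, the
#'   all-mesothelial denominator.
#' @param threshold_pct suspicion threshold in percent (> 0); the oral
#'   alternative of 5% is available by passing `threshold_pct = 5`.
#' @param adequacy_floor warning threshold on corrected normal nuclei.
#' @return `specimen_diagnosis` list: `category`, `test_positive`,
#'   `abnormal_pct`, `threshold_used`, `aneuploid`, `single_cell_aneuploid`,
#'   `stemline_aneuploid`, `rationale`, `warnings`.
#' @export
diagnose_specimen <- function(counts, histogram_analysis = NULL,
                              specimen_type = "oral", threshold_pct = NULL,
                              adequacy_floor = 300) {
  threshold_pct <- threshold_pct %||% default_threshold(specimen_type)
  if (threshold_pct <= 0) stop("threshold_pct must be > 0")
  denom <- if (specimen_type == "effusion") "all" else "normal"
  warnings <- character(0)
  pct <- tryCatch(abnormal_fraction(counts, denom), error = function(e) {
    warnings <<- c(warnings, conditionMessage(e))
    NA_real_
  })
  if (!is.na(counts$n_normal_corrected) &&
      counts$n_normal_corrected < adequacy_floor)
    warnings <- c(warnings, sprintf(
      "only %d corrected normal reference nuclei (< %d): specimen may be inadequate",
      counts$n_normal_corrected, adequacy_floor))
  sc <- isTRUE(histogram_analysis$single_cell_aneuploid)
  sl <- isTRUE(histogram_analysis$stemline_aneuploid)
  if (!is.null(histogram_analysis) && isTRUE(histogram_analysis$insufficient))
    warnings <- c(warnings, "too few abnormal nuclei for DNA histogram analysis")
  if (sc || sl) {
    category <- "positive"
    rationale <- paste0("DNA aneuploidy present (",
                        paste(c("single-cell"[sc], "stemline"[sl]),
                              collapse = " and "),
                        "): specific marker of malignancy")
  } else if (!is.na(pct) && pct > threshold_pct) {
    category <- "suspicious"
    rationale <- sprintf(
      "%.2f%% abnormal nuclei exceeds the %.2f%% threshold without DNA aneuploidy",
      pct, threshold_pct)
  } else {
    category <- "negative"
    rationale <- sprintf(
      "no DNA aneuploidy and abnormal-nucleus percentage (%.2f%%) at or below %.2f%%",
      if (is.na(pct)) 0 else pct, threshold_pct)
  }
  structure(list(
    category = category, test_positive = category != "negative",
    abnormal_pct = pct, threshold_used = threshold_pct,
    aneuploid = sc || sl, single_cell_aneuploid = sc,
    stemline_aneuploid = sl, rationale = rationale, warnings = warnings
  ), class = "specimen_diagnosis")
}

#' @export
print.specimen_diagnosis <- function(x, ...) {
  cat(sprintf("specimen diagnosis: %s (%.2f%% abnormal, threshold %.2f%%)\n",
              toupper(x$category),
              if (is.na(x$abnormal_pct)) 0 else x$abnormal_pct,
              x$threshold_used))
  cat(" ", x$rationale, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  if (!is.null(x$dna_grade))
    cat(sprintf("  DNA grade %d (%s)\n", x$dna_grade$grade, x$dna_grade$label))
  invisible(x)
}

#' Prostate diagnosis with DNA malignancy grade
#'
#' Attaches the four-level DNA grade to the aneuploidy-based category for
#' enzymatic cell-separation specimens of prostate cancer.
#'
#' @param histogram_analysis a [analyse_histogram()] result over the
#'   cancer-cell nuclei; at least one stemline is required.
#' @return `specimen_diagnosis` with a `dna_grade` component.
#' @export
diagnose_prostate <- function(histogram_analysis) {
  grade <- dna_grade(histogram_analysis) # errors when ungradeable
  sc <- isTRUE(histogram_analysis$single_cell_aneuploid)
  sl <- isTRUE(histogram_analysis$stemline_aneuploid)
  category <- if (sc || sl) "positive" else "negative"
  structure(list(
    category = category, test_positive = category != "negative",
    abnormal_pct = NA_real_, threshold_used = NA_real_,
    aneuploid = sc || sl, single_cell_aneuploid = sc,
    stemline_aneuploid = sl, dna_grade = grade,
    rationale = sprintf("DNA grade %d (%s); %s", grade$grade, grade$label,
                        if (sc || sl) "DNA aneuploidy present"
                        else "no DNA aneuploidy"),
    warnings = character(0)
  ), class = "specimen_diagnosis")
}
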