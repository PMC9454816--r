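#' Contingency table against a reference standard
#'
#' @param tp,fp,tn,fn non-negative integer cell counts (truth in rows:
#'   positives split into TP/FN, negatives into TN/FP).
#' @return `contingency_table` list.
#' @export
contingency_table <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) == 0) stop("contingency table is all zero")
  structure(as.list(cells), class = "contingency_table")
}

#' Diagnostic accuracy statistics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
#' NPV TN/(TN+FN) and overall diagnostic accuracy (TP+TN)/N, each as the
#' exact fraction plus a percentage rounded half-up to one decimal.
#' Undefined ratios (zero denominator) are reported as not applicable
#' (`NA` value, fraction `"n/a"`), never as 0.
#'
#' @param table a [contingency_table()].
#' @return `diagnostic_accuracy` data.frame: metric, numerator,
#'   denominator, fraction, value (exact proportion), pct (rounded %).
#' @export
contingency_stats <- function(table) {
  tp <- table$tp; fp <- table$fp; tn <- table$tn; fn <- table$fn
  num <- c(sensitivity = tp, specificity = tn, ppv = tp, npv = tn,
           oda = tp + tn)
  den <- c(sensitivity = tp + fn, specificity = tn + fp, ppv = tp + fp,
           npv = tn + fn, oda = tp + fp + tn + fn)
  value <- ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(
    metric = names(num), numerator = unname(num), denominator = unname(den),
    fraction = ifelse(den > 0, paste0(num, "/", den), "n/a"),
    value = unname(value),
    pct = unname(ifelse(den > 0, round_half_up(100 * num / den, 1), NA_real_)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("diagnostic_accuracy", class(out))
  out
}

#' @export
print.diagnostic_accuracy <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf(" %-11s %9s = %s\n", x$metric[i], x$fraction[i],
                if (is.na(x$pct[i])) "n/a" else paste0(x$pct[i], "%")))
  }
  invisible(x)
}

#' The packaged study count fixture
#'
#' Per-rule contingency counts of the 92-smear oral screening study,
#' encoded from the published accuracy table at count level (the per-slide
#' raw data are not public). Two reference standards are available: the
#' `original` follow-up (20 positive / 72 negative slides) and the
#' `modified` one (25 / 67), in which five documented discordant slides
#' with proven DNA aneuploidy were re-rated as correct positive.
#'
#' @param standard `"original"`, `"modified"`, or `"both"` (default).
#' @return data.frame: standard, rule, tp, fn, tn, fp.
#' @export
table1_counts <- function(standard = "both") {
  path <- system.file("extdata", "table1_counts.csv", package = "karyoscan")
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (standard != "both") df <- df[df$standard == standard, ]
  df
}

#' Regenerate the diagnostic-accuracy table from the count fixture
#'
#' @param standard `"original"` or `"modified"` reference standard.
#' @return data.frame with one row per metric x rule, as produced by
#'   [contingency_stats()], plus `rule` and `standard` columns.
#' @export
table1 <- function(standard = c("modified", "original")) {
  standard <- match.arg(standard)
  cnt <- table1_counts(standard)
  out <- do.call(rbind, lapply(seq_len(nrow(cnt)), function(i) {
    st <- contingency_stats(contingency_table(cnt$tp[i], cnt$fp[i],
                                              cnt$tn[i], cnt$fn[i]))
    st$rule <- cnt$rule[i]
    st$standard <- standard
    st
  }))
  rownames(out) <- NULL
  out
}

#' Evaluate several diagnostic rules against a reference standard
#'
#' @param per_slide_results data.frame with `slide_id` and one logical
#'   column per rule (test-positive calls).
#' @param reference data.frame with `slide_id` and logical `truth`
#'   (positive follow-up).
#' @return data.frame of [contingency_stats()] rows per rule. Invariant to
#'   slide ordering.
#' @export
evaluate_rules <- function(per_slide_results, reference) {
  rules <- setdiff(names(per_slide_results), "slide_id")
  if (!length(rules)) stop("no rule columns in per_slide_results")
  m <- merge(per_slide_results, reference[, c("slide_id", "truth")],
             by = "slide_id")
  if (nrow(m) < nrow(per_slide_results))
    stop("slides without reference truth: ",
         paste(setdiff(per_slide_results$slide_id, reference$slide_id),
               collapse = ", "))
  out <- list()
  for (r in rules) {
    v <- m[[r]]
    if (any(is.na(v))) stop("slide missing a result for rule ", r)
    ct <- contingency_table(tp = sum(v & m$truth), fp = sum(v & !m$truth),
                            tn = sum(!v & !m$truth), fn = sum(!v & m$truth))
    st <- contingency_stats(ct)
    st$rule <- r
    out[[r]] <- st
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the diagnostic pipeline over one simulated slide
#'
#' Densitometric path: uses the slide's truth class labels (an oracle
#' classifier) or a trained model, calibrates on the reference class,
#' converts the abnormal IODs to c-values, analyses the DNA histogram and
#' issues a specimen diagnosis.
#'
#' @param slide a [render_slide()] result.
#' @param config see [karyo_config()].
#' @param threshold_pct suspicion threshold (default oral, 4%).
#' @param reference_class,analysed_class class labels used for calibration
#'   and DNA analysis.
#' @param mode `"tables"` (truth-table IODs) or `"images"` (full imaging
#'   pipeline via [scan_slide()] with truth-matched labels).
#' @return List: `diagnosis`, `analysis`, `calibration`, `counts`,
#'   `scan` (images mode only).
#' @export
diagnose_slide <- function(slide, config = karyo_config(),
                           threshold_pct = 4,
                           reference_class = "normal_epithelial",
                           analysed_class = "abnormal",
                           mode = c("tables", "images")) {
  mode <- match.arg(mode)
  if (mode == "tables") {
    tab <- slide$truth
    if (is.null(tab$measured_iod)) tab$measured_iod <- tab$target_iod
    cls <- tab$class
    scan <- NULL
  } else {
    scan <- match_truth(scan_slide(slide, config), slide$truth)
    tab <- scan[!is.na(scan$truth_class), ]
    tab$measured_iod <- tab$iod
    cls <- tab$truth_class
  }
  ref_iod <- tab$measured_iod[cls == reference_class]
  calib <- calibrate(ref_iod)
  abn_iod <- tab$measured_iod[cls == analysed_class]
  analysis <- analyse_histogram(to_c_values(abn_iod, calib))
  counts <- specimen_counts(
    n_normal_corrected = sum(cls == reference_class),
    n_abnormal_corrected = sum(cls == analysed_class))
  diag <- diagnose_specimen(counts, analysis, specimen_type = "oral",
                            threshold_pct = threshold_pct)
  list(diagnosis = diag, analysis = analysis, calibration = calib,
       counts = counts, scan = scan)
}

#' Benchmark the full pipeline on a simulated cohort
#'
#' Runs [diagnose_slide()] on every slide of a cohort and scores the
#' specimen-level test-positive calls against the ground-truth manifest.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param config see [karyo_config()].
#' @param threshold_pct suspicion threshold in percent.
#' @param mode `"tables"` or `"images"` (see [diagnose_slide()]).
#' @return List: `accuracy` ([contingency_stats()]), `per_slide`
#'   (data.frame with category, abnormal_pct, aneuploidy flags,
#'   calibration CV), `calibration_cvs`.
#' @export
benchmark_pipeline <- function(cohort, config = karyo_config(),
                               threshold_pct = 4,
                               mode = c("tables", "images")) {
  mode <- match.arg(mode)
  if (is.null(cohort$manifest)) stop("cohort has no truth manifest")
  n <- nrow(cohort$manifest)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- diagnose_slide(cohort$slides[[i]], config,
                          threshold_pct = threshold_pct, mode = mode)
    d <- res$diagnosis
    rows[[i]] <- data.frame(
      slide_id = cohort$manifest$slide_id[i],
      truth = cohort$manifest$malignant[i],
      category = d$category, test_positive = d$test_positive,
      abnormal_pct = d$abnormal_pct, aneuploid = d$aneuploid,
      calibration_cv = res$calibration$final_cv,
      stringsAsFactors = FALSE)
  }
  per_slide <- do.call(rbind, rows)
  ct <- contingency_table(
    tp = sum(per_slide$test_positive & per_slide$truth),
    fp = sum(per_slide$test_positive & !per_slide$truth),
    tn = sum(!per_slide$test_positive & !per_slide$truth),
    fn = sum(!per_slide$test_positive & per_slide$truth))
  list(accuracy = contingency_stats(ct), per_slide = per_slide,
       calibration_cvs = per_slide$calibration_cv)
}
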