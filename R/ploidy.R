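#' Internal DNA calibration by iterative outlier trimming
#'
#' The reference population (morphologically normal epithelial/mesothelial
#' or fibroblast nuclei on the same slide) defines the diploid 2c value.
#' Outliers below and above the running mean are eliminated automatically —
#' one farthest-from-mean IOD per iteration — until the coefficient of
#' variation falls below `cv_target` percent or the sample floor is
#' reached, in which case calibration fails with an explicit error
#' carrying the trimming trace.
#'
#' @param reference_iods numeric vector of reference IODs (> 0).
#' @param cv_target terminating CV in percent (default 4).
#' @param min_n floor on the number of surviving reference nuclei.
#' @return `calibration_result` list: `reference_mean_iod`, `final_cv` (%),
#'   `n_initial`, `n_used`, `n_trimmed`, `trimmed` (removed IODs in
#'   order), `cv_trace` (CV before each iteration and at termination).
#' @export
calibrate <- function(reference_iods, cv_target = 4, min_n = 30) {
  x <- reference_iods
  if (length(x) < min_n)
    stop("need at least ", min_n, " reference IODs, got ", length(x))
  if (any(!is.finite(x)) || any(x <= 0))
    stop("reference IODs must be positive and finite")
  cv <- function(v) 100 * sd(v) / mean(v)
  trimmed <- numeric(0)
  trace <- cv(x)
  while (cv(x) >= cv_target && length(x) > min_n) {
    worst <- which.max(abs(x - mean(x)))
    trimmed <- c(trimmed, x[worst])
    x <- x[-worst]
    trace <- c(trace, cv(x))
  }
  if (cv(x) >= cv_target) {
    cond <- structure(class = c("karyoscan_calibration_failure", "error",
                                "condition"),
                      list(message = sprintf(
                        "calibration failed: CV %.2f%% >= %.1f%% at floor n = %d",
                        cv(x), cv_target, length(x)),
                        call = sys.call(-1), cv_trace = trace,
                        trimmed = trimmed))
    stop(cond)
  }
  structure(list(
    reference_mean_iod = mean(x), final_cv = cv(x),
    n_initial = length(reference_iods), n_used = length(x),
    n_trimmed = length(trimmed), trimmed = trimmed, cv_trace = trace
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "internal calibration: 2c = IOD %.2f, CV %.2f%% (%d of %d nuclei kept, %d trimmed)\n",
    x$reference_mean_iod, x$final_cv, x$n_used, x$n_initial, x$n_trimmed))
  invisible(x)
}

#' Convert IODs to c-values
#'
#' Linear, order-preserving map: `c = 2 * IOD / reference_mean_iod`, so the
#' calibrated reference mean sits exactly at 2c (diploid).
#'
#' @param iods numeric IODs.
#' @param calibration a [calibrate()] result (or a bare reference mean).
#' @return Numeric c-values.
#' @export
to_c_values <- function(iods, calibration) {
  ref <- if (is.list(calibration)) calibration$reference_mean_iod
  else calibration
  2 * iods / ref
}

#' Classify a DNA stemline as euploid or aneuploid
#'
#' ESACP rule: stemlines outside the closed euploid windows [1.8, 2.2]c
#' (peridiploid) and [3.6, 4.4]c (peritetraploid) are aneuploid; the window
#' boundaries themselves count as euploid.
#'
#' @param position_c stemline modal position(s) in c-units (> 0).
#' @return Logical vector, `TRUE` = aneuploid.
#' @export
classify_stemline <- function(position_c) {
  if (any(position_c <= 0)) stop("stemline position must be > 0")
  !((position_c >= 1.8 & position_c <= 2.2) |
      (position_c >= 3.6 & position_c <= 4.4))
}

#' Detect DNA stemlines in a c-value distribution
#'
#' Gaussian kernel density (bandwidth 0.1c) over the analysed nuclei;
#' local density maxima holding at least `min_mass` of the nuclei within
#' +/-10% of the mode are reported as stemlines, positioned at the mean
#' c-value of their members and sorted by mass descending.
#'
#' @param c_values measured c-values of the analysed (abnormal) nuclei.
#' @param min_n minimum analysed nuclei for a meaningful histogram.
#' @param bandwidth kernel bandwidth in c-units.
#' @param min_mass minimum mass fraction of a reportable stemline.
#' @return data.frame: position_c, mass_fraction, aneuploid — empty with
#'   attribute `insufficient = TRUE` when fewer than `min_n` nuclei are
#'   available.
#' @export
detect_stemlines <- function(c_values, min_n = 10, bandwidth = 0.1,
                             min_mass = 0.05) {
  empty <- data.frame(position_c = numeric(), mass_fraction = numeric(),
                      aneuploid = logical())
  if (length(c_values) < min_n) {
    attr(empty, "insufficient") <- TRUE
    return(empty)
  }
  d <- density(c_values, bw = bandwidth, n = 1024,
               from = max(min(c_values) - 0.5, 0.01),
               to = max(c_values) + 0.5)
  y <- d$y
  loc <- which(diff(sign(diff(y))) < 0) + 1
  if (!length(loc)) loc <- which.max(y)
  out <- list()
  for (m in d$x[loc]) {
    members <- c_values[c_values >= 0.9 * m & c_values <= 1.1 * m]
    mass <- length(members) / length(c_values)
    if (mass < min_mass) next
    out[[length(out) + 1]] <- data.frame(position_c = mean(members),
                                         mass_fraction = mass)
  }
  if (!length(out)) return(empty)
  st <- do.call(rbind, out)
  # merge modes that resolved to (nearly) the same position
  st <- st[order(-st$mass_fraction), ]
  keep <- rep(TRUE, nrow(st))
  for (i in seq_len(nrow(st))[-1]) {
    if (any(abs(st$position_c[seq_len(i - 1)][keep[seq_len(i - 1)]] -
                st$position_c[i]) < 0.15))
      keep[i] <- FALSE
  }
  st <- st[keep, , drop = FALSE]
  st$aneuploid <- classify_stemline(st$position_c)
  rownames(st) <- NULL
  st
}

#' ESACP DNA-histogram analysis
#'
#' Combines stemline detection with single-cell aneuploidy counting:
#' `n_9cEE` counts nuclei with DNA content strictly above 9c (9c exceeding
#' events); one or more such events constitute single-cell aneuploidy, and
#' any aneuploid stemline constitutes stemline aneuploidy. DNA aneuploidy
#' (either flag) is the specific marker of malignancy.
#'
#' @param c_values measured c-values of the analysed (abnormal) nuclei.
#' @param min_n,bandwidth,min_mass passed to [detect_stemlines()].
#' @return `dna_histogram_analysis` list: `c_values`, `stemlines`,
#'   `n_9cEE`, `single_cell_aneuploid`, `stemline_aneuploid`, `aneuploid`,
#'   `insufficient`.
#' @export
analyse_histogram <- function(c_values, min_n = 10, bandwidth = 0.1,
                              min_mass = 0.05) {
  st <- detect_stemlines(c_values, min_n = min_n, bandwidth = bandwidth,
                         min_mass = min_mass)
  insufficient <- isTRUE(attr(st, "insufficient"))
  n9 <- sum(c_values > 9.0)
  structure(list(
    c_values = c_values, stemlines = st, n_9cEE = as.integer(n9),
    single_cell_aneuploid = n9 >= 1,
    stemline_aneuploid = nrow(st) > 0 && any(st$aneuploid),
    aneuploid = (n9 >= 1) || (nrow(st) > 0 && any(st$aneuploid)),
    insufficient = insufficient
  ), class = "dna_histogram_analysis")
}

#' @export
print.dna_histogram_analysis <- function(x, ...) {
  cat(sprintf("DNA histogram: %d analysed nuclei, %d stemline(s), %d 9cEE\n",
              length(x$c_values), nrow(x$stemlines), x$n_9cEE))
  if (nrow(x$stemlines)) print(round(x$stemlines, 3))
  cat(" stemline aneuploidy:", x$stemline_aneuploid,
      "| single-cell aneuploidy:", x$single_cell_aneuploid, "\n")
  invisible(x)
}

#' DNA grade of malignancy
#'
#' Four-level grading of a DNA histogram: grade 1 (peridiploid) if all
#' stemlines lie in [1.8, 2.2]c; grade 2 (peritetraploid) if all stemlines
#' are euploid with at least one in [3.6, 4.4]c; grade 3 (x-ploid) if
#' exactly one stemline is aneuploid; grade 4 (multiploid) if two or more
#' are.
#'
#' @param analysis a [analyse_histogram()] result (or a data.frame of
#'   stemlines).
#' @return List: `grade` (1..4), `label`.
#' @export
dna_grade <- function(analysis) {
  st <- if (is.data.frame(analysis)) analysis else analysis$stemlines
  if (is.null(st) || nrow(st) == 0)
    stop("ungradeable: no DNA stemline detected")
  peridip <- st$position_c >= 1.8 & st$position_c <= 2.2
  peritet <- st$position_c >= 3.6 & st$position_c <= 4.4
  n_aneu <- sum(!(peridip | peritet))
  if (n_aneu == 0 && all(peridip)) g <- 1L
  else if (n_aneu == 0) g <- 2L
  else if (n_aneu == 1) g <- 3L
  else g <- 4L
  list(grade = g, label = c("peridiploid", "peritetraploid", "x-ploid",
                            "multiploid")[g])
}

#' Plot a DNA histogram with euploid windows
#'
#' @param analysis a [analyse_histogram()] result.
#' @param file optional PNG path; when given the plot is written there.
#' @param main plot title.
#' @return Invisibly, the analysis.
#' @export
plot_dna_histogram <- function(analysis, file = NULL,
                               main = "DNA histogram") {
  if (!is.null(file)) {
    png(file, width = 800, height = 500)
    on.exit(dev.off())
  }
  cv <- analysis$c_values
  h <- hist(cv, breaks = seq(0, max(cv, 10) + 0.25, by = 0.25), plot = FALSE)
  ylim <- c(0, max(h$counts) * 1.05)
  plot(h, col = "grey80", border = "grey50", main = main,
       xlab = "DNA content (c)", ylim = ylim)
  rect(1.8, 0, 2.2, ylim[2], col = grDevices::adjustcolor("seagreen", 0.15),
       border = NA)
  rect(3.6, 0, 4.4, ylim[2], col = grDevices::adjustcolor("seagreen", 0.15),
       border = NA)
  abline(v = 9, lty = 2, col = "firebrick")
  if (nrow(analysis$stemlines))
    abline(v = analysis$stemlines$position_c, col = "steelblue", lwd = 2)
  invisible(analysis)
}
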