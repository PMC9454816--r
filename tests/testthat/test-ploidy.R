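test_that("identical reference IODs calibrate without trimming", {
  cal <- calibrate(rep(100, 50))
  expect_equal(cal$reference_mean_iod, 100)
  expect_equal(cal$final_cv, 0)
  expect_equal(cal$n_trimmed, 0)
})

test_that("trimming removes the farthest outlier first and matches a step-by-step replay", {
  set.seed(13)
  x <- c(rnorm(49, 100, 3), 150)
  cal <- calibrate(x)
  # replayed by hand: repeatedly drop the value farthest from the mean
  y <- x; removed <- numeric(0)
  while (100 * sd(y) / mean(y) >= 4 && length(y) > 30) {
    k <- which.max(abs(y - mean(y)))
    removed <- c(removed, y[k]); y <- y[-k]
  }
  expect_equal(cal$trimmed[1], 150) # gross outlier goes first
  expect_identical(cal$trimmed, removed)
  expect_equal(cal$reference_mean_iod, mean(y))
  expect_lt(cal$final_cv, 4)
  expect_equal(cal$n_initial, cal$n_used + cal$n_trimmed)
})

test_that("calibration CV trace is monotone non-increasing", {
  set.seed(14)
  converged <- 0
  for (i in 1:10) {
    x <- simulate_reference_iods(50, cv = 6)
    # the trace is monotone whether or not trimming reaches the target
    res <- tryCatch(calibrate(x), error = function(e) e)
    trace <- if (is.list(res) && !inherits(res, "error")) res$cv_trace
    else res$cv_trace
    expect_true(all(diff(trace) <= 1e-9))
    if (!inherits(res, "error")) {
      converged <- converged + 1
      expect_lt(res$final_cv, 4)
    }
  }
  expect_gte(converged, 9)
})

test_that("calibration fails loudly at the sample floor", {
  set.seed(15)
  x <- runif(31, 10, 300) # hopelessly dispersed
  err <- tryCatch(calibrate(x), error = function(e) e)
  expect_s3_class(err, "karyoscan_calibration_failure")
  expect_match(conditionMessage(err), "floor")
  expect_true(length(err$trimmed) > 0)
  expect_error(calibrate(rep(100, 10)), "at least 30")
  expect_error(calibrate(c(rep(100, 49), -5)), "positive")
})

test_that("c-value conversion is the exact linear diploid anchor", {
  cal <- calibrate(rep(80, 40))
  expect_equal(to_c_values(80, cal), 2)
  expect_equal(to_c_values(160, cal), 4)
  expect_equal(to_c_values(80 * 4.6, cal), 9.2) # a >9c event
  # linearity: scaling IODs scales c-values exactly
  iods <- c(40, 80, 120)
  expect_identical(to_c_values(3 * iods, cal), 3 * to_c_values(iods, cal))
})

test_that("the ESACP euploid windows classify stemlines with closed boundaries", {
  pos <- c(1.7, 1.8, 2.0, 2.2, 2.3, 3.47, 3.6, 4.0, 4.4, 4.5)
  expect_identical(classify_stemline(pos),
                   c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
                     FALSE, TRUE))
  expect_error(classify_stemline(0), "> 0")
})

test_that("stemline detection recovers unimodal and bimodal populations", {
  set.seed(16)
  one <- rnorm(200, 2.0, 0.05)
  st <- detect_stemlines(one)
  expect_equal(nrow(st), 1)
  expect_lt(abs(st$position_c - 2.0), 0.05)
  expect_false(st$aneuploid)
  two <- c(rnorm(150, 2.0, 0.05), rnorm(150, 3.5, 0.07))
  st2 <- detect_stemlines(two)
  expect_equal(nrow(st2), 2)
  got <- sort(st2$position_c)
  expect_lt(abs(got[1] - 2.0), 0.07)
  expect_lt(abs(got[2] - 3.5), 0.07)
  expect_identical(st2$aneuploid[order(st2$position_c)], c(FALSE, TRUE))
  # mass fractions are plausible and sorted descending
  expect_true(all(st2$mass_fraction > 0.05 & st2$mass_fraction <= 1))
  expect_true(!is.unsorted(rev(st2$mass_fraction)))
})

test_that("too few analysed nuclei yield the insufficient flag, no stemlines", {
  st <- detect_stemlines(c(2, 2.1, 1.9, 2, 2))
  expect_equal(nrow(st), 0)
  expect_true(attr(st, "insufficient"))
})

test_that("histogram analysis composes the aneuploidy rules", {
  set.seed(17)
  dip <- runif(100, 1.9, 2.1)
  a <- analyse_histogram(dip)
  expect_false(a$aneuploid)
  expect_equal(a$n_9cEE, 0L)
  # one 9.1c nucleus among diploids: single-cell aneuploidy only
  b <- analyse_histogram(c(dip, 9.1))
  expect_true(b$single_cell_aneuploid)
  expect_equal(b$n_9cEE, 1L)
  expect_false(b$stemline_aneuploid)
  # 9cEE counting is strict at 9.0c
  expect_equal(analyse_histogram(c(dip, 9.0))$n_9cEE, 0L)
  # aneuploid stemline without any >9c nucleus
  cc <- analyse_histogram(rnorm(120, 3.0, 0.05))
  expect_true(cc$stemline_aneuploid)
  expect_false(cc$single_cell_aneuploid)
  expect_true(cc$aneuploid)
})

test_that("DNA grading follows the four-level stemline rule", {
  mk <- function(pos) data.frame(position_c = pos,
                                 mass_fraction = rep(1 / length(pos),
                                                     length(pos)),
                                 aneuploid = classify_stemline(pos))
  expect_equal(dna_grade(mk(2.0))$grade, 1)
  expect_equal(dna_grade(mk(2.0))$label, "peridiploid")
  expect_equal(dna_grade(mk(c(2.0, 4.0)))$grade, 2)
  expect_equal(dna_grade(mk(c(2.0, 4.0)))$label, "peritetraploid")
  expect_equal(dna_grade(mk(c(2.0, 3.0)))$grade, 3)
  expect_equal(dna_grade(mk(c(2.6, 3.3)))$grade, 4)
  expect_error(dna_grade(mk(numeric(0))), "ungradeable")
  # brute-force cross-check of the decision rule over a position grid
  grade_oracle <- function(pos) {
    d <- pos >= 1.8 & pos <= 2.2
    t <- pos >= 3.6 & pos <= 4.4
    na <- sum(!(d | t))
    if (na >= 2) 4 else if (na == 1) 3 else if (any(t)) 2 else 1
  }
  grid <- c(1.5, 1.8, 2.0, 2.2, 3.0, 3.6, 4.0, 4.4, 5.1)
  for (p1 in grid) for (p2 in grid) {
    pos <- unique(c(p1, p2))
    expect_equal(dna_grade(mk(pos))$grade, grade_oracle(pos))
  }
})

test_that("stemline positions are recovered within 0.1c under 3% measurement noise", {
  set.seed(18)
  hits <- 0
  for (i in 1:40) {
    cv <- simulate_c_values(150, stemline_positions = c(2.0, 3.47),
                            weights = c(1, 1), stemline_cv = 3,
                            measurement_cv = 3)
    st <- detect_stemlines(cv)
    ok <- nrow(st) >= 2 &&
      min(abs(st$position_c - 2.0)) <= 0.1 &&
      min(abs(st$position_c - 3.47)) <= 0.1
    hits <- hits + ok
  }
  expect_gte(hits / 40, 0.95)
})

test_that("histogram plot renders to a PNG file", {
  set.seed(19)
  a <- analyse_histogram(c(rnorm(100, 2, 0.06), rnorm(50, 3.4, 0.1), 9.4))
  f <- tempfile(fileext = ".png")
  plot_dna_histogram(a, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  unlink(f)
})
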