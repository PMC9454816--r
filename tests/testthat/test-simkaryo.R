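test_that("noise-free render round-trips the target IOD exactly", {
  set.seed(1)
  for (cl in c("normal_epithelial", "lymphocyte", "abnormal")) {
    sp <- sample_nucleus_spec(cl, c_value = if (cl == "abnormal") 3 else 2)
    rn <- render_nucleus(sp, measurement_cv = 0, planes = sp$z_position,
                         camera_noise_sd = 0)
    od <- to_optical_density(rn$stack[, , 1], rn$background_level)
    measured <- sum(od[rn$mask])
    expect_lt(abs(measured - rn$truth$target_iod) / rn$truth$target_iod, 0.01)
  }
})

test_that("a >9c spec renders a nucleus measuring above 9c", {
  set.seed(7)
  cfg <- karyo_config()
  sp <- nucleus_spec("abnormal", c_value = 9.5, radius = 20,
                     shape_irregularity = 0.5, chromatin_coarseness = 0.7)
  rn <- render_nucleus(sp, measurement_cv = 0, planes = sp$z_position,
                       camera_noise_sd = 0)
  cal_unit <- cfg$iod_per_2c # IOD of a 2c nucleus
  od <- to_optical_density(rn$stack[, , 1], rn$background_level)
  c_measured <- 2 * sum(od[rn$mask]) / cal_unit
  expect_gt(c_measured, 9)
})

test_that("renders are bit-identical under the same seed", {
  sp <- nucleus_spec("normal_epithelial", 2, 11)
  set.seed(42)
  a <- render_nucleus(sp, measurement_cv = 3)
  set.seed(42)
  b <- render_nucleus(sp, measurement_cv = 3)
  expect_identical(a$stack, b$stack)
  expect_identical(a$mask, b$mask)
})

test_that("too-dense IOD requests are rejected with an explicit error", {
  sp <- nucleus_spec("abnormal", c_value = 40, radius = 5)
  set.seed(1)
  expect_error(render_nucleus(sp), "radius too small")
})

test_that("slide truth tables carry one row per generated object", {
  sl <- render_slide(slide_spec(n_normal = 12, n_abnormal = 0,
                                n_per_other_class = c(lymphocyte = 0),
                                seed = 3),
                     render = FALSE)
  expect_equal(nrow(sl$truth), 12)
  expect_true(all(sl$truth$class == "normal_epithelial"))

  sl2 <- render_slide(tiny_slide_spec(seed = 5), render = FALSE)
  expect_equal(nrow(sl2$truth), 40 + 3 + 5 + 4 + 3 + 3 + 3 + 3)
  expect_setequal(unique(sl2$truth$class), oral_classes())
})

test_that("rendered stacks have exactly 7 planes and in-field objects", {
  sl <- render_slide(tiny_slide_spec(seed = 2))
  for (f in sl$fields) expect_equal(dim(f)[3], 7)
  fs <- sl$spec$field_size
  expect_true(all(sl$truth$row > 0 & sl$truth$row <= fs))
  expect_true(all(sl$truth$col > 0 & sl$truth$col <= fs))
  expect_true(all(sl$truth$field %in% seq_along(sl$fields)))
})

test_that("malignant slides with 9cEE fraction contain >9c truth nuclei", {
  sl <- render_slide(slide_spec(n_normal = 10, n_abnormal = 60,
                                malignant = TRUE, fraction_9cEE = 0.05,
                                n_per_other_class = c(lymphocyte = 0),
                                seed = 11),
                     render = FALSE)
  expect_gte(sum(sl$truth$c_value > 9), 1)
})

test_that("benign slides never carry aneuploid truth", {
  for (seed in 1:5) {
    sl <- render_slide(tiny_slide_spec(seed = seed, malignant = FALSE),
                       render = FALSE)
    abn <- sl$truth$c_value[sl$truth$class == "abnormal"]
    expect_true(all(abn <= 9))
  }
  expect_error(slide_spec(malignant = FALSE, stemline_positions = 3.0),
               "euploid")
  expect_error(slide_spec(malignant = FALSE, fraction_9cEE = 0.1),
               "fraction_9cEE")
})

test_that("nuclei are placed without overlap (disjoint truth footprints)", {
  sl <- render_slide(tiny_slide_spec(seed = 9), render = FALSE)
  tr <- sl$truth
  for (f in unique(tr$field)) {
    sub <- tr[tr$field == f, ]
    if (nrow(sub) < 2) next
    d <- as.matrix(dist(sub[, c("row", "col")]))
    diag(d) <- Inf
    rsum <- outer(sub$radius, sub$radius, "+")
    expect_true(all(d > rsum))
  }
})

test_that("cohort manifests list one truth per slide and reproduce byte-identically", {
  cs <- cohort_spec(1, 1, seed = 0, n_normal = 15, n_abnormal = 3,
                    n_per_other_class = c(lymphocyte = 0))
  a <- simulate_cohort(cs, render = FALSE)
  expect_equal(nrow(a$manifest), 2)
  expect_equal(sum(a$manifest$malignant), 1)
  b <- simulate_cohort(cs, render = FALSE)
  expect_identical(a$manifest, b$manifest)
  expect_identical(lapply(a$slides, `[[`, "truth"),
                   lapply(b$slides, `[[`, "truth"))
  # different seeds: same slide count, different compositions
  c2 <- simulate_cohort(cohort_spec(1, 1, seed = 1, n_normal = 15,
                                    n_abnormal = 3,
                                    n_per_other_class = c(lymphocyte = 0)),
                        render = FALSE)
  expect_equal(nrow(c2$manifest), 2)
  expect_false(identical(a$slides[[1]]$truth$c_value,
                         c2$slides[[1]]$truth$c_value))
})

test_that("cohort round-trips through TIFF/CSV/JSON serialization", {
  dir <- tempfile("cohort")
  cs <- cohort_spec(1, 0, seed = 4, n_normal = 6, n_abnormal = 0,
                    n_per_other_class = c(lymphocyte = 2), field_size = 128)
  coh <- simulate_cohort(cs, out_dir = dir)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  tifs <- list.files(dir, pattern = "\\.tif$", full.names = TRUE)
  expect_gte(length(tifs), 1)
  st <- read_stack(tifs[1])
  expect_equal(dim(st)[3], 7)
  orig <- coh$slides[[1]]$fields[[1]]
  expect_lt(max(abs(st - orig)), 0.01 * 255) # 16-bit quantization only
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$slides$slide_id, "slide001")
  expect_true(man$slides$malignant) # the single slide is the positive one
  unlink(dir, recursive = TRUE)
})

test_that("reference IOD generator hits the requested CV and outliers", {
  set.seed(10)
  x <- simulate_reference_iods(5000, mean_iod = 100, cv = 6,
                               outlier_fraction = 0)
  expect_lt(abs(100 * sd(x) / mean(x) - 6), 0.5)
  y <- simulate_reference_iods(50, outlier_fraction = 0.02,
                               outlier_factor = 1.5)
  expect_equal(sum(y == 150), 1)
})
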