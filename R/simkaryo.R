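#' Specification of a single synthetic nucleus
#'
#' Describes one object to be rendered on a synthetic Feulgen-stained slide.
#' DNA content is given in c-units (2c = diploid); the rendered integrated
#' optical density (IOD) of a nucleus is `c_value / 2 * iod_per_2c`, making
#' Feulgen stoichiometry (IOD proportional to DNA) literally true in the
#' fixture. Lytic nuclei are rendered at strongly reduced staining contrast
#' (their truth `c_value` records the nominal DNA content, the rendered
#' `target_iod` the degraded stain uptake); artefacts carry no DNA semantics
#' (`c_value = 0`) but still absorb light.
#'
#' @param class_label one of [oral_classes()].
#' @param c_value DNA content in c-units (> 0; 0 for artefacts).
#' @param radius nominal radius in px (>= 3).
#' @param z_position focal-plane index of sharpest focus; forced outside
#'   the in-focus plane set (0..6) for the defocused class.
#' @param shape_irregularity dimensionless boundary irregularity in [0, 1].
#' @param chromatin_coarseness dimensionless texture coarseness in [0, 1].
#' @param centroid numeric (row, col) position, filled in during slide
#'   placement; may be NA for stand-alone rendering.
#' @return An object of class `nucleus_spec`.
#' @export
nucleus_spec <- function(class_label, c_value, radius, z_position = 3L,
                         shape_irregularity = 0.1, chromatin_coarseness = 0.3,
                         centroid = c(NA_real_, NA_real_)) {
  stopifnot(length(class_label) == 1)
  if (!class_label %in% c(oral_classes(), prostate_classes()))
    stop("unknown class label: ", class_label)
  if (radius < 3) stop("radius must be >= 3 px")
  if (class_label != "artefact" && (!is.finite(c_value) || c_value <= 0))
    stop("c_value must be > 0 for nuclear classes")
  if (shape_irregularity < 0 || shape_irregularity > 1)
    stop("shape_irregularity must lie in [0, 1]")
  structure(list(
    class_label = class_label, c_value = c_value, radius = radius,
    z_position = as.integer(z_position),
    shape_irregularity = shape_irregularity,
    chromatin_coarseness = chromatin_coarseness,
    centroid = centroid
  ), class = "nucleus_spec")
}

# Default appearance parameters per diagnostic class. Values are stated
# assumptions (no per-class morphometric statistics exist for real nuclei);
# they are chosen so the classes are learnably separable and are all
# overridable through `sample_nucleus_spec()` arguments.
class_appearance <- function(class_label) {
  switch(class_label,
    normal_epithelial = list(radius = c(11, 1.5), irr = c(0.05, 0.20),
                             coarse = c(0.15, 0.35), c_cv = 4),
    fibroblast        = list(radius = c(10, 1.2), irr = c(0.10, 0.30),
                             coarse = c(0.15, 0.35), c_cv = 4),
    abnormal          = list(radius = c(16, 2.5), irr = c(0.40, 0.80),
                             coarse = c(0.60, 0.95), c_cv = NA),
    cancer            = list(radius = c(16, 2.5), irr = c(0.40, 0.80),
                             coarse = c(0.60, 0.95), c_cv = NA),
    lymphocyte        = list(radius = c(6, 0.5),  irr = c(0.02, 0.10),
                             coarse = c(0.30, 0.50), c_cv = 4),
    granulocyte       = list(radius = c(7, 0.7),  irr = c(0.05, 0.15),
                             coarse = c(0.35, 0.55), c_cv = 4),
    doublet           = list(radius = c(10, 1.0), irr = c(0.05, 0.15),
                             coarse = c(0.15, 0.35), c_cv = 4),
    defocused         = list(radius = c(11, 1.5), irr = c(0.05, 0.20),
                             coarse = c(0.15, 0.35), c_cv = 4),
    lytic             = list(radius = c(11, 1.5), irr = c(0.10, 0.30),
                             coarse = c(0.05, 0.20), c_cv = 4),
    artefact          = list(radius = c(12, 3.0), irr = c(0.75, 0.95),
                             coarse = c(0.70, 1.00), c_cv = NA),
    stop("no appearance defaults for class ", class_label)
  )
}

#' Draw a random nucleus specification for a diagnostic class
#'
#' Samples radius, shape irregularity, chromatin coarseness and (for 2c
#' classes) DNA content from the class appearance defaults. Abnormal nuclei
#' take their c-value from `c_value` (usually a stemline draw made by
#' [render_slide()]); artefacts get `c_value = 0`.
#'
#' @param class_label one of [oral_classes()] or [prostate_classes()].
#' @param c_value DNA content override in c-units; default draws near 2c
#'   for euploid classes.
#' @param z_position focal plane of sharpest focus (defocused class is
#'   forced outside 0..6 regardless).
#' @return A [nucleus_spec()].
#' @export
sample_nucleus_spec <- function(class_label, c_value = NULL,
                                z_position = sample(1:5, 1)) {
  ap <- class_appearance(class_label)
  radius <- max(ap$radius[1] - 2 * ap$radius[2], 4,
                rnorm(1, ap$radius[1], ap$radius[2]))
  irr <- runif(1, ap$irr[1], ap$irr[2])
  coarse <- runif(1, ap$coarse[1], ap$coarse[2])
  if (is.null(c_value)) {
    c_value <- if (class_label == "artefact") 0
    else if (is.na(ap$c_cv)) 2 * (1 + abs(rnorm(1, 0.5, 0.5)))
    else if (class_label == "doublet") 4 * (1 + rnorm(1) * ap$c_cv / 100)
    else 2 * (1 + rnorm(1) * ap$c_cv / 100)
  }
  if (class_label == "defocused") z_position <- sample(c(-2L, 8L), 1)
  nucleus_spec(class_label, c_value = c_value, radius = radius,
               z_position = z_position, shape_irregularity = irr,
               chromatin_coarseness = coarse)
}

# Rasterize a star-convex boundary: r(theta) = radius * (1 + irr/2 * s(theta))
# with s a band-limited harmonic perturbation; optional anisotropic stretch.
star_mask <- function(size, center, radius, irregularity, elongation = 1,
                      theta0 = runif(1, 0, 2 * pi)) {
  nh <- 2:5
  amp <- rnorm(length(nh), 0, 1)
  phs <- runif(length(nh), 0, 2 * pi)
  rr <- matrix(seq_len(size) - center[1], size, size)
  cc <- matrix(seq_len(size) - center[2], size, size, byrow = TRUE)
  # rotate by theta0, stretch the first axis by `elongation`
  u <- (cos(theta0) * rr + sin(theta0) * cc) / elongation
  v <- -sin(theta0) * rr + cos(theta0) * cc
  d <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  s <- matrix(0, size, size)
  for (i in seq_along(nh)) s <- s + amp[i] * cos(nh[i] * th + phs[i])
  smax <- max(abs(amp)) * length(nh)
  if (smax > 0) s <- s / (sum(abs(amp)) + 1e-12)
  d <= radius * (1 + irregularity * 0.5 * s)
}

# Composite mask for one object (doublets/granulocytes are disc unions).
object_mask <- function(spec, size, center) {
  cl <- spec$class_label
  if (cl == "doublet") {
    ang <- runif(1, 0, 2 * pi)
    off <- 0.60 * spec$radius
    m1 <- star_mask(size, center + off * c(cos(ang), sin(ang)),
                    spec$radius, spec$shape_irregularity)
    m2 <- star_mask(size, center - off * c(cos(ang), sin(ang)),
                    spec$radius * runif(1, 0.85, 1), spec$shape_irregularity)
    m1 | m2
  } else if (cl == "granulocyte") {
    angs <- runif(1, 0, 2 * pi) + c(0, 2, 4) * pi / 3
    m <- matrix(FALSE, size, size)
    for (a in angs) {
      m <- m | star_mask(size, center + 0.62 * spec$radius * c(cos(a), sin(a)),
                         0.62 * spec$radius, spec$shape_irregularity)
    }
    m
  } else if (cl == "artefact") {
    star_mask(size, center, spec$radius, spec$shape_irregularity,
              elongation = runif(1, 1.6, 3.2))
  } else {
    star_mask(size, center, spec$radius, spec$shape_irregularity)
  }
}

# Texture of the OD field, normalized on the mask so its sum hits
# `target_iod` exactly. Chromatin is smoothed noise with contrast scaled
# by coarseness; non-nuclear debris ("grain") is nearly unsmoothed
# high-variance noise without chromatin structure.
od_field <- function(mask, coarseness, target_iod, od_max,
                     texture = c("chromatin", "grain")) {
  texture <- match.arg(texture)
  area <- sum(mask)
  if (area < 1) stop("empty mask")
  if (target_iod / area > od_max)
    stop("radius too small to carry requested IOD at maximum optical density (",
         sprintf("mean OD %.2f > %.2f", target_iod / area, od_max), ")")
  if (texture == "grain") {
    tx <- blur_pad(matrix(runif(length(mask)), nrow(mask)), 0.4,
                   pad_value = 0.5)
    contrast <- 1.6
  } else {
    sig <- 0.6 + 2.5 * coarseness
    tx <- blur_pad(matrix(runif(length(mask)), nrow(mask)), sig,
                   pad_value = 0.5)
    contrast <- 0.35 + 0.9 * coarseness
  }
  tr <- range(tx[mask])
  tx <- if (diff(tr) > 0) (tx - tr[1]) / diff(tr) else tx * 0 + 0.5
  od <- pmax(1 - contrast / 2 + contrast * tx, 0.02) * mask
  od * (target_iod / sum(od[mask]))
}

# Target IOD of a spec in densitometric units (before measurement noise).
spec_target_iod <- function(spec, config) {
  base <- spec$c_value / 2 * config$iod_per_2c
  if (spec$class_label == "artefact") runif(1, 30, 300)
  else if (spec$class_label == "lytic") 0.3 * base
  else base
}

#' Render one nucleus as a focal-stack patch
#'
#' Implements the brightfield imaging model: a per-pixel optical density
#' (OD) field whose mask-sum equals the target IOD, pixel transmittance
#' `T = 10^(-OD)`, intensity `I = background * T` plus Gaussian camera
#' noise. Planes other than the spec's `z_position` are blurred with a
#' Gaussian of sigma `defocus_sigma_per_plane * |plane - z_position|`.
#'
#' @param spec a [nucleus_spec()].
#' @param background_level background intensity (> 0).
#' @param config see [karyo_config()].
#' @param measurement_cv percent multiplicative noise applied to the target
#'   IOD before rendering (per-nucleus stain/measurement variability).
#' @param planes integer vector of plane indices to render (default 0..6).
#' @param camera_noise_sd overrides `config$camera_noise_sd`.
#' @return A list with `stack` (h x w x planes intensity array), `mask`
#'   (logical truth mask), `truth` (one-row data.frame with class, c_value,
#'   target_iod, z_position) and `planes`.
#' @export
#' @examples
#' set.seed(1)
#' rn <- render_nucleus(nucleus_spec("lymphocyte", 2, 5), planes = 3L)
#' dim(rn$stack)
render_nucleus <- function(spec, background_level = NULL,
                           config = karyo_config(), measurement_cv = 0,
                           planes = 0:6, camera_noise_sd = NULL) {
  background_level <- background_level %||% config$background_level
  camera_noise_sd <- camera_noise_sd %||% config$camera_noise_sd
  if (background_level <= 0) stop("background_level must be positive")
  max_sigma <- config$defocus_sigma_per_plane *
    max(abs(planes - spec$z_position))
  pad <- max(4, ceiling(2 * max_sigma))
  half <- ceiling(spec$radius * (1 + 0.5 * spec$shape_irregularity) *
                    (if (spec$class_label == "artefact") 3.2 else
                       if (spec$class_label %in% c("doublet", "granulocyte")) 1.8 else 1))
  size <- 2L * (half + pad) + 1L
  center <- c(half + pad + 1, half + pad + 1)
  mask <- object_mask(spec, size, center)
  target <- spec_target_iod(spec, config) *
    (1 + rnorm(1) * measurement_cv / 100)
  od <- od_field(mask, spec$chromatin_coarseness, target, config$od_max,
                 texture = if (spec$class_label == "artefact") "grain"
                 else "chromatin")
  transmittance <- 10^(-od)
  stack <- array(0, c(size, size, length(planes)))
  for (i in seq_along(planes)) {
    sig <- config$defocus_sigma_per_plane * abs(planes[i] - spec$z_position)
    tp <- blur_pad(transmittance, sig, pad_value = 1)
    img <- background_level * tp
    if (camera_noise_sd > 0) img <- img + rnorm(length(img), 0, camera_noise_sd)
    stack[, , i] <- pmax(img, background_level * 1e-3)
  }
  truth <- data.frame(
    class = spec$class_label, c_value = spec$c_value, target_iod = target,
    z_position = spec$z_position, radius = spec$radius,
    area_px = sum(mask), stringsAsFactors = FALSE
  )
  list(stack = stack, mask = mask, truth = truth, planes = planes,
       background_level = background_level)
}

#' Specification of a synthetic slide
#'
#' Default composition is the study-scale mean object counts scaled down
#' tenfold so that a slide renders in seconds (about 340 normal epithelial
#' nuclei; about 31 abnormal nuclei on malignant and 4 on benign slides,
#' matching the corrected positive/negative follow-up means); pass
#' `scale = 1` for full study scale. Benign slides are constrained to
#' euploid stemlines (within [1.8, 2.2]c or [3.6, 4.4]c) and zero 9c
#' exceeding events.
#'
#' @param n_normal number of normal epithelial (reference) nuclei.
#' @param n_abnormal number of abnormal nuclei; defaults depend on
#'   `malignant`.
#' @param malignant slide-level ground truth.
#' @param stemline_positions modal c-values of the abnormal population.
#' @param fraction_9cEE fraction of abnormal nuclei drawn above 9c
#'   (malignant slides only).
#' @param n_per_other_class named counts for the remaining classes.
#' @param measurement_cv percent IOD rendering noise per nucleus.
#' @param stemline_cv percent width (CV) of each stemline population.
#' @param scale multiplier applied to the default class counts.
#' @param seed RNG seed for the slide.
#' @param field_size side of a square scan field in px.
#' @param fixed_c optional named list pinning classes to an exact DNA
#'   content in c-units (e.g. `list(lymphocyte = 2)` for an
#'   identical-content reference population).
#' @return An object of class `slide_spec`.
#' @export
slide_spec <- function(n_normal = NULL, n_abnormal = NULL, malignant = FALSE,
                       stemline_positions = NULL, fraction_9cEE = NULL,
                       n_per_other_class = NULL, measurement_cv = 3,
                       stemline_cv = 5, scale = 0.1, seed = 1L,
                       field_size = 256L, fixed_c = list()) {
  n_normal <- n_normal %||% round(3426 * scale)
  n_abnormal <- n_abnormal %||%
    (if (malignant) round(314 * scale) else round(44 * scale))
  stemline_positions <- stemline_positions %||%
    (if (malignant) c(2.0, 3.47) else 2.0)
  fraction_9cEE <- fraction_9cEE %||% (if (malignant) 0.02 else 0)
  n_per_other_class <- n_per_other_class %||%
    round(c(lymphocyte = 300, granulocyte = 200, doublet = 100,
            defocused = 100, lytic = 100, artefact = 150) * scale)
  euploid <- function(p) (p >= 1.8 & p <= 2.2) | (p >= 3.6 & p <= 4.4)
  if (!malignant) {
    if (!all(euploid(stemline_positions)))
      stop("benign slides must have euploid stemline positions")
    if (fraction_9cEE != 0)
      stop("benign slides must have fraction_9cEE = 0")
  }
  structure(list(
    n_normal = n_normal, n_abnormal = n_abnormal, malignant = malignant,
    stemline_positions = stemline_positions, fraction_9cEE = fraction_9cEE,
    n_per_other_class = n_per_other_class, measurement_cv = measurement_cv,
    stemline_cv = stemline_cv, seed = as.integer(seed),
    field_size = as.integer(field_size), fixed_c = fixed_c
  ), class = "slide_spec")
}

# Draw truth c-values for the abnormal population of a slide.
draw_abnormal_c <- function(n, spec) {
  if (n == 0) return(numeric(0))
  pos <- spec$stemline_positions
  comp <- sample(seq_along(pos), n, replace = TRUE)
  cv <- rnorm(n, pos[comp], pos[comp] * spec$stemline_cv / 100)
  cv <- pmax(cv, 0.2)
  if (!spec$malignant) {
    # truth invariant: benign slides never carry a >9c truth value
    cv <- pmin(cv, 8.5)
  } else if (spec$fraction_9cEE > 0) {
    n9 <- round(n * spec$fraction_9cEE)
    if (n9 > 0) cv[sample(n, n9)] <- runif(n9, 9.5, 12)
  }
  cv
}

# Greedy non-overlapping placement of object footprints into square fields.
place_objects <- function(half_sizes, field_size, max_tries = 200) {
  margin <- half_sizes + 2
  if (any(2 * margin >= field_size))
    stop("object of footprint ", max(2 * margin),
         " px cannot fit; increase field size to at least ",
         max(2 * margin) + 2, " px")
  n <- length(half_sizes)
  field <- integer(n); row <- numeric(n); col <- numeric(n)
  cur <- 1L
  placed_r <- list(); placed_c <- list(); placed_h <- list()
  pr <- numeric(0); pc <- numeric(0); ph <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      r <- runif(1, margin[i] + 1, field_size - margin[i])
      cc <- runif(1, margin[i] + 1, field_size - margin[i])
      if (!length(pr) || all((pr - r)^2 + (pc - cc)^2 >
                             (ph + half_sizes[i] + 2)^2)) {
        ok <- TRUE; break
      }
    }
    if (!ok) { # field full: open the next one
      cur <- cur + 1L
      pr <- numeric(0); pc <- numeric(0); ph <- numeric(0)
      r <- runif(1, margin[i] + 1, field_size - margin[i])
      cc <- runif(1, margin[i] + 1, field_size - margin[i])
    }
    field[i] <- cur; row[i] <- r; col[i] <- cc
    pr <- c(pr, r); pc <- c(pc, cc); ph <- c(ph, half_sizes[i])
  }
  data.frame(field = field, row = row, col = col)
}

#' Render a full synthetic slide
#'
#' Generates every object of a [slide_spec()], packs the objects into as
#' many square scan fields as needed (masks of distinct objects are
#' disjoint), and renders each field as a 7-plane focal stack with a gently
#' shaded background. Per-object transmittances compose multiplicatively,
#' so optical densities of (deliberately) overlapping doublet lobes add.
#'
#' @param spec a [slide_spec()].
#' @param config see [karyo_config()].
#' @param render if `FALSE`, skip image rendering and return the ground
#'   truth only, with a simulated measured IOD column (the densitometric
#'   fast path used for cohort-scale experiments).
#' @return A list with `fields` (list of h x w x 7 intensity arrays, NULL
#'   when `render = FALSE`), `truth` (data.frame: nucleus_id, field, class,
#'   c_value, target_iod, row, col, z_position, area_px and, when
#'   `render = FALSE`, measured_iod), `background` (per-field background
#'   intensity matrices) and the spec.
#' @export
render_slide <- function(spec, config = karyo_config(), render = TRUE) {
  set.seed(spec$seed)
  counts <- c(normal_epithelial = spec$n_normal, abnormal = spec$n_abnormal,
              spec$n_per_other_class)
  counts <- counts[counts > 0]
  if (sum(counts) < 1) stop("slide must contain at least one object")
  labels <- rep(names(counts), counts)
  labels <- sample(labels) # interleave classes across fields
  abn_c <- draw_abnormal_c(sum(labels == "abnormal"), spec)
  ai <- 0L
  specs <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    cl <- labels[i]
    cval <- NULL
    if (cl == "abnormal") { ai <- ai + 1L; cval <- abn_c[ai] }
    if (cl %in% names(spec$fixed_c)) cval <- spec$fixed_c[[cl]]
    specs[[i]] <- sample_nucleus_spec(cl, c_value = cval)
  }
  half <- vapply(specs, function(s) {
    ceiling(s$radius * (1 + 0.5 * s$shape_irregularity) *
              (if (s$class_label == "artefact") 3.2 else
                 if (s$class_label %in% c("doublet", "granulocyte")) 1.8 else 1)) +
      max(4, ceiling(2 * config$defocus_sigma_per_plane *
                       max(abs(0:6 - s$z_position))))
  }, numeric(1))
  pos <- place_objects(half, spec$field_size)
  truth <- data.frame(
    nucleus_id = sprintf("n%04d", seq_along(specs)),
    field = pos$field,
    class = vapply(specs, `[[`, "", "class_label"),
    c_value = vapply(specs, `[[`, 0, "c_value"),
    target_iod = NA_real_,
    row = pos$row, col = pos$col,
    z_position = vapply(specs, `[[`, 0L, "z_position"),
    radius = vapply(specs, `[[`, 0, "radius"),
    area_px = NA_real_,
    stringsAsFactors = FALSE
  )
  n_fields <- max(pos$field)
  fs <- spec$field_size
  backgrounds <- vector("list", n_fields)
  masks <- vector("list", length(specs))
  if (!render) {
    truth$target_iod <- vapply(seq_along(specs), function(i) {
      spec_target_iod(specs[[i]], config) *
        (1 + rnorm(1) * spec$measurement_cv / 100)
    }, numeric(1))
    truth$measured_iod <- truth$target_iod
    return(list(fields = NULL, truth = truth, background = NULL, spec = spec))
  }
  fields <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    # linear illumination ramp (shading) in a random direction
    ang <- runif(1, 0, 2 * pi)
    rr <- matrix(seq_len(fs) - fs / 2, fs, fs)
    cc <- matrix(seq_len(fs) - fs / 2, fs, fs, byrow = TRUE)
    ramp <- (cos(ang) * rr + sin(ang) * cc) / fs
    bg <- config$background_level * (1 + config$shading_amplitude * 2 * ramp)
    backgrounds[[f]] <- bg
    trans <- array(1, c(fs, fs, config$n_planes))
    idx <- which(pos$field == f)
    for (i in idx) {
      rn <- render_nucleus(specs[[i]], background_level = 1, config = config,
                           measurement_cv = spec$measurement_cv,
                           planes = 0:(config$n_planes - 1), camera_noise_sd = 0)
      truth$target_iod[i] <- rn$truth$target_iod
      truth$area_px[i] <- rn$truth$area_px
      masks[[i]] <- rn$mask
      half_i <- (nrow(rn$mask) - 1) / 2
      r0 <- round(pos$row[i]) - half_i; c0 <- round(pos$col[i]) - half_i
      rs <- r0 + seq_len(nrow(rn$mask)) - 1
      cs <- c0 + seq_len(ncol(rn$mask)) - 1
      keep_r <- rs >= 1 & rs <= fs; keep_c <- cs >= 1 & cs <= fs
      for (p in seq_len(config$n_planes)) {
        trans[rs[keep_r], cs[keep_c], p] <-
          trans[rs[keep_r], cs[keep_c], p] * rn$stack[keep_r, keep_c, p]
      }
    }
    stack <- array(0, c(fs, fs, config$n_planes))
    for (p in seq_len(config$n_planes)) {
      img <- bg * trans[, , p]
      if (config$camera_noise_sd > 0)
        img <- img + rnorm(length(img), 0, config$camera_noise_sd)
      stack[, , p] <- pmax(img, 0.5)
    }
    fields[[f]] <- stack
  }
  list(fields = fields, truth = truth, background = backgrounds,
       masks = masks, spec = spec)
}

#' Specification of a synthetic cohort of slides
#'
#' @param n_positive_slides,n_negative_slides slide counts; the study-sized
#'   default is 25 positive / 67 negative follow-up.
#' @param seed cohort RNG seed; per-slide seeds are derived from it.
#' @param ... further arguments passed to every [slide_spec()] (for
#'   example `scale`, `measurement_cv`, `n_normal`).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_positive_slides = 25, n_negative_slides = 67,
                        seed = 1L, ...) {
  if (n_positive_slides + n_negative_slides < 1)
    stop("cohort must contain at least one slide")
  structure(list(n_positive_slides = n_positive_slides,
                 n_negative_slides = n_negative_slides,
                 seed = as.integer(seed), slide_args = list(...)),
            class = "cohort_spec")
}

#' Simulate a cohort of slides with a ground-truth manifest
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory; when given, per-field multi-page TIFF
#'   stacks, `truth.csv` and `manifest.json` are written there.
#' @param config see [karyo_config()].
#' @param render render images (`TRUE`) or ground-truth tables only.
#' @return A list with `manifest` (data.frame: slide_id, malignant, seed),
#'   `slides` (list of [render_slide()] results) and `spec`.
#' @export
simulate_cohort <- function(spec, out_dir = NULL, config = karyo_config(),
                            render = TRUE) {
  set.seed(spec$seed)
  n <- spec$n_positive_slides + spec$n_negative_slides
  truth_flags <- rep(c(TRUE, FALSE),
                     c(spec$n_positive_slides, spec$n_negative_slides))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  slide_ids <- sprintf("slide%03d", seq_len(n))
  slides <- vector("list", n)
  for (i in seq_len(n)) {
    args <- c(list(malignant = truth_flags[i], seed = seeds[i]),
              spec$slide_args)
    sl <- render_slide(do.call(slide_spec, args), config = config,
                       render = render)
    sl$truth$slide_id <- slide_ids[i]
    slides[[i]] <- sl
  }
  manifest <- data.frame(slide_id = slide_ids, malignant = truth_flags,
                         seed = seeds,
                         n_objects = vapply(slides, function(s) nrow(s$truth), 0))
  res <- list(manifest = manifest, slides = slides, spec = spec)
  if (!is.null(out_dir)) write_cohort(res, out_dir)
  res
}

# Serialize a simulated cohort: multi-page TIFFs, truth.csv, manifest.json.
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth_all <- do.call(rbind, lapply(cohort$slides, `[[`, "truth"))
  write.csv(truth_all, file.path(out_dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(slides = cohort$manifest,
         spec = cohort$spec[c("n_positive_slides", "n_negative_slides", "seed")]),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  for (i in seq_along(cohort$slides)) {
    sl <- cohort$slides[[i]]
    if (is.null(sl$fields)) next
    for (f in seq_along(sl$fields)) {
      pages <- lapply(seq_len(dim(sl$fields[[f]])[3]),
                      function(p) pmin(pmax(sl$fields[[f]][, , p] / 255, 0), 1))
      tiff::writeTIFF(pages, file.path(out_dir,
        sprintf("%s_field%02d.tif", cohort$manifest$slide_id[i], f)),
        bits.per.sample = 16)
    }
  }
  invisible(out_dir)
}

#' Read a focal-stack TIFF written by [write_cohort()]
#'
#' @param path multi-page TIFF file.
#' @return h x w x planes intensity array on the 0-255 scale.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  array(unlist(pages), c(dim(pages[[1]]), length(pages))) * 255
}

#' Simulated reference-nucleus IODs for calibration experiments
#'
#' Draws a lognormal reference population with a given coefficient of
#' variation and contaminates a fraction of it with multiplicative
#' outliers, emulating misclassified or degenerate reference nuclei.
#'
#' @param n number of IODs.
#' @param mean_iod population mean IOD.
#' @param cv percent coefficient of variation of the clean population.
#' @param outlier_fraction fraction of values replaced by outliers.
#' @param outlier_factor multiplicative offset of the outliers.
#' @return Numeric vector of IODs.
#' @export
simulate_reference_iods <- function(n = 50, mean_iod = 100, cv = 6,
                                    outlier_fraction = 0.02,
                                    outlier_factor = 1.5) {
  s2 <- log(1 + (cv / 100)^2)
  x <- rlnorm(n, meanlog = log(mean_iod) - s2 / 2, sdlog = sqrt(s2))
  k <- round(n * outlier_fraction)
  if (k > 0) x[sample(n, k)] <- mean_iod * outlier_factor
  x
}

#' Simulated measured c-values of an abnormal population
#'
#' Densitometric fast path: draws c-values from a stemline mixture with a
#' population width and multiplies in per-nucleus measurement noise,
#' without rendering any image.
#'
#' @param n number of nuclei.
#' @param stemline_positions modal c-values.
#' @param weights mixture weights (recycled, normalized).
#' @param stemline_cv percent width of each stemline population.
#' @param measurement_cv percent measurement noise.
#' @param fraction_9cEE fraction of draws replaced by values above 9c.
#' @return Numeric vector of measured c-values.
#' @export
simulate_c_values <- function(n, stemline_positions = 2.0, weights = 1,
                              stemline_cv = 5, measurement_cv = 3,
                              fraction_9cEE = 0) {
  w <- rep_len(weights, length(stemline_positions))
  comp <- sample(seq_along(stemline_positions), n, replace = TRUE,
                 prob = w / sum(w))
  x <- rnorm(n, stemline_positions[comp],
             stemline_positions[comp] * stemline_cv / 100)
  x <- x * (1 + rnorm(n) * measurement_cv / 100)
  n9 <- round(n * fraction_9cEE)
  if (n9 > 0) x[sample(n, n9)] <- runif(n9, 9.5, 12)
  pmax(x, 0.1)
}
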