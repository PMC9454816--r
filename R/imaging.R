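#' Construct a focal stack
#'
#' @param planes h x w x n intensity array, a list of equally sized
#'   matrices, or a single matrix (promoted to one plane).
#' @param n_planes expected number of planes (default 7).
#' @return An h x w x n array of class `focal_stack`.
#' @export
focal_stack <- function(planes, n_planes = 7L) {
  if (is.list(planes)) {
    d <- dim(planes[[1]])
    if (!all(vapply(planes, function(p) identical(dim(p), d), TRUE)))
      stop("all planes must have identical dimensions")
    planes <- array(unlist(planes), c(d, length(planes)))
  }
  if (is.matrix(planes)) planes <- array(planes, c(dim(planes), 1L))
  if (dim(planes)[3] != n_planes)
    stop("expected ", n_planes, " planes, got ", dim(planes)[3])
  structure(planes, class = c("focal_stack", class(planes)))
}

# Collapse RGB input to the densitometric channel (green for
# pararosaniline; configurable for thionine-stained material).
as_gray <- function(img, channel = 2L) {
  if (length(dim(img)) == 3 && dim(img)[3] %in% c(3L, 4L)) img[, , channel]
  else img
}

#' Estimate the background illumination field of a stack
#'
#' Background (object-free) pixels are identified on the per-pixel maximum
#' projection across planes (background is bright in brightfield and
#' unaffected by focus); a second-order polynomial illumination surface is
#' then fitted to them, capturing shading ramps without following nuclei.
#'
#' @param stack a [focal_stack()] or h x w x n array.
#' @param config see [karyo_config()].
#' @return h x w matrix of strictly positive background intensities.
#' @export
estimate_background <- function(stack, config = karyo_config()) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  proj <- apply(stack, c(1, 2), max)
  thr <- otsu_threshold(as.numeric(proj))
  bgmask <- proj > thr
  # uniform image: everything is background
  if (diff(range(proj)) < 1e-6) bgmask[] <- TRUE
  if (mean(bgmask) < 0.05)
    stop("no background estimable: too few bright pixels")
  rr <- as.numeric(row(proj)); cc <- as.numeric(col(proj))
  df <- data.frame(v = as.numeric(proj), r = rr / nrow(proj),
                   c = cc / ncol(proj))
  fit <- lm(v ~ poly(r, 2, raw = TRUE) + poly(c, 2, raw = TRUE) + r:c,
            data = df[bgmask, ])
  bg <- matrix(predict(fit, df), nrow(proj), ncol(proj))
  pmax(bg, 1e-3)
}

#' Convert intensity to optical density
#'
#' `OD = log10(background / clip(image, 1, background))`; saturated or
#' brighter-than-background pixels clip to OD 0, so the result is always
#' non-negative.
#'
#' @param image intensity matrix.
#' @param background matching background matrix (or scalar), > 0.
#' @return Optical-density matrix.
#' @export
to_optical_density <- function(image, background) {
  if (any(background <= 0)) stop("background must be positive everywhere")
  log10(background / pmin(pmax(image, 1), background))
}

#' Segment nuclei in an optical-density image
#'
#' Otsu threshold on OD (with a small stain floor), morphological opening
#' with a radius-1 disc, hole filling, connected-component labelling and an
#' area filter. Overlapping nuclei come out as single objects (candidate
#' doublets); they are never split.
#'
#' @param od_image optical-density matrix.
#' @param config see [karyo_config()] (`min_area_px`, `max_area_px`,
#'   `od_floor`).
#' @return List of `nucleus_object` lists: `object_id`, `mask` (logical
#'   matrix), `bbox` (r0, r1, c0, c1; half-open, 0-based), `centroid`
#'   (row, col), `area_px`.
#' @export
segment_nuclei <- function(od_image, config = karyo_config()) {
  thr <- max(otsu_threshold(as.numeric(od_image)), config$od_floor)
  bw <- od_image > thr
  if (!any(bw)) return(list())
  bw <- EBImage::opening(bw, EBImage::makeBrush(3, "disc"))
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(lab), nrow(od_image))
  objs <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    a <- nrow(idx)
    if (a < config$min_area_px || a > config$max_area_px) next
    mask <- lab == k
    objs[[length(objs) + 1]] <- structure(list(
      object_id = length(objs) + 1L,
      mask = mask,
      bbox = c(r0 = min(idx[, 1]) - 1L, r1 = max(idx[, 1]),
               c0 = min(idx[, 2]) - 1L, c1 = max(idx[, 2])),
      centroid = c(mean(idx[, 1]), mean(idx[, 2])),
      area_px = a
    ), class = "nucleus_object")
  }
  objs
}

# Focus metric: variance of the 4-neighbour Laplacian over a bbox window.
laplacian_variance <- function(img) {
  n <- nrow(img); m <- ncol(img)
  if (n < 3 || m < 3) return(0)
  core <- img[2:(n - 1), 2:(m - 1)]
  lap <- img[1:(n - 2), 2:(m - 1)] + img[3:n, 2:(m - 1)] +
    img[2:(n - 1), 1:(m - 2)] + img[2:(n - 1), 3:m] - 4 * core
  var(as.numeric(lap))
}

#' Select per-object best focus and fuse the stack
#'
#' For each detected object, the plane maximizing the variance of the
#' Laplacian over the object's bounding box is selected (ties break to the
#' lowest plane index); the object's pixels in the fused image are copied
#' from that plane. Pixels belonging to no object come from the globally
#' sharpest plane. This extends the depth of focus: every fused pixel value
#' exists at the same coordinate in some plane.
#'
#' @param stack a [focal_stack()] or h x w x n intensity array.
#' @param objects preliminary detections from [segment_nuclei()].
#' @param per_pixel if `TRUE`, fuse by per-pixel sharpest plane instead of
#'   per object (alternative fusion mode).
#' @return List: `fused` (intensity matrix), `objects` (input objects with
#'   `best_plane` in 0..n-1 and `focus_score` added), `global_best_plane`.
#' @export
fuse_focal_stack <- function(stack, objects, per_pixel = FALSE) {
  np <- dim(stack)[3]
  gscore <- vapply(seq_len(np), function(p) laplacian_variance(stack[, , p]),
                   numeric(1))
  gbest <- which.max(gscore) # ties: lowest index
  fused <- stack[, , gbest]
  if (per_pixel) {
    sharp <- array(0, dim(stack))
    for (p in seq_len(np)) {
      lap <- stack[, , p]
      padded <- rbind(lap[1, ], lap, lap[nrow(lap), ])
      padded <- cbind(padded[, 1], padded, padded[, ncol(padded)])
      n <- nrow(lap); m <- ncol(lap)
      l <- padded[1:n, 2:(m + 1)] + padded[3:(n + 2), 2:(m + 1)] +
        padded[2:(n + 1), 1:m] + padded[2:(n + 1), 3:(m + 2)] - 4 * lap
      sharp[, , p] <- abs(l)
    }
    best <- apply(sharp, c(1, 2), which.max)
    for (p in seq_len(np)) {
      sel <- best == p
      fused[sel] <- stack[, , p][sel]
    }
    return(list(fused = fused, objects = objects,
                global_best_plane = gbest - 1L))
  }
  for (i in seq_along(objects)) {
    b <- objects[[i]]$bbox
    rows <- (b["r0"] + 1):b["r1"]; cols <- (b["c0"] + 1):b["c1"]
    scores <- vapply(seq_len(np), function(p)
      laplacian_variance(stack[rows, cols, p]), numeric(1))
    bp <- which.max(scores)
    objects[[i]]$best_plane <- bp - 1L
    objects[[i]]$focus_score <- scores[bp]
    sel <- objects[[i]]$mask
    plane <- stack[, , bp]
    fused[sel] <- plane[sel]
  }
  list(fused = fused, objects = objects, global_best_plane = gbest - 1L)
}

#' Scan one focal stack end to end
#'
#' Background estimation, preliminary segmentation on the maximum-OD
#' projection (so every object is crisp at its own sharp plane), per-object
#' best-focus selection, and fused OD computation.
#'
#' @param stack a [focal_stack()] or h x w x n intensity array.
#' @param config see [karyo_config()].
#' @return List: `objects` (with best_plane, focus_score), `od` (fused OD
#'   image), `background`, `global_best_plane`.
#' @export
scan_stack <- function(stack, config = karyo_config()) {
  stack <- unclass(stack)
  bg <- estimate_background(stack, config)
  np <- dim(stack)[3]
  od_max_proj <- to_optical_density(stack[, , 1], bg)
  for (p in seq_len(np)[-1])
    od_max_proj <- pmax(od_max_proj, to_optical_density(stack[, , p], bg))
  objs <- segment_nuclei(od_max_proj, config)
  fu <- fuse_focal_stack(stack, objs)
  od <- to_optical_density(fu$fused, bg)
  # per-object OD from each object's own best plane
  for (ob in fu$objects) {
    sel <- ob$mask
    plane_od <- to_optical_density(stack[, , ob$best_plane + 1L], bg)
    od[sel] <- plane_od[sel]
  }
  list(objects = fu$objects, od = od, background = bg,
       global_best_plane = fu$global_best_plane)
}

#' Scan all fields of a rendered slide
#'
#' Runs [scan_stack()] on every field of a [render_slide()] result and
#' returns one measurement row per segmented object.
#'
#' @param slide result of [render_slide()] (with images).
#' @param config see [karyo_config()].
#' @return data.frame: object_id, field, row, col, area_px, best_plane,
#'   focus_score, iod — plus the per-field scan results in attribute
#'   `scans`.
#' @export
scan_slide <- function(slide, config = karyo_config()) {
  stopifnot(!is.null(slide$fields))
  rows <- list()
  scans <- vector("list", length(slide$fields))
  oid <- 0L
  for (f in seq_along(slide$fields)) {
    sc <- scan_stack(slide$fields[[f]], config)
    scans[[f]] <- sc
    for (ob in sc$objects) {
      oid <- oid + 1L
      rows[[oid]] <- data.frame(
        object_id = sprintf("o%04d", oid), field = f,
        row = ob$centroid[1], col = ob$centroid[2], area_px = ob$area_px,
        best_plane = ob$best_plane, focus_score = ob$focus_score,
        iod = integrated_optical_density(ob, sc$od))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(object_id = character(), field = integer(), row = numeric(),
               col = numeric(), area_px = numeric(), best_plane = integer(),
               focus_score = numeric(), iod = numeric())
  attr(out, "scans") <- scans
  out
}

#' Match segmented objects to simulator ground truth
#'
#' Greedy nearest-centroid matching between a scan table and the slide's
#' truth table, within a distance gate.
#'
#' @param scan data.frame from [scan_slide()].
#' @param truth truth data.frame from [render_slide()].
#' @param max_dist maximum centroid distance in px for a match.
#' @return `scan` with matched `truth_id`, `truth_class`, `truth_c`,
#'   `truth_iod`, `truth_z` columns (NA where unmatched).
#' @export
match_truth <- function(scan, truth, max_dist = 12) {
  scan$truth_id <- NA_character_
  scan$truth_class <- NA_character_
  scan$truth_c <- NA_real_
  scan$truth_iod <- NA_real_
  scan$truth_z <- NA_integer_
  for (f in unique(scan$field)) {
    si <- which(scan$field == f)
    ti <- which(truth$field == f)
    if (!length(ti)) next
    used <- logical(length(ti))
    for (i in si) {
      d <- sqrt((truth$row[ti] - scan$row[i])^2 +
                  (truth$col[ti] - scan$col[i])^2)
      d[used] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= max_dist) {
        used[j] <- TRUE
        k <- ti[j]
        scan$truth_id[i] <- truth$nucleus_id[k]
        scan$truth_class[i] <- truth$class[k]
        scan$truth_c[i] <- truth$c_value[k]
        scan$truth_iod[i] <- truth$target_iod[k]
        scan$truth_z[i] <- truth$z_position[k]
      }
    }
  }
  scan
}
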