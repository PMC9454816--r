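# shared fixture builders for the test suite (everything generated in code)

# rasterized solid disc / ellipse masks on a square canvas
disc_mask <- function(r, size = 2 * r + 11) {
  ctr <- (size + 1) / 2
  d2 <- (row(matrix(0, size, size)) - ctr)^2 +
    (col(matrix(0, size, size)) - ctr)^2
  d2 <= r^2
}

ellipse_mask <- function(a, b, size = 2 * max(a, b) + 11) {
  ctr <- (size + 1) / 2
  rr <- row(matrix(0, size, size)) - ctr
  cc <- col(matrix(0, size, size)) - ctr
  (cc / a)^2 + (rr / b)^2 <= 1
}

# small, quick-to-render slide composition used across tests
tiny_slide_spec <- function(seed = 1, malignant = FALSE, ...) {
  args <- list(
    n_normal = 40,
    n_abnormal = if (malignant) 15 else 3,
    malignant = malignant,
    n_per_other_class = c(lymphocyte = 5, granulocyte = 4, doublet = 3,
                          defocused = 3, lytic = 3, artefact = 3),
    seed = seed)
  do.call(slide_spec, modifyList(args, list(...)))
}

# intersection-over-union between a truth patch mask (centred at the truth
# row/col) and a detected object mask in field coordinates
mask_iou <- function(truth_mask, truth_row, truth_col, det_mask) {
  fs <- nrow(det_mask)
  tm <- matrix(FALSE, fs, fs)
  half <- (nrow(truth_mask) - 1) / 2
  r0 <- round(truth_row) - half; c0 <- round(truth_col) - half
  rs <- r0 + seq_len(nrow(truth_mask)) - 1
  cs <- c0 + seq_len(ncol(truth_mask)) - 1
  ok_r <- rs >= 1 & rs <= fs; ok_c <- cs >= 1 & cs <= fs
  tm[rs[ok_r], cs[ok_c]] <- truth_mask[ok_r, ok_c]
  sum(tm & det_mask) / sum(tm | det_mask)
}
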