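# Compartment quantification: background subtraction, integrated
# intensities and concentrations with cytoplasm-by-subtraction, top-k
# brightest-pixel estimators, two-ROI cytoplasmic means, N/C ratios and
# trace normalization/smoothing.

#' Estimate the image background from off-cell regions
#'
#' Mean intensity over square ROIs placed automatically on background
#' (away from any cell by a safety margin), emulating manually drawn
#' off-cell regions.
#'
#' @param img numeric matrix.
#' @param cell_labels integer label matrix (0 = background).
#' @param n_rois number of ROIs.
#' @param roi_size ROI side length, px.
#' @param margin dilation of the cell mask, px, that ROIs must avoid.
#' @return mean background level, a.u./px.
#' @export
estimate_background <- function(img, cell_labels, n_rois = 5,
                                roi_size = 15, margin = 5) {
  if (!any(cell_labels == 0)) stop("no background pixels", call. = FALSE)
  avoid <- cell_labels > 0
  if (margin > 0 && any(avoid))
    avoid <- as.matrix(EBImage::dilate(avoid + 0,
                                       EBImage::makeBrush(2 * margin + 1,
                                                          "disc"))) > 0
  H <- nrow(img); W <- ncol(img)
  vals <- c(); found <- 0
  step <- roi_size + 2
  for (r0 in seq(1, H - roi_size + 1, by = step)) {
    for (c0 in seq(1, W - roi_size + 1, by = step)) {
      rr <- r0:(r0 + roi_size - 1); cc <- c0:(c0 + roi_size - 1)
      if (!any(avoid[rr, cc])) {
        vals <- c(vals, mean(img[rr, cc]))
        found <- found + 1
        if (found >= n_rois) return(mean(vals))
      }
    }
  }
  if (!found) stop("no background region large enough for an ROI",
                   call. = FALSE)
  mean(vals)
}

#' Measure one cell in one frame
#'
#' Background-subtracted integrated intensities and concentrations of
#' whole cell, nucleus and cytoplasm. The cytoplasm is obtained by
#' subtraction: `I_cyt = I_cell - I_nuc`, `A_cyt = A_cell - A_nuc`, and
#' `c_cyt = (I_cell - I_nuc) / (A_cell - A_nuc)`. Negative
#' background-corrected integrals are clamped at 0 and flagged.
#'
#' @param img numeric matrix.
#' @param cell_mask,nucleus_mask logical matrices; the nucleus must lie
#'   inside the cell.
#' @param b background level per pixel (>= 0).
#' @return one-row data frame with areas (px^2), intensities (a.u.),
#'   concentrations (a.u./px^2) and a `clamped` flag; `c_cyt` is `NA`
#'   when `A_cyt = 0`.
#' @export
measure_cell <- function(img, cell_mask, nucleus_mask, b = 0) {
  stopifnot(b >= 0)
  nucleus_mask <- nucleus_mask & cell_mask
  A_cell <- sum(cell_mask); A_nuc <- sum(nucleus_mask)
  A_cyt <- A_cell - A_nuc
  I_cell_raw <- sum(img[cell_mask]) - b * A_cell
  I_nuc_raw <- sum(img[nucleus_mask]) - b * A_nuc
  clamped <- I_cell_raw < 0 || I_nuc_raw < 0
  I_cell <- max(I_cell_raw, 0)
  I_nuc <- max(I_nuc_raw, 0)
  I_nuc <- min(I_nuc, I_cell) # keep the decomposition identity with clamping
  I_cyt <- I_cell - I_nuc
  data.frame(A_cell = A_cell, A_nuc = A_nuc, A_cyt = A_cyt,
             I_cell = I_cell, I_nuc = I_nuc, I_cyt = I_cyt,
             c_cell = if (A_cell > 0) I_cell / A_cell else NA_real_,
             c_nuc = if (A_nuc > 0) I_nuc / A_nuc else NA_real_,
             c_cyt = if (A_cyt > 0) I_cyt / A_cyt else NA_real_,
             b = b, clamped = clamped)
}

#' Mean of the k brightest pixels in a cell
#'
#' @param img numeric matrix.
#' @param mask logical matrix selecting the cell.
#' @param k number of brightest pixels (default 40).
#' @param cell_id used in the error message when the cell is too small.
#' @return mean of the k largest in-mask values, a.u.
#' @export
topk_mean <- function(img, mask, k = 40, cell_id = NULL) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  v <- img[mask]
  if (length(v) < k)
    stop_config("cell %s has %d pixels, fewer than k = %d",
                cell_id %||% "?", length(v), k)
  mean(sort(v, decreasing = TRUE)[seq_len(k)])
}

#' Cytoplasmic mean from two ROIs flanking the nucleus
#'
#' Two disc ROIs are auto-placed on the cell long axis on either side of
#' the nucleus (emulating manually placed cytoplasmic regions). If an
#' ROI collides with the nucleus it is pushed outward once; a second
#' collision is an error.
#'
#' @param img numeric matrix.
#' @param cell_mask,nucleus_mask logical matrices.
#' @param roi_radius ROI radius, px.
#' @param gap gap between the nuclear boundary and the ROI edge, px.
#' @return mean intensity over the two ROIs, a.u.
#' @export
two_roi_cytoplasm <- function(img, cell_mask, nucleus_mask,
                              roi_radius = 4, gap = 2) {
  idxc <- which(cell_mask, arr.ind = TRUE)
  idxn <- which(nucleus_mask, arr.ind = TRUE)
  if (!nrow(idxn)) stop("empty nucleus mask", call. = FALSE)
  cen <- colMeans(idxn)
  # cell long axis by principal component of the mask
  ax <- principal_axis(idxc)
  r_nuc <- sqrt(nrow(idxn) / pi)
  make_roi <- function(offset, sign) {
    ctr <- cen + sign * offset * ax
    d2 <- (idxc[, 1] - ctr[1])^2 + (idxc[, 2] - ctr[2])^2
    idxc[d2 <= roi_radius^2, , drop = FALSE]
  }
  roi_vals <- lapply(c(-1, 1), function(s) {
    off <- r_nuc + gap + roi_radius
    for (attempt in 1:2) {
      roi <- make_roi(off, s)
      if (nrow(roi) == 0) stop("ROI falls outside the cell", call. = FALSE)
      inside_nuc <- nucleus_mask[roi]
      if (!any(inside_nuc)) return(img[roi])
      off <- off + roi_radius + gap   # reposition once, further out
    }
    stop("cytoplasmic ROI collides with the nucleus after repositioning",
         call. = FALSE)
  })
  mean(unlist(roi_vals))
}

principal_axis <- function(idx) {
  cen <- colMeans(idx)
  d <- sweep(idx, 2, cen)
  e <- eigen(crossprod(d) / nrow(idx), symmetric = TRUE)
  ax <- e$vectors[, 1]
  if (ax[2] < 0 || (ax[2] == 0 && ax[1] < 0)) ax <- -ax # fixed orientation
  ax
}

#' Nucleocytoplasmic ratio and reference normalization
#'
#' `nc_ratio` divides nuclear by cytoplasmic concentration;
#' `normalize_to_reference` divides ratios by the mean ratio of a
#' reference (wild-type) population, as done within each experiment.
#'
#' @param meas data frame with columns `c_nuc`, `c_cyt` (one or more
#'   rows).
#' @return numeric vector of ratios; `NA` where `c_cyt <= 0`.
#' @export
nc_ratio <- function(meas) {
  r <- meas$c_nuc / meas$c_cyt
  r[!is.finite(r) | meas$c_cyt <= 0] <- NA_real_
  r
}

#' @rdname nc_ratio
#' @param ratios,reference numeric vectors of N/C ratios.
#' @export
normalize_to_reference <- function(ratios, reference) {
  reference <- reference[is.finite(reference)]
  if (!length(reference)) stop("reference is empty", call. = FALSE)
  ratios / mean(reference)
}

#' Min-max normalize a trace to [0, 1]
#'
#' @param x numeric vector spanning one cell cycle.
#' @return `(x - min) / (max - min)`; errors on a constant trace.
#' @export
minmax_normalize <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!(rng[2] > rng[1]))
    stop("constant trace: min-max normalization is degenerate",
         call. = FALSE)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Loess smoothing of a single-cell trace
#'
#' Locally weighted quadratic regression with tricube weights
#' (`stats::loess`, `degree = 2`, exact `surface = "direct"` fit),
#' evaluated at the observed times. Default span 0.3. When the span
#' covers too few points for a quadratic local fit the degree is
#' reduced to 1 with a warning.
#'
#' @param t,y numeric vectors (>= 5 points).
#' @param span fraction of points in each local fit, in (0, 1].
#' @return smoothed values at `t`.
#' @export
loess_smooth <- function(t, y, span = 0.3) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  n <- length(y)
  if (n < 5) stop("need at least 5 points", call. = FALSE)
  degree <- 2
  q <- floor(n * span)
  if (q < 4) {
    degree <- 1
    # widen so each local line still sees >= 4 neighbors
    span <- max(span, min(1, 4.5 / n))
    warning("span covers too few points for a quadratic fit; using degree 1")
  }
  fit <- stats::loess(y ~ t, span = span, degree = degree,
                      family = "gaussian", surface = "direct")
  unname(stats::predict(fit, t))
}
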