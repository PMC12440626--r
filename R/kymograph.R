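# Space-time (kymograph) images of single cells.

#' Build a kymograph for one cell
#'
#' For each (subsampled) frame the cell is projected onto its long axis
#' (principal axis of the cell mask) and the axial intensity profile
#' (max across the short axis by default, mean optional) becomes one
#' column. The row extent covers the maximal cell length over the
#' window, so positions are comparable across frames.
#'
#' @param movie a `movie` object.
#' @param cell truth label of the cell.
#' @param channel channel name.
#' @param subsample keep every `subsample`-th frame.
#' @param mode `"max"` or `"mean"` across the short axis.
#' @param masks optional list of label matrices to use instead of the
#'   truth cell labels.
#' @return a `kymograph`: list with `image` (rows = axial position,
#'   columns = frames), `positions_um`, `times`, `channel`, `subsample`,
#'   `blank_frames` (frames where the cell was absent).
#' @export
build_kymograph <- function(movie, cell, channel, subsample = 1,
                            mode = c("max", "mean"), masks = NULL) {
  mode <- match.arg(mode)
  if (is.null(masks)) masks <- movie$cell_labels
  f_idx <- seq(1, length(movie$times), by = subsample)
  px <- movie$optics$pixel_size

  # common axial grid across the window
  half_len <- 0
  axes <- vector("list", length(f_idx))
  cents <- vector("list", length(f_idx))
  for (j in seq_along(f_idx)) {
    idx <- which(masks[[f_idx[j]]] == cell, arr.ind = TRUE)
    if (!nrow(idx)) next
    cents[[j]] <- colMeans(idx)
    axes[[j]] <- principal_axis(idx)
    proj <- (idx[, 1] - cents[[j]][1]) * axes[[j]][1] +
      (idx[, 2] - cents[[j]][2]) * axes[[j]][2]
    half_len <- max(half_len, max(abs(proj)))
  }
  if (half_len == 0) stop_config("cell %s never appears in the window", cell)
  breaks <- seq(-ceiling(half_len) - 0.5, ceiling(half_len) + 0.5, by = 1)
  nrows <- length(breaks) - 1
  img <- matrix(NA_real_, nrows, length(f_idx))
  blank <- integer()
  for (j in seq_along(f_idx)) {
    f <- f_idx[j]
    idx <- which(masks[[f]] == cell, arr.ind = TRUE)
    if (!nrow(idx)) { blank <- c(blank, f); next }
    proj <- (idx[, 1] - cents[[j]][1]) * axes[[j]][1] +
      (idx[, 2] - cents[[j]][2]) * axes[[j]][2]
    vals <- movie$frames[[f]][[channel]][idx]
    bin <- cut(proj, breaks, labels = FALSE)
    agg <- tapply(vals, bin, if (mode == "max") max else mean)
    img[as.integer(names(agg)), j] <- agg
  }
  structure(list(image = img,
                 positions_um = (breaks[-1] - 0.5) * px,
                 times = movie$times[f_idx], channel = channel,
                 subsample = subsample, blank_frames = blank),
            class = "kymograph")
}

#' Write a kymograph as CSV (profile matrix) and optionally TIFF
#' @param kym a `kymograph`.
#' @param csv_path path of the CSV profile matrix.
#' @param tiff_path optional path of a 16-bit TIFF rendering.
#' @export
write_kymograph <- function(kym, csv_path, tiff_path = NULL) {
  m <- kym$image
  utils::write.csv(data.frame(position_um = kym$positions_um, m),
                   csv_path, row.names = FALSE)
  if (!is.null(tiff_path)) {
    x <- m; x[!is.finite(x)] <- 0
    tiff::writeTIFF(pmin(pmax(x, 0), 65535) / 65535, tiff_path,
                    bits.per.sample = 16)
  }
  invisible(csv_path)
}
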