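# Classical segmentation: Gaussian blur + global Otsu threshold,
# connected labeling, hole filling, border-cell removal, centroid-based
# nucleus-to-cell assignment and greedy overlap tracking.

#' Otsu threshold of an image
#'
#' Global threshold maximizing between-class variance on a 256-bin
#' histogram of the min-max scaled image. Ties between equal-variance
#' cut points are broken toward the lower threshold. On 8-bit integer
#' data with `nbins = 256` this is exactly the exhaustive search over
#' all 255 cut points.
#'
#' @param x numeric matrix or vector.
#' @param nbins histogram bin count (default 256).
#' @return threshold on the original intensity scale: pixels strictly
#'   above it are foreground. `NA` (with a warning) for a constant
#'   image.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    warning("constant image: no Otsu threshold exists")
    return(NA_real_)
  }
  b <- pmin(floor((v - lo) / (hi - lo) * nbins), nbins - 1)
  h <- as.double(tabulate(b + 1L, nbins))
  w <- cumsum(h)                     # class-0 counts for cut after bin k
  m <- cumsum(h * (seq_len(nbins) - 1))
  wt <- w[nbins]; mt <- m[nbins]
  k <- seq_len(nbins - 1)
  w0 <- w[k]; w1 <- wt - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1)
  bcv[valid] <- (mt * w0[valid] - m[k][valid] * wt)^2 /
    (w0[valid] * w1[valid])
  kbest <- which.max(bcv)            # which.max takes the first = lowest tie
  lo + (kbest - 0.5) / nbins * (hi - lo)
}

label_mask <- function(mask, min_area = 0) {
  lab <- EBImage::bwlabel(EBImage::fillHull(mask))
  if (min_area > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0
    lab <- relabel_consecutive(lab)
  }
  m <- as.matrix(lab)
  storage.mode(m) <- "integer"
  m
}

relabel_consecutive <- function(lab) {
  u <- sort(unique(as.integer(lab[lab > 0])))
  if (!length(u)) return(lab)
  map <- integer(max(u)); map[u] <- seq_along(u)
  lab[lab > 0] <- map[as.integer(lab[lab > 0])]
  lab
}

#' Segment cells from an outline-proxy image
#'
#' Gaussian blur, Otsu threshold, hole filling and connected labeling,
#' with a minimum-area filter; optionally splits touching cells by a
#' distance-map watershed.
#'
#' @param img 2-D numeric matrix.
#' @param blur_sigma blur SD in px.
#' @param min_area minimum object area, px^2.
#' @param split_touching watershed-split touching objects.
#' @return integer label matrix (0 = background).
#' @export
segment_cells <- function(img, blur_sigma = 1, min_area = 200,
                          split_touching = FALSE) {
  if (length(img) == 0 || all(img == img[1]))
    return(matrix(0L, nrow(img), ncol(img)))
  x <- if (blur_sigma > 0) as.matrix(EBImage::gblur(img, blur_sigma)) else img
  thr <- otsu_threshold(x)
  mask <- x > thr
  if (split_touching) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = max(dm) / 2)
    lab <- as.matrix(lab); storage.mode(lab) <- "integer"
    if (min_area > 0) {
      sizes <- tabulate(lab[lab > 0])
      lab[lab %in% which(sizes < min_area)] <- 0L
      lab <- relabel_consecutive(lab)
    }
    return(lab)
  }
  label_mask(mask, min_area)
}

#' Segment nuclei from a nuclear-marker image
#'
#' Gaussian blur (smoothing the nuclear edges), global Otsu threshold,
#' hole filling, connected labeling.
#'
#' @param img 2-D numeric matrix.
#' @param blur_sigma blur SD in px (default 1.5).
#' @param min_area minimum nucleus area, px^2.
#' @return integer label matrix; a constant image yields an empty map
#'   with a warning.
#' @export
segment_nuclei <- function(img, blur_sigma = 1.5, min_area = 30) {
  if (blur_sigma < 0) stop("blur_sigma must be >= 0", call. = FALSE)
  x <- if (blur_sigma > 0) as.matrix(EBImage::gblur(img, blur_sigma)) else img
  if (all(x == x[1])) {
    warning("constant image: returning empty nucleus map")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  thr <- otsu_threshold(x)
  label_mask(x > thr, min_area)
}

#' Assign nuclei to cells by centroid position
#'
#' Each nucleus is assigned to the cell label under its centroid pixel;
#' nuclei whose centroid falls on background are dropped with a
#' recorded reason. A cell may hold two nuclei (post-anaphase).
#'
#' @param cells,nuclei integer label matrices of identical shape.
#' @return data frame `nucleus`, `cell` (0 = dropped), `reason`.
#' @export
assign_nuclei <- function(cells, nuclei) {
  if (!all(dim(cells) == dim(nuclei)))
    stop("cells and nuclei label maps must share shape", call. = FALSE)
  ids <- sort(unique(as.integer(nuclei[nuclei > 0])))
  if (!length(ids))
    return(data.frame(nucleus = integer(), cell = integer(),
                      reason = character()))
  out <- do.call(rbind, lapply(ids, function(id) {
    idx <- which(nuclei == id, arr.ind = TRUE)
    cen <- round(colMeans(idx))
    cell <- cells[cen[1], cen[2]]
    data.frame(nucleus = id, cell = as.integer(cell),
               reason = if (cell == 0) "centroid_on_background" else "")
  }))
  rownames(out) <- NULL
  out
}

#' Remove cells touching the image border
#'
#' @param cells integer label matrix.
#' @return list `labels` (filtered map) and `excluded` (removed ids).
#' @export
filter_border_cells <- function(cells) {
  border <- unique(as.integer(c(cells[1, ], cells[nrow(cells), ],
                                cells[, 1], cells[, ncol(cells)])))
  border <- border[border > 0]
  out <- cells
  if (length(border)) out[out %in% border] <- 0L
  list(labels = out, excluded = sort(border))
}

#' Track cells across frames by greedy maximal overlap
#'
#' Labels in frame f are linked to the track whose previous-frame region
#' they overlap most; unmatched regions start new track ids. When two
#' regions claim the same previous track (a split), the parent track
#' ends and both children get new ids with the parent recorded.
#'
#' @param label_maps list of integer label matrices (>= 1 frame).
#' @return data frame `frame`, `label`, `track`, `parent`.
#' @export
track_cells <- function(label_maps) {
  stopifnot(length(label_maps) >= 1)
  next_id <- 0L
  links <- list()
  prev <- NULL; prev_tracks <- NULL
  for (f in seq_along(label_maps)) {
    lab <- label_maps[[f]]
    ids <- sort(unique(as.integer(lab[lab > 0])))
    tr <- integer(length(ids)); par <- rep(NA_integer_, length(ids))
    if (!is.null(prev) && length(ids)) {
      # overlap counts between current labels and previous tracks
      best_prev <- vapply(ids, function(id) {
        ov <- prev[lab == id]
        ov <- ov[ov > 0]
        if (!length(ov)) return(NA_integer_)
        as.integer(names(sort(table(ov), decreasing = TRUE))[1])
      }, 1L)
      for (pid in unique(stats::na.omit(best_prev))) {
        claimants <- which(best_prev == pid)
        if (length(claimants) == 1) {
          tr[claimants] <- prev_tracks[as.character(pid)]
        } else {
          for (ci in claimants) {
            next_id <- next_id + 1L
            tr[ci] <- next_id
            par[ci] <- prev_tracks[as.character(pid)]
          }
        }
      }
    }
    for (i in seq_along(ids)) if (tr[i] == 0L) {
      next_id <- next_id + 1L
      tr[i] <- next_id
    }
    if (length(ids))
      links[[f]] <- data.frame(frame = f, label = ids, track = tr,
                               parent = par)
    prev <- lab
    prev_tracks <- stats::setNames(tr, ids)
  }
  out <- do.call(rbind, links)
  if (is.null(out)) out <- data.frame(frame = integer(), label = integer(),
                                      track = integer(), parent = integer())
  out
}
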