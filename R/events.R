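# Event detection (anaphase, SPB separation, Plo1 onset) and
# event-aligned ensemble pooling.

#' Detect anaphase (nuclear separation) per tracked cell
#'
#' Anaphase is called at the first frame in which the number of nuclei
#' assigned to a cell goes from 1 to >= 2 and remains >= 2 for at least
#' `persist` frames; single-frame splits are ignored.
#'
#' @param nucleus_counts data frame with columns `track`, `frame`,
#'   `n_nuclei` (one row per tracked cell per frame).
#' @param times frame times, min.
#' @param persist minimum number of consecutive frames with >= 2 nuclei.
#' @return data frame `track`, `anaphase_time` (`NA` when no persistent
#'   split occurs).
#' @export
detect_anaphase <- function(nucleus_counts, times, persist = 2) {
  out <- lapply(split(nucleus_counts, nucleus_counts$track), function(d) {
    d <- d[order(d$frame), ]
    two <- d$n_nuclei >= 2
    t_ana <- NA_real_
    runs <- rle(two)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    hit <- which(runs$values & runs$lengths >= persist)
    if (length(hit)) t_ana <- times[d$frame[starts[hit[1]]]]
    data.frame(track = d$track[1], anaphase_time = t_ana)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Local maxima (8-neighborhood) above med + m * MAD inside a mask.
# `smooth_sigma` applies a matched Gaussian filter before peak finding
# (pass 0 when the image is already smoothed).
find_foci <- function(img, mask, m = 6, smooth_sigma = 1) {
  if (smooth_sigma > 0) img <- as.matrix(EBImage::gblur(img, smooth_sigma))
  v <- img[mask]
  thr <- stats::median(v) + m * stats::mad(v)
  H <- nrow(img); W <- ncol(img)
  idx <- which(mask & img > thr, arr.ind = TRUE)
  if (!nrow(idx)) return(idx[, , drop = FALSE])
  keep <- vapply(seq_len(nrow(idx)), function(i) {
    r <- idx[i, 1]; c <- idx[i, 2]
    rr <- max(1, r - 1):min(H, r + 1); cc <- max(1, c - 1):min(W, c + 1)
    img[r, c] >= max(img[rr, cc])
  }, TRUE)
  idx[keep, , drop = FALSE]
}

#' Detect SPB separation from a focus channel
#'
#' Per frame, up to two foci are detected inside each cell as local
#' maxima above `median + m * MAD` of the in-cell intensities; SPB
#' separation is the first frame with two foci at distance > `d_min`
#' persisting for >= `persist` frames.
#'
#' @param frames list of focus-channel matrices.
#' @param cell_masks list of logical matrices (one cell) or a function
#'   `(frame_index) -> mask`.
#' @param times frame times, min.
#' @param m MAD multiplier for the focus threshold.
#' @param d_min minimum focus separation, px.
#' @param persist minimum consecutive frames.
#' @param smooth_sigma Gaussian pre-filter SD for peak finding, px
#'   (0 when `frames` are already smoothed).
#' @return separation time (min) or `NA` if never observed.
#' @export
detect_spb_separation <- function(frames, cell_masks, times, m = 6,
                                  d_min = 3, persist = 2,
                                  smooth_sigma = 1) {
  sep <- vapply(seq_along(frames), function(f) {
    msk <- if (is.function(cell_masks)) cell_masks(f) else cell_masks[[f]]
    if (is.null(msk) || !any(msk)) return(FALSE)
    img <- frames[[f]]
    if (smooth_sigma > 0) img <- as.matrix(EBImage::gblur(img, smooth_sigma))
    foci <- find_foci(img, msk, m, smooth_sigma = 0)
    if (nrow(foci) < 2) return(FALSE)
    peaks <- img[foci]
    top2 <- foci[order(peaks, decreasing = TRUE)[1:2], , drop = FALSE]
    sqrt(sum((top2[1, ] - top2[2, ])^2)) > d_min
  }, TRUE)
  runs <- rle(sep)
  starts <- cumsum(runs$lengths) - runs$lengths + 1
  hit <- which(runs$values & runs$lengths >= persist)
  if (!length(hit)) return(NA_real_)
  times[starts[hit[1]]]
}

#' Detect Plo1 enrichment onset from a top-k focus trace
#'
#' The loess-smoothed top-k trace is compared against a baseline formed
#' by the earliest quartile of time points: onset is the first time the
#' smoothed trace exceeds `baseline mean + q * baseline SD` and stays
#' above for >= `persist` frames. Baseline mean and SD are taken from
#' the smoothed trace over the baseline window.
#'
#' @param t,y times (min) and top-k mean values.
#' @param q SD multiplier.
#' @param persist minimum consecutive frames above threshold.
#' @param span loess span used for smoothing.
#' @return onset time (min) or `NA`.
#' @export
detect_plo1_onset <- function(t, y, q = 4, persist = 3, span = 0.3) {
  o <- order(t); t <- t[o]; y <- y[o]
  s <- loess_smooth(t, y, span)
  nb <- max(3, floor(length(t) / 4))
  base <- s[seq_len(nb)]
  thr <- mean(base) + q * stats::sd(base)
  above <- s > thr
  runs <- rle(above)
  starts <- cumsum(runs$lengths) - runs$lengths + 1
  hit <- which(runs$values & runs$lengths >= persist)
  if (!length(hit)) return(NA_real_)
  t[starts[hit[1]]]
}

#' Align per-cell traces to a shared event and pool them
#'
#' Times are shifted so the anchor event is 0 and snapped to the
#' acquisition grid; no interpolation is done across cells, so all
#' pooled traces must share one frame interval. The ensemble mean is
#' reported wherever >= 1 cell contributes; the SD is the sample SD
#' where n >= 2 and 0 where n = 1 (the `n` column lets consumers
#' restrict to n >= 2).
#'
#' @param traces named list of data frames with columns `t` and `value`.
#' @param anchors named numeric vector of anchor event times (same
#'   names as `traces`); cells with a missing anchor are dropped with a
#'   record.
#' @param interval shared frame interval, min.
#' @return an `aligned_ensemble`: list with `grid`, `mat` (cells x grid
#'   values), `mean`, `sd`, `n`, `dropped`.
#' @export
align_and_pool <- function(traces, anchors, interval) {
  stopifnot(length(traces) >= 1)
  nm <- names(traces)
  dropped <- nm[!is.finite(anchors[nm])]
  keep <- setdiff(nm, dropped)
  if (!length(keep)) stop("no cell has the anchor event", call. = FALSE)
  shifted <- lapply(keep, function(id) {
    d <- traces[[id]]
    dt <- diff(sort(unique(d$t)))
    if (length(dt) && any(abs(dt - interval) > 1e-6 * interval))
      stop_config("trace %s is not on the %g-min grid (pools must share one frame interval)",
                  id, interval)
    data.frame(rel = round((d$t - anchors[id]) / interval) * interval,
               value = d$value)
  })
  names(shifted) <- keep
  grid <- sort(unique(unlist(lapply(shifted, `[[`, "rel"))))
  mat <- matrix(NA_real_, length(keep), length(grid),
                dimnames = list(keep, NULL))
  for (id in keep) {
    j <- match(round(shifted[[id]]$rel / interval),
               round(grid / interval))
    mat[id, j] <- shifted[[id]]$value
  }
  n <- colSums(!is.na(mat))
  mu <- colMeans(mat, na.rm = TRUE); mu[n == 0] <- NA_real_
  sdv <- apply(mat, 2, stats::sd, na.rm = TRUE)
  sdv[n == 1] <- 0; sdv[n == 0] <- NA_real_
  structure(list(grid = grid, mat = mat, mean = mu, sd = sdv, n = n,
                 dropped = dropped, interval = interval),
            class = "aligned_ensemble")
}
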