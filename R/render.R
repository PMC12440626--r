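# Synthetic movie rendering.
#
# Cells are rods (capsules) laid out horizontally on a fixed grid; the
# nucleus is a disc that splits into two discs at anaphase; SPB foci are
# sub-pixel point depositions. Per-compartment reporter amounts are
# painted as uniform per-pixel shares (amount / pixel count), so the
# pixel sum over a compartment equals its amount exactly before noise.
# The expected image is background + photon_scale * (paint convolved
# with a Gaussian PSF); noise is Poisson on the expected counts plus
# Gaussian read noise. Convolution uses circular boundaries, so flux is
# conserved over the whole field.
#
# Coordinate convention (shared with masks): row-major, origin top-left,
# pixel (r, c) has center (x = c, y = r) in pixel units.

#' Optics and acquisition configuration
#'
#' @param pixel_size um per pixel.
#' @param frame_interval frame interval in minutes (5, 3 and 0.25 are
#'   the three supported acquisition regimes).
#' @param psf_sigma Gaussian PSF standard deviation, px; 0 disables
#'   blurring.
#' @param background_level camera background offset, counts/px.
#' @param read_noise_sd Gaussian read noise SD, counts.
#' @param photon_scale conversion from painted a.u. to expected counts.
#' @param field `c(height, width)` in px.
#' @param marker_level painted nuclear-marker concentration, a.u./px.
#' @param outline_level painted cell-interior level of the outline-proxy
#'   channel, a.u./px.
#' @param plo1_diffuse painted diffuse level of the optional Plo1 focus
#'   channel, a.u./px.
#' @param ... overrides.
#' @return an `optics_config` object.
#' @export
optics_config <- function(pixel_size = 0.11, frame_interval = 5,
                          psf_sigma = 1.0, background_level = 100,
                          read_noise_sd = 2, photon_scale = 1,
                          field = c(512L, 512L), marker_level = 150,
                          outline_level = 60, plo1_diffuse = 20, ...) {
  o <- c(as.list(environment()), list(...))
  o <- o[!duplicated(names(o))]
  if (o$pixel_size <= 0) stop_config("pixel_size must be > 0")
  if (o$frame_interval <= 0) stop_config("frame_interval must be > 0")
  class(o) <- "optics_config"
  o
}

# Deterministic non-overlapping grid placement; cells lie horizontally.
place_cells <- function(pop, optics) {
  px <- optics$pixel_size
  maxlen <- vapply(pop$cells, function(cl)
    cl$trace$length_um[nrow(cl$trace)], 0)
  slot_w <- ceiling(max(maxlen) / px) + 12
  slot_h <- ceiling(pop$params$cell_width / px) + 10
  ncol_s <- floor((optics$field[2] - 4) / slot_w)
  nrow_s <- floor((optics$field[1] - 4) / slot_h)
  n <- length(pop$cells)
  if (ncol_s < 1 || nrow_s < 1 || n > ncol_s * nrow_s) {
    ids <- vapply(pop$cells, `[[`, "", "cell_id")
    bad <- if (ncol_s * nrow_s < n) ids[seq(max(1, ncol_s * nrow_s + 1), n)] else ids
    stop_config("cannot place cells without overlap in a %dx%d field: %s",
                optics$field[1], optics$field[2], paste(bad, collapse = ", "))
  }
  i <- seq_len(n) - 1L
  data.frame(cell_id = vapply(pop$cells, `[[`, "", "cell_id"),
             cx = 2 + (i %% ncol_s) * slot_w + slot_w / 2,
             cy = 2 + (i %/% ncol_s) * slot_h + slot_h / 2)
}

# Pixel sets of one cell's geometry at local time tl (minutes after its
# birth). Returns NULL when the cell is not alive at tl.
cell_geometry_px <- function(cell, tl, cx, cy, optics) {
  ev <- cell$events
  if (tl < 0 || tl > ev[["division"]]) return(NULL)
  px <- optics$pixel_size
  p <- cell$resolved$p
  L <- cell_length_at(cell, tl) / px
  w <- p$cell_width / px
  rn <- p$nuclear_radius / px
  half <- (L - w) / 2
  x0 <- floor(cx - L / 2 - 2); x1 <- ceiling(cx + L / 2 + 2)
  y0 <- floor(cy - w / 2 - 2); y1 <- ceiling(cy + w / 2 + 2)
  xs <- x0:x1; ys <- y0:y1
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  dx <- pmin(pmax(X - cx, -half), half) # nearest point on the axis segment
  cellm <- ((X - cx) - dx)^2 + (Y - cy)^2 <= (w / 2)^2
  # nucleus: one disc before anaphase, two separating discs after
  if (tl < ev[["anaphase"]]) {
    ncx <- cx; rr <- rn
    nucm <- (X - cx)^2 + (Y - cy)^2 <= rn^2
  } else {
    d <- (3.0 + 0.5 * (tl - ev[["anaphase"]])) / px
    d <- min(d, 2 * half)
    rr <- rn / sqrt(2)
    nucm <- ((X - (cx - d / 2))^2 + (Y - cy)^2 <= rr^2) |
      ((X - (cx + d / 2))^2 + (Y - cy)^2 <= rr^2)
  }
  nucm <- nucm & cellm
  # SPB foci (sub-pixel coordinates)
  if (tl < ev[["spb_separation"]]) {
    foci <- cbind(x = cx + rn, y = cy)
  } else {
    # spindle elongates slowly until anaphase, fast afterwards
    d_spb <- 0.6 + 0.3 * min(tl - ev[["spb_separation"]],
                             max(0, ev[["anaphase"]] - ev[["spb_separation"]])) +
      0.8 * max(0, tl - ev[["anaphase"]])
    d_spb <- min(d_spb / px, 2 * half)
    foci <- cbind(x = c(cx - d_spb / 2, cx + d_spb / 2), y = c(cy, cy))
  }
  list(xs = xs, ys = ys, cell = cellm, nuc = nucm, foci = foci)
}

# Add values into `img` over a bounding-box mask.
paint_mask <- function(img, geom, mask, value) {
  H <- nrow(img); W <- ncol(img)
  idx <- which(mask, arr.ind = TRUE)
  r <- geom$ys[idx[, 1]]; c <- geom$xs[idx[, 2]]
  keep <- r >= 1 & r <= H & c >= 1 & c <= W
  img[cbind(r[keep], c[keep])] <- img[cbind(r[keep], c[keep])] + value
  img
}

# Bilinear sub-pixel deposition of point amounts.
paint_points <- function(img, xy, amounts) {
  H <- nrow(img); W <- ncol(img)
  for (i in seq_len(nrow(xy))) {
    x <- xy[i, 1]; y <- xy[i, 2]; a <- amounts[i]
    if (a <= 0) next
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    for (dd in list(c(0, 0, (1 - fx) * (1 - fy)), c(1, 0, fx * (1 - fy)),
                    c(0, 1, (1 - fx) * fy), c(1, 1, fx * fy))) {
      cc <- x0 + dd[1]; rr <- y0 + dd[2]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W)
        img[rr, cc] <- img[rr, cc] + a * dd[3]
    }
  }
  img
}

# Plo1-overlay focus amount at local time tl: first-order binding to a
# finite pool of SPB sites switched on at Plo1 onset (the same law the
# kinetic ODE uses), S(t) = spb_max * (1 - exp(-spb_rate/spb_max * r(t)))
# with r(t) the logistic-smoothed time since onset.
plo1_focus_amount <- function(cell, tl) {
  p <- cell$resolved$p
  tau <- switch_tau(p$transition_width)
  ramp <- tau * log1p(exp(pmin((tl - cell$events[["plo1_onset"]]) / tau, 50)))
  p$spb_max * (1 - exp(-p$spb_rate / p$spb_max * ramp))
}

#' Render one frame of a synthetic movie
#'
#' @param pop a `gt_population`.
#' @param t absolute movie time, min.
#' @param optics an [optics_config()].
#' @param seed integer seed for the noise draws of this frame.
#' @param placement data frame from the internal grid placement (one row
#'   per cell: `cell_id`, `cx`, `cy`); computed automatically by
#'   [render_movie()].
#' @param t0_abs per-cell absolute birth times (min); cells outside
#'   their lifetime are absent from the frame.
#' @param channels subset of `c("outline", "nucmarker", "reporter",
#'   "spb")`.
#' @param noise logical; `FALSE` returns the expected (noise-free)
#'   image.
#' @return list with `images` (named list of matrices), `cell_labels`
#'   and `nucleus_labels` (truth label matrices; the two post-anaphase
#'   nuclei of a cell share its label).
#' @export
render_frame <- function(pop, t, optics, seed = 1, placement = NULL,
                         t0_abs = NULL,
                         channels = c("outline", "nucmarker", "reporter"),
                         noise = TRUE) {
  if (length(pop$cells) == 0) stop("population is empty", call. = FALSE)
  if (is.null(placement)) placement <- place_cells(pop, optics)
  if (is.null(t0_abs)) t0_abs <- rep(0, length(pop$cells))
  H <- optics$field[1]; W <- optics$field[2]
  imgs <- stats::setNames(lapply(channels, function(ch) matrix(0, H, W)),
                          channels)
  cell_lab <- matrix(0L, H, W); nuc_lab <- matrix(0L, H, W)

  for (i in seq_along(pop$cells)) {
    cl <- pop$cells[[i]]
    tl <- t - t0_abs[i]
    g <- cell_geometry_px(cl, tl, placement$cx[i], placement$cy[i], optics)
    if (is.null(g)) next
    n_cell <- sum(g$cell); n_nuc <- sum(g$nuc)
    am <- amounts_at(cl, tl)
    idx <- which(g$cell, arr.ind = TRUE)
    r <- g$ys[idx[, 1]]; cc <- g$xs[idx[, 2]]
    keep <- r >= 1 & r <= H & cc >= 1 & cc <= W
    cell_lab[cbind(r[keep], cc[keep])] <- i
    idx <- which(g$nuc, arr.ind = TRUE)
    r <- g$ys[idx[, 1]]; cc <- g$xs[idx[, 2]]
    keep <- r >= 1 & r <= H & cc >= 1 & cc <= W
    nuc_lab[cbind(r[keep], cc[keep])] <- i

    if ("outline" %in% channels)
      imgs$outline <- paint_mask(imgs$outline, g, g$cell, optics$outline_level)
    if ("nucmarker" %in% channels)
      imgs$nucmarker <- paint_mask(imgs$nucmarker, g, g$nuc, optics$marker_level)
    if ("reporter" %in% channels) {
      c_nuc <- if (n_nuc > 0) am$nuclear_amount / n_nuc else 0
      n_cyt <- n_cell - n_nuc
      c_cyt <- if (n_cyt > 0) am$cytoplasmic_amount / n_cyt else 0
      imgs$reporter <- paint_mask(imgs$reporter, g, g$cell & !g$nuc, c_cyt)
      imgs$reporter <- paint_mask(imgs$reporter, g, g$nuc, c_nuc)
      if (am$spb_amount > 0)
        imgs$reporter <- paint_points(imgs$reporter, g$foci,
                                      rep(am$spb_amount / nrow(g$foci),
                                          nrow(g$foci)))
    }
    if ("spb" %in% channels) {
      imgs$spb <- paint_mask(imgs$spb, g, g$cell, optics$plo1_diffuse)
      s <- plo1_focus_amount(cl, tl)
      if (s > 0)
        imgs$spb <- paint_points(imgs$spb, g$foci,
                                 rep(s / nrow(g$foci), nrow(g$foci)))
    }
  }

  for (k in seq_along(channels)) {
    x <- imgs[[k]]
    if (optics$psf_sigma > 0)
      x <- as.matrix(EBImage::gblur(x, sigma = optics$psf_sigma))
    x <- x * optics$photon_scale + optics$background_level
    if (noise) {
      set.seed(derive_seed(seed, k))
      x <- stats::rpois(length(x), pmax(x, 0)) +
        stats::rnorm(length(x), 0, optics$read_noise_sd)
      x <- matrix(pmax(round(x), 0), H, W)
      storage.mode(x) <- "integer"
    }
    imgs[[k]] <- x
  }
  list(images = imgs, cell_labels = cell_lab, nucleus_labels = nuc_lab)
}

#' Render a multi-frame synthetic movie
#'
#' Frames are placed at multiples of `optics$frame_interval` from 0 to
#' `t_end` inclusive. Truth label maps and event/amount tables are
#' carried along so downstream modules can be tested against the
#' generator.
#'
#' @inheritParams render_frame
#' @param t_end movie duration, min.
#' @param anaphase_window optional `c(lo, hi)`: absolute times between
#'   which each cell's anaphase is placed (uniformly, from the movie
#'   seed); default places every cell's birth at time 0.
#' @return a `movie` object: per-frame channel images and truth label
#'   maps, frame times, optics, truth event table (absolute minutes) and
#'   per-frame truth amounts.
#' @export
render_movie <- function(pop, optics, seed = 1, t_end,
                         channels = c("outline", "nucmarker", "reporter"),
                         noise = TRUE, anaphase_window = NULL) {
  if (length(pop$cells) == 0) stop("population is empty", call. = FALSE)
  n <- length(pop$cells)
  if (is.null(anaphase_window)) {
    t0_abs <- rep(0, n)
  } else {
    set.seed(derive_seed(seed, 0))
    target <- stats::runif(n, anaphase_window[1], anaphase_window[2])
    t0_abs <- target - vapply(pop$cells, function(cl)
      cl$events[["anaphase"]], 0)
  }
  placement <- place_cells(pop, optics)
  times <- seq(0, t_end, by = optics$frame_interval)
  frames <- vector("list", length(times))
  cell_labels <- vector("list", length(times))
  nucleus_labels <- vector("list", length(times))
  for (f in seq_along(times)) {
    fr <- render_frame(pop, times[f], optics, seed = derive_seed(seed, f),
                       placement = placement, t0_abs = t0_abs,
                       channels = channels, noise = noise)
    frames[[f]] <- fr$images
    cell_labels[[f]] <- fr$cell_labels
    nucleus_labels[[f]] <- fr$nucleus_labels
  }
  events <- data.frame(
    cell = seq_len(n),
    cell_id = vapply(pop$cells, `[[`, "", "cell_id"),
    species = vapply(pop$cells, `[[`, "", "species"),
    t0_abs = t0_abs,
    birth = t0_abs,
    plo1_onset = t0_abs + vapply(pop$cells, function(cl) cl$events[["plo1_onset"]], 0),
    export_onset = t0_abs + vapply(pop$cells, function(cl) cl$events[["export_onset"]], 0),
    spb_separation = t0_abs + vapply(pop$cells, function(cl) cl$events[["spb_separation"]], 0),
    anaphase = t0_abs + vapply(pop$cells, function(cl) cl$events[["anaphase"]], 0),
    division = t0_abs + vapply(pop$cells, function(cl) cl$events[["division"]], 0))
  truth_frames <- do.call(rbind, lapply(seq_len(n), function(i) {
    tl <- times - t0_abs[i]
    alive <- tl >= 0 & tl <= pop$cells[[i]]$events[["division"]]
    if (!any(alive)) return(NULL)
    cbind(data.frame(cell = i, cell_id = pop$cells[[i]]$cell_id,
                     t_abs = times[alive]),
          amounts_at(pop$cells[[i]], tl[alive]))
  }))
  structure(list(frames = frames, cell_labels = cell_labels,
                 nucleus_labels = nucleus_labels, times = times,
                 optics = optics, channels = channels,
                 placement = placement,
                 truth = list(events = events, frames = truth_frames),
                 seed = seed, noise = noise),
            class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  cat(sprintf("synthetic movie: %d frames x %s channels, %dx%d px, dt = %g min\n",
              length(x$times), paste(x$channels, collapse = "/"),
              x$optics$field[1], x$optics$field[2], x$optics$frame_interval))
  invisible(x)
}

#' Write / read a movie as multi-page TIFFs plus a JSON sidecar
#'
#' One 16-bit multi-page TIFF per channel (one page per frame, counts
#' stored as `value / 65535`), 16-bit label TIFFs for the truth masks,
#' truth tables as CSV and acquisition metadata as JSON.
#'
#' @param movie a `movie` object.
#' @param dir output directory (created if missing).
#' @export
write_movie <- function(movie, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in movie$channels) {
    pages <- lapply(movie$frames, function(fr)
      pmin(pmax(fr[[ch]], 0), 65535) / 65535)
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16)
  }
  for (nm in c("cell_labels", "nucleus_labels"))
    tiff::writeTIFF(lapply(movie[[nm]], function(m) m / 65535),
                    file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 16)
  utils::write.csv(movie$truth$events, file.path(dir, "truth_events.csv"),
                   row.names = FALSE)
  utils::write.csv(movie$truth$frames, file.path(dir, "truth_frames.csv"),
                   row.names = FALSE)
  meta <- list(optics = unclass(movie$optics), channels = movie$channels,
               times = movie$times, seed = movie$seed, noise = movie$noise,
               placement = movie$placement)
  jsonlite::write_json(meta, file.path(dir, "movie.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_movie
#' @export
read_movie <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "movie.json"),
                              simplifyVector = TRUE)
  optics <- do.call(optics_config, as.list(meta$optics))
  channels <- meta$channels
  read_stack <- function(path, integer = TRUE) {
    pages <- tiff::readTIFF(path, all = TRUE)
    lapply(pages, function(p) {
      m <- round(p * 65535)
      if (integer) storage.mode(m) <- "integer"
      m
    })
  }
  stacks <- lapply(channels, function(ch)
    read_stack(file.path(dir, paste0(ch, ".tif"))))
  names(stacks) <- channels
  nf <- length(stacks[[1]])
  frames <- lapply(seq_len(nf), function(f)
    stats::setNames(lapply(channels, function(ch) stacks[[ch]][[f]]), channels))
  structure(list(frames = frames,
                 cell_labels = read_stack(file.path(dir, "cell_labels.tif")),
                 nucleus_labels = read_stack(file.path(dir, "nucleus_labels.tif")),
                 times = meta$times, optics = optics, channels = channels,
                 placement = meta$placement,
                 truth = list(
                   events = utils::read.csv(file.path(dir, "truth_events.csv")),
                   frames = utils::read.csv(file.path(dir, "truth_frames.csv"))),
                 seed = meta$seed, noise = meta$noise),
            class = "movie")
}
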