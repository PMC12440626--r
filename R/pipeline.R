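# End-to-end pipeline: simulate -> (render) -> segment -> quantify ->
# align -> change-point, plus a trace-only entry point and run configs.

#' Assemble a run configuration
#'
#' One serializable object holding the seeds and all stage parameter
#' blocks; a run's config is written verbatim next to its outputs.
#'
#' @param seed master seed.
#' @param n_cells cells to simulate.
#' @param species reporter species.
#' @param timeline a [timeline_params()].
#' @param optics an [optics_config()].
#' @param t_end movie duration, min.
#' @param anaphase_window `c(lo, hi)` placement of anaphase, min.
#' @param channels channels to render.
#' @param analysis named list of analysis parameters (top-k `k`, loess
#'   `span`, export-window `lookback`, focus-detection `m`, `q`,
#'   `d_min`, nucleus `blur_sigma`, `use_truth_masks`).
#' @return a `run_config` object.
#' @export
run_config <- function(seed = 1, n_cells = 30, species = "cdc13",
                       timeline = timeline_params(),
                       optics = optics_config(frame_interval = 0.25),
                       t_end = 30, anaphase_window = c(26, 28.5),
                       channels = c("outline", "nucmarker", "reporter", "spb"),
                       analysis = list()) {
  analysis <- utils::modifyList(
    list(k = 40, span = 0.3, lookback = 25, m = 6, q = 4, d_min = 3,
         persist_anaphase = 2, persist_spb = 2, persist_plo1 = 3,
         blur_sigma = 1.5, cell_blur_sigma = 1, min_cell_area = 200,
         min_nucleus_area = 30, use_truth_masks = FALSE),
    analysis)
  structure(list(seed = seed, n_cells = n_cells, species = species,
                 timeline = timeline, optics = optics, t_end = t_end,
                 anaphase_window = anaphase_window, channels = channels,
                 analysis = analysis),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$timeline <- unclass(x$timeline)
  x$timeline$cycle_length_fn <- as.list(x$timeline$cycle_length_fn)
  x$optics <- unclass(x$optics)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$timeline$cycle_length_fn <- unlist(x$timeline$cycle_length_fn)
  x$timeline <- do.call(timeline_params, x$timeline)
  x$optics <- do.call(optics_config, x$optics)
  do.call(run_config, x)
}

# FNV-1a hash of the serialized config, recorded in output tables.
config_hash <- function(config) {
  s <- utf8ToInt(paste(utils::capture.output(utils::str(unclass(config))),
                       collapse = "\n"))
  h <- 5381
  for (ch in s) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Simulate a run: population plus rendered movie
#'
#' @param config a [run_config()].
#' @param out_dir optional directory: the movie (TIFF + sidecar), truth
#'   tables and the config itself are written there.
#' @return a `movie` object (with the generating population attached as
#'   `$pop`).
#' @export
simulate_run <- function(config, out_dir = NULL) {
  if (config$n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  pop <- sample_population(config$timeline, config$n_cells, config$seed,
                           species = config$species,
                           dt = config$optics$frame_interval)
  movie <- render_movie(pop, config$optics, seed = config$seed,
                        t_end = config$t_end, channels = config$channels,
                        anaphase_window = config$anaphase_window)
  movie$pop <- pop
  movie$config <- config
  if (!is.null(out_dir)) {
    write_movie(movie, out_dir)
    write_traces(pop_traces(pop), file.path(out_dir, "truth_traces.csv"))
    write_run_config(config, file.path(out_dir, "run_config.yaml"))
  }
  movie
}

# Per-frame measurement of every retained cell, via label-wise sums.
measure_frame <- function(img, cell_lab, nuc_lab, assignment, b, k = 40) {
  ids <- sort(unique(as.integer(cell_lab[cell_lab > 0])))
  if (!length(ids)) return(NULL)
  lab_v <- as.integer(cell_lab); img_v <- as.numeric(img)
  in_cell <- lab_v > 0
  A_cell <- tabulate(lab_v[in_cell], max(ids))
  I_cell_raw <- rowsum(img_v[in_cell], lab_v[in_cell])
  sums_cell <- stats::setNames(I_cell_raw[, 1], rownames(I_cell_raw))
  # nucleus pixels grouped by assigned cell
  nuc_v <- as.integer(nuc_lab)
  nuc2cell <- integer(max(c(nuc_v, assignment$nucleus, 1)))
  if (nrow(assignment))
    nuc2cell[assignment$nucleus] <- assignment$cell
  in_nuc <- nuc_v > 0
  nuc_cell <- rep(0L, length(nuc_v))
  nuc_cell[in_nuc] <- nuc2cell[nuc_v[in_nuc]]
  keepn <- nuc_cell > 0 & lab_v == nuc_cell # nucleus pixels inside their cell
  A_nuc <- tabulate(nuc_cell[keepn], max(ids))
  sums_nuc <- rep(0, max(ids))
  if (any(keepn)) {
    sn <- rowsum(img_v[keepn], nuc_cell[keepn])
    sums_nuc[as.integer(rownames(sn))] <- sn[, 1]
  }
  n_nuclei <- rep(0L, max(ids))
  if (nrow(assignment)) {
    tb <- table(assignment$cell[assignment$cell > 0])
    n_nuclei[as.integer(names(tb))] <- as.integer(tb)
  }
  vals_by_cell <- split(img_v[in_cell], lab_v[in_cell])
  do.call(rbind, lapply(ids, function(i) {
    Ac <- A_cell[i]; An <- A_nuc[i]
    Ic <- max(sums_cell[[as.character(i)]] - b * Ac, 0)
    In <- min(max(sums_nuc[i] - b * An, 0), Ic)
    v <- vals_by_cell[[as.character(i)]]
    tk <- if (length(v) >= k) mean(sort(v, decreasing = TRUE)[seq_len(k)])
          else NA_real_
    data.frame(label = i, A_cell = Ac, A_nuc = An, A_cyt = Ac - An,
               I_cell = Ic, I_nuc = In, I_cyt = Ic - In,
               c_cell = Ic / Ac,
               c_nuc = if (An > 0) In / An else NA_real_,
               c_cyt = if (Ac - An > 0) (Ic - In) / (Ac - An) else NA_real_,
               topk_mean = tk, b = b, n_nuclei = n_nuclei[i])
  }))
}

#' Analyze a movie end to end
#'
#' Segments (or passes through the truth masks), removes border cells,
#' assigns nuclei, tracks cells, measures every cell in every frame,
#' detects anaphase (and, when a focus channel is present, Plo1 onset
#' and SPB separation), and estimates per-cell export windows and
#' transition widths from the nuclear-concentration traces.
#'
#' @param movie a `movie` object.
#' @param config a [run_config()]; its `analysis` block controls the
#'   stage parameters. `analysis$use_truth_masks = TRUE` bypasses
#'   segmentation (truth passthrough).
#' @param channel reporter channel to quantify.
#' @return list with `measurements`, `events`, `windows`, `config_hash`
#'   and `warnings` (dropped nuclei / flagged cells), each a data frame.
#' @export
analyze_movie <- function(movie, config = run_config(), channel = "reporter") {
  a <- config$analysis
  nf <- length(movie$times)
  warnings <- list()

  cell_labs <- vector("list", nf); nuc_labs <- vector("list", nf)
  assignments <- vector("list", nf)
  for (f in seq_len(nf)) {
    if (isTRUE(a$use_truth_masks)) {
      cl <- movie$cell_labels[[f]]
      nl <- movie$nucleus_labels[[f]]
      # split each cell's nuclear region into connected components so
      # that post-anaphase cells carry two nucleus objects
      nl <- label_mask(nl > 0, 0)
    } else {
      cl <- segment_cells(movie$frames[[f]]$outline,
                          blur_sigma = a$cell_blur_sigma,
                          min_area = a$min_cell_area)
      nl <- segment_nuclei(movie$frames[[f]]$nucmarker,
                           blur_sigma = a$blur_sigma,
                           min_area = a$min_nucleus_area)
    }
    fb <- filter_border_cells(cl)
    cell_labs[[f]] <- fb$labels
    if (length(fb$excluded))
      warnings[[length(warnings) + 1]] <-
        data.frame(frame = f, what = "border_cell",
                   id = as.character(fb$excluded))
    nuc_labs[[f]] <- nl
    asg <- assign_nuclei(fb$labels, nl)
    dropped <- asg[asg$cell == 0, , drop = FALSE]
    if (nrow(dropped))
      warnings[[length(warnings) + 1]] <-
        data.frame(frame = f, what = "nucleus_dropped",
                   id = as.character(dropped$nucleus))
    assignments[[f]] <- asg[asg$cell > 0, , drop = FALSE]
  }

  tracks <- track_cells(cell_labs)

  # when the movie carries truth masks, record each track's dominant
  # truth cell (by pixel overlap at the track's first frame)
  truth_of_track <- NULL
  if (!is.null(movie$cell_labels)) {
    first_rows <- tracks[!duplicated(tracks$track), ]
    truth_of_track <- vapply(seq_len(nrow(first_rows)), function(i) {
      f <- first_rows$frame[i]
      ov <- movie$cell_labels[[f]][cell_labs[[f]] == first_rows$label[i]]
      ov <- ov[ov > 0]
      if (!length(ov)) return(NA_integer_)
      as.integer(names(sort(table(ov), decreasing = TRUE))[1])
    }, 1L)
    names(truth_of_track) <- first_rows$track
  }

  meas <- list()
  for (f in seq_len(nf)) {
    b <- estimate_background(movie$frames[[f]][[channel]], cell_labs[[f]])
    m <- measure_frame(movie$frames[[f]][[channel]], cell_labs[[f]],
                       nuc_labs[[f]], assignments[[f]], b, k = a$k)
    if (is.null(m)) next
    m$frame <- f; m$t_min <- movie$times[f]
    meas[[f]] <- m
  }
  meas <- do.call(rbind, meas)
  meas <- merge(meas, tracks[, c("frame", "label", "track")],
                by = c("frame", "label"), all.x = TRUE)
  meas <- meas[order(meas$track, meas$frame), ]

  ana <- detect_anaphase(meas[, c("track", "frame", "n_nuclei")],
                         movie$times, persist = a$persist_anaphase)
  ana_t <- stats::setNames(ana$anaphase_time, ana$track)

  # focus channel: Plo1 onset + SPB separation per track
  has_spb <- "spb" %in% names(movie$frames[[1]])
  plo1 <- spbsep <- stats::setNames(rep(NA_real_, nrow(ana)),
                                    names(ana_t))
  if (has_spb) {
    # matched-filter the focus channel once per frame
    spb_smooth <- lapply(seq_len(nf), function(f)
      as.matrix(EBImage::gblur(movie$frames[[f]]$spb, 1)))
    for (tr in names(ana_t)) {
      sub <- meas[meas$track == as.integer(tr), ]
      tk <- vapply(seq_len(nrow(sub)), function(i) {
        f <- sub$frame[i]
        msk <- cell_labs[[f]] == sub$label[i]
        topk_mean(movie$frames[[f]]$spb, msk, k = a$k, cell_id = tr)
      }, 0)
      plo1[tr] <- tryCatch(
        detect_plo1_onset(sub$t_min, tk, q = a$q,
                          persist = a$persist_plo1, span = a$span),
        error = function(e) NA_real_)
      label_of <- stats::setNames(sub$label, sub$frame)
      mask_fn <- function(f) {
        lb <- label_of[as.character(f)]
        if (is.na(lb)) return(NULL)
        cell_labs[[f]] == lb
      }
      spbsep[tr] <- detect_spb_separation(
        spb_smooth, mask_fn, movie$times, m = a$m, d_min = a$d_min,
        persist = a$persist_spb, smooth_sigma = 0)
    }
  }

  windows <- do.call(rbind, lapply(names(ana_t), function(tr) {
    sub <- meas[meas$track == as.integer(tr), ]
    w <- if (is.finite(ana_t[tr]))
      estimate_export_window(sub$t_min, sub$c_nuc, ana_t[tr],
                             lookback = a$lookback, span = a$span)
    else list(onset = NA_real_, stop = NA_real_, valid = FALSE, fit = NULL,
              flag = "no_anaphase")
    width <- if (!is.null(w$fit))
      transition_width(sub$t_min, sub$c_nuc, w$fit, which_break = 1)
    else NA_real_
    data.frame(track = as.integer(tr),
               truth_cell = if (!is.null(truth_of_track))
                 truth_of_track[tr] else NA_integer_,
               anaphase_time = ana_t[tr],
               onset_before_anaphase = w$onset, stop_before_anaphase = w$stop,
               valid = w$valid, flag = w$flag,
               onset_width_min = width,
               plo1_onset_time = plo1[tr], spb_separation_time = spbsep[tr])
  }))
  rownames(windows) <- NULL

  warn_df <- if (length(warnings)) do.call(rbind, warnings) else
    data.frame(frame = integer(), what = character(), id = character())
  hash <- config_hash(config)
  meas$config_hash <- hash
  windows$config_hash <- hash
  list(measurements = meas, events = windows[, c("track", "anaphase_time",
                                                 "plo1_onset_time",
                                                 "spb_separation_time")],
       windows = windows, warnings = warn_df, config_hash = hash)
}

#' Analyze ground-truth trace tables (no imaging stages)
#'
#' The trace-only entry point: concentrations are formed from the truth
#' amounts and areas, anaphase is quantized to the frame grid, and the
#' same export-window estimator runs per cell.
#'
#' @param traces data frame in the [write_traces()] layout.
#' @param config a [run_config()] (only the `analysis` block is used).
#' @return list with `traces` (with concentration columns added) and
#'   `windows`.
#' @export
analyze_traces <- function(traces, config = run_config()) {
  a <- config$analysis
  traces$c_nuc <- traces$nuclear_amount / traces$nuclear_area_um2
  traces$c_cyt <- traces$cytoplasmic_amount /
    (traces$cell_area_um2 - traces$nuclear_area_um2)
  windows <- do.call(rbind, lapply(split(traces, traces$cell_id), function(d) {
    d <- d[order(d$t_min), ]
    ana_frame <- d$t_min[which(d$t_min >= d$anaphase[1])[1]]
    w <- estimate_export_window(d$t_min, d$c_nuc, ana_frame,
                                lookback = a$lookback, span = a$span)
    width <- if (!is.null(w$fit))
      transition_width(d$t_min, d$c_nuc, w$fit, which_break = 1)
    else NA_real_
    data.frame(cell_id = d$cell_id[1], anaphase_time = ana_frame,
               onset_before_anaphase = w$onset,
               stop_before_anaphase = w$stop, valid = w$valid,
               flag = w$flag, onset_width_min = width)
  }))
  rownames(windows) <- NULL
  list(traces = traces, windows = windows, config_hash = config_hash(config))
}
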