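# Population statistics: cycle length and cell length summaries,
# rank-sum testing and the size-homeostasis regression.

#' Per-cell cycle metrics from tracked traces
#'
#' Cycle length is the time between consecutive division events; birth
#' length is the cell length at the first frame at/after birth and
#' pre-division length the length at the last frame before division.
#' Cells whose birth or division falls outside the observation window
#' are excluded and counted.
#'
#' @param traces data frame with columns `cell_id`, `t_min`,
#'   `length_um`, `birth_time`, `division` (one row per cell per frame;
#'   the layout written by [write_traces()]).
#' @param window optional `c(start, end)` observation window, min;
#'   default is the observed time range.
#' @return list with `cells` (data frame `cell_id`, `cycle_length_min`,
#'   `birth_length_um`, `predivision_length_um`) and `excluded`
#'   (ids of incomplete cells).
#' @export
cycle_metrics <- function(traces, window = NULL) {
  if (is.null(window)) window <- range(traces$t_min)
  per <- split(traces, traces$cell_id)
  rows <- list(); excluded <- character()
  for (id in names(per)) {
    d <- per[[id]][order(per[[id]]$t_min), ]
    birth <- d$birth_time[1]; division <- d$division[1]
    if (!is.finite(birth) || !is.finite(division) ||
        birth < window[1] || division > window[2]) {
      excluded <- c(excluded, id)
      next
    }
    i_birth <- which(d$t_min >= birth)[1]
    i_pre <- max(which(d$t_min < division))
    rows[[id]] <- data.frame(cell_id = id,
                             cycle_length_min = division - birth,
                             birth_length_um = d$length_um[i_birth],
                             predivision_length_um = d$length_um[i_pre])
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(), cycle_length_min = numeric(),
               birth_length_um = numeric(), predivision_length_um = numeric())
  rownames(cells) <- NULL
  list(cells = cells, excluded = excluded)
}

#' Wilcoxon rank sum test with continuity correction
#'
#' Midranks for ties, normal approximation with tie-corrected variance
#' and a 0.5 continuity correction, two-sided (the standard R test).
#' `exact = TRUE` switches to the exact distribution (small samples, no
#' ties).
#'
#' @param x,y numeric samples (each non-empty).
#' @param continuity apply the continuity correction.
#' @param exact use the exact null distribution instead of the normal
#'   approximation.
#' @return list `statistic` (W), `p_value`, `method`, `n` (group sizes).
#' @export
wilcoxon_rank_sum <- function(x, y, continuity = TRUE, exact = FALSE) {
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = continuity))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method, n = c(length(x), length(y)))
}

#' Size-homeostasis regression
#'
#' Ordinary least-squares fit of cycle length on birth length, with the
#' Pearson correlation coefficient.
#'
#' @param birth_lengths,cycle_lengths numeric vectors (n >= 3).
#' @return list `slope`, `intercept`, `r`, `n`.
#' @export
homeostasis_fit <- function(birth_lengths, cycle_lengths) {
  ok <- is.finite(birth_lengths) & is.finite(cycle_lengths)
  x <- birth_lengths[ok]; y <- cycle_lengths[ok]
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in birth lengths", call. = FALSE)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y), n = length(x))
}

#' Box-plot summary (median, quartiles, 1.5 IQR whiskers)
#'
#' Quartiles use the linear-interpolation (type-7) convention; whiskers
#' sit at the most extreme observations within 1.5 IQR of the quartiles
#' (data points, never the fence itself).
#'
#' @param values numeric vector (n >= 1).
#' @return list `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`, `n`.
#' @export
box_summary <- function(values) {
  v <- values[is.finite(values)]
  stopifnot(length(v) >= 1)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr; hi_fence <- q[3] + 1.5 * iqr
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(v[v >= lo_fence]),
       whisker_hi = max(v[v <= hi_fence]),
       n = length(v))
}
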