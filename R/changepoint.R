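# Change-point estimation of export onset/stop times.
#
# The export-phase timings are formalized as a continuous
# piecewise-linear least-squares fit with breakpoints restricted to the
# observed frame times and found by exhaustive search; the local
# sharpness of each switch is the 10-90% width of a logistic blend of
# the two adjoining segments.

#' Continuous piecewise-linear least-squares fit
#'
#' Fits `y ~ a + b t + sum_j c_j (t - b_j)_+` for all admissible
#' breakpoint combinations on the observed time grid (at least
#' `min_seg` points strictly between consecutive breakpoints and at the
#' ends) and returns the global residual-sum-of-squares minimizer.
#' Ties are broken toward earlier breakpoints.
#'
#' @param t,y numeric vectors; `t` strictly increasing.
#' @param n_breakpoints 1, 2 or 3.
#' @param min_seg minimum number of points per segment.
#' @return a `changepoint_fit`: list with `breakpoints`, `slopes` (one
#'   per segment), `coef`, `rss`, `fitted`, `t`, `y`.
#' @export
fit_piecewise_linear <- function(t, y, n_breakpoints = 2, min_seg = 2) {
  stopifnot(n_breakpoints %in% 1:3)
  o <- order(t); t <- as.numeric(t[o]); y <- as.numeric(y[o])
  n <- length(t)
  if (n < 4 + 2 * n_breakpoints)
    stop_config("need at least %d points for %d breakpoints",
                4 + 2 * n_breakpoints, n_breakpoints)
  if (stats::sd(y) == 0)
    stop("constant trace: piecewise-linear fit is degenerate", call. = FALSE)

  # candidate breakpoint indices leave >= min_seg points per segment
  cand <- seq(min_seg + 1, n - min_seg)
  combos <- utils::combn(cand, n_breakpoints)
  if (n_breakpoints > 1) {
    ok <- apply(combos, 2, function(ix) all(diff(ix) >= min_seg))
    combos <- combos[, ok, drop = FALSE]
  }
  if (!ncol(combos)) stop("no admissible breakpoint placement", call. = FALSE)

  # Hinge columns are nonzero on suffixes of the (sorted) time grid, so
  # every entry of the normal equations comes from suffix sums in O(1)
  # per candidate; only the winning fit is re-materialized.
  mt <- mean(t); tc <- t - mt
  S1 <- rev(cumsum(rev(t))); S2 <- rev(cumsum(rev(t^2)))
  Sy <- rev(cumsum(rev(y))); Sty <- rev(cumsum(rev(t * y)))
  suf <- function(S, i) if (i < n) S[i + 1] else 0
  cnt <- function(i) n - i
  h_dot_1 <- function(i, b) suf(S1, i) - b * cnt(i)
  h_dot_tc <- function(i, b) suf(S2, i) - (mt + b) * suf(S1, i) +
    mt * b * cnt(i)
  h_dot_h <- function(i1, b1, i2, b2) { # requires i1 <= i2
    suf(S2, i2) - (b1 + b2) * suf(S1, i2) + b1 * b2 * cnt(i2)
  }
  h_dot_y <- function(i, b) suf(Sty, i) - b * suf(Sy, i)
  sum_y <- sum(y); sum_tcy <- sum(tc * y); yy <- sum(y^2)
  sum_tc2 <- sum(tc^2)

  k <- n_breakpoints
  best <- NULL; best_rss <- Inf
  for (j in seq_len(ncol(combos))) {
    ix <- combos[, j]; bks <- t[ix]
    p <- 2 + k
    G <- matrix(0, p, p); v <- numeric(p)
    G[1, 1] <- n; G[1, 2] <- G[2, 1] <- 0; G[2, 2] <- sum_tc2
    v[1] <- sum_y; v[2] <- sum_tcy
    for (a in seq_len(k)) {
      G[1, 2 + a] <- G[2 + a, 1] <- h_dot_1(ix[a], bks[a])
      G[2, 2 + a] <- G[2 + a, 2] <- h_dot_tc(ix[a], bks[a])
      v[2 + a] <- h_dot_y(ix[a], bks[a])
      for (b in seq_len(a))
        G[2 + b, 2 + a] <- G[2 + a, 2 + b] <-
          h_dot_h(ix[b], bks[b], ix[a], bks[a])
    }
    beta <- tryCatch(solve(G, v), error = function(e) NULL)
    if (is.null(beta)) next
    rss <- yy - sum(beta * v)
    if (rss < best_rss - 1e-12) { # strict improvement: earlier ties win
      best_rss <- rss
      best <- list(bks = bks, coef = beta)
    }
  }
  if (is.null(best)) stop("piecewise-linear fit failed", call. = FALSE)
  X <- cbind(1, tc)
  for (b in best$bks) X <- cbind(X, pmax(t - b, 0))
  best$coef <- tryCatch(drop(solve(crossprod(X), crossprod(X, y))),
                        error = function(e) stats::lm.fit(X, y)$coefficients)
  best$fitted <- drop(X %*% best$coef)
  best_rss <- sum((y - best$fitted)^2)
  # restate the intercept/slope on the original time scale
  best$coef[1] <- best$coef[1] - best$coef[2] * mt
  slopes <- cumsum(best$coef[-1])
  structure(list(breakpoints = best$bks, slopes = unname(slopes),
                 coef = unname(best$coef), rss = best_rss,
                 fitted = unname(best$fitted), t = t, y = y,
                 n_breakpoints = n_breakpoints),
            class = "changepoint_fit")
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat(sprintf("piecewise-linear fit: breakpoints at %s min, slopes %s, RSS %.4g\n",
              paste(signif(x$breakpoints, 4), collapse = ", "),
              paste(signif(x$slopes, 3), collapse = ", "), x$rss))
  invisible(x)
}

#' Estimate the export window of a nuclear-concentration trace
#'
#' Fits two breakpoints to the pre-anaphase portion of the trace
#' (degradation after anaphase is excluded by construction) and reports
#' onset and stop as positive minutes before anaphase. The middle
#' segment must fall faster than both flanking segments (the nuclear
#' signal drops during export); fits violating this are flagged.
#'
#' @param t,y trace times (min) and nuclear concentration values.
#' @param anaphase_time anaphase anchor, min (same clock as `t`).
#' @param lookback length of the fitted pre-anaphase window, min.
#' @param span loess span for pre-smoothing; `NULL` fits the raw trace.
#' @return list `onset`, `stop` (min before anaphase), `valid`, `fit`,
#'   `flag` (reason when invalid).
#' @export
estimate_export_window <- function(t, y, anaphase_time, lookback = 25,
                                   span = 0.3) {
  keep <- t >= anaphase_time - lookback & t < anaphase_time &
    is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 8)
    return(list(onset = NA_real_, stop = NA_real_, valid = FALSE,
                fit = NULL, flag = "too_few_points"))
  ys <- if (!is.null(span)) loess_smooth(t, y, span) else y
  fit <- tryCatch(fit_piecewise_linear(t, ys, 2),
                  error = function(e) NULL)
  if (is.null(fit))
    return(list(onset = NA_real_, stop = NA_real_, valid = FALSE,
                fit = NULL, flag = "fit_failed"))
  sl <- fit$slopes
  valid <- sl[2] < sl[1] && sl[2] < sl[3] && sl[2] < 0
  list(onset = anaphase_time - fit$breakpoints[1],
       stop = anaphase_time - fit$breakpoints[2],
       valid = valid, fit = fit,
       flag = if (valid) "" else "middle_segment_not_falling")
}

#' 10-90% transition width at a breakpoint
#'
#' Locally fits a logistic blend of the two adjoining linear segments:
#' the slope switches logistically, `y'(t) = s1 + (s2 - s1)
#' plogis((t - b)/tau)`, so the fitted curve is `y = c + s1 t +
#' (s2 - s1) tau softplus((t - b)/tau)`. The width is the time for the
#' blend weight to travel 0.1 -> 0.9, i.e. `2 log(9) tau`. For each
#' candidate `(b, tau)` the three linear coefficients are profiled out
#' by ordinary least squares (variable projection); the global fit
#' supplies the starting breakpoint.
#'
#' @param t,y raw trace.
#' @param fit a `changepoint_fit`.
#' @param which_break index of the breakpoint in `fit$breakpoints`.
#' @param halfwin local window half-width, min.
#' @return width in minutes, or `NA` if the local fit does not converge
#'   or has fewer than 8 points.
#' @export
transition_width <- function(t, y, fit, which_break = 1, halfwin = 3) {
  b0 <- fit$breakpoints[which_break]
  keep <- abs(t - b0) <= halfwin & is.finite(y)
  if (sum(keep) < 8) return(NA_real_)
  tt <- t[keep]; yy <- y[keep]
  tc <- tt - b0 # center for numerical conditioning
  softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))
  sse <- function(par) {
    b <- par[1]; tau <- exp(par[2])
    X <- cbind(1, tc, tau * softplus((tc - b) / tau))
    f <- tryCatch(stats::lm.fit(X, yy), error = function(e) NULL)
    if (is.null(f)) return(Inf)
    sum(f$residuals^2)
  }
  fits <- lapply(c(0.05, 0.2, 1), function(tau0)
    tryCatch(stats::optim(c(0, log(tau0)), sse, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
             error = function(e) NULL))
  fits <- Filter(function(r) !is.null(r) && r$convergence == 0 &&
                   is.finite(r$value) && abs(r$par[1]) <= halfwin, fits)
  if (!length(fits)) return(NA_real_)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  2 * log(9) * exp(best$par[2])
}
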