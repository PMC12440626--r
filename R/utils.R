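# Shared numerical helpers.

# Logistic smooth switch. `width` is the 10-90% rise width in minutes, so
# the logistic time constant is width / (2 * log(9)).
switch_tau <- function(width) width / (2 * log(9))

smooth_step <- function(t, t0, tau) stats::plogis((t - t0) / tau)

#' Derive an order-independent per-unit random seed from a master seed
#'
#' Populations and frames draw their randomness from counter-derived
#' substreams so that simulating cell i does not depend on how many cells
#' were simulated before it.
#'
#' @param master integer master seed.
#' @param counter non-negative integer stream index.
#' @return an integer seed in `[0, 2^31)`.
#' @keywords internal
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + as.double(counter) * 1000003 + 12345) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# Capsule (rod with hemispherical caps) cross-section area in um^2 for a
# cell of total length L and width w, projected to 2-D.
capsule_area <- function(length_um, width_um) {
  stopifnot(all(length_um >= width_um))
  (length_um - width_um) * width_um + pi * (width_um / 2)^2
}
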