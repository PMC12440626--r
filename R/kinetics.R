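# Ground-truth single-cell kinetics of the cyclin reporter.
#
# The generator encodes, in one place, the event structure of the
# pre-mitotic nuclear-export phase: export of nuclear cyclin starts
# together with Plo1 enrichment at the spindle pole body (SPB) region
# (default 15 min before anaphase), stops at SPB separation (default
# 7 min before anaphase, i.e. Plo1 enrichment leads SPB separation by
# 8 min), and cyclin degradation begins at anaphase. All switches are
# logistic with a configurable 10-90% width (default 0.5 min).

#' Ground-truth timeline and kinetic parameters
#'
#' Builds the parameter set that drives [simulate_cell()] and
#' [sample_population()]. Defaults are the package's calibrated study
#' conditions; every value can be overridden by name.
#'
#' @param export_onset_offset minutes before anaphase at which nuclear
#'   export of the cyclin reporter begins (default 15).
#' @param spb_separation_offset minutes before anaphase at which SPBs
#'   separate and export stops (default 7).
#' @param plo1_onset_offset minutes before SPB separation at which Plo1
#'   starts to enrich at the SPB region (default 8, so Plo1 onset and
#'   export onset coincide under the defaults).
#' @param degradation_onset_offset minutes relative to anaphase at which
#'   cyclin degradation starts (default 0 = at anaphase).
#' @param transition_width 10-90% width, in minutes, of each logistic
#'   switch (default 0.5).
#' @param synthesis_rate reporter synthesis rate, a.u./min.
#' @param export_fraction fraction of the nuclear pool relocated to the
#'   cytoplasm over the export window; must lie in `[0, 1)`.
#' @param degradation_halflife post-onset half-life of the reporter, min.
#'   `Inf` disables degradation.
#' @param cycle_length_fn named numeric `c(intercept=, slope=)`: affine
#'   map from birth length (um) to cycle length (min); a negative slope
#'   builds size homeostasis into the population.
#' @param post_anaphase_duration minutes from anaphase to division.
#' @param growth_rate tip elongation rate, um/min; length is frozen from
#'   SPB separation until division.
#' @param birth_length_mean mean birth length, um.
#' @param cell_width rod width, um.
#' @param nuclear_radius nuclear radius, um (post-anaphase the two
#'   daughter nuclei jointly keep this cross-section area).
#' @param conc_scale initial whole-cell reporter concentration,
#'   a.u./um^2; sets the absolute intensity scale.
#' @param spb_rate accrual rate of reporter amount at the SPB focus for
#'   focus-forming species, a.u./min.
#' @param spb_max saturation amount of the SPB focus, a.u.
#' @param import_rate first-order nuclear import rate (1/min) used by
#'   the securin-like (`cut2`) species after SPB separation.
#' @param nuclear_fraction interphase nuclear share of the reporter
#'   amount (dimensionless).
#' @param cv named list of coefficients of variation applied across
#'   cells by [sample_population()]; names must match parameter names
#'   (plus `birth_length` and `cycle_length`).
#' @param ... overrides for any of the above.
#' @return an object of class `timeline_params`.
#' @export
timeline_params <- function(export_onset_offset = 15,
                            spb_separation_offset = 7,
                            plo1_onset_offset = 8,
                            degradation_onset_offset = 0,
                            transition_width = 0.5,
                            synthesis_rate = 700,
                            export_fraction = 0.4,
                            degradation_halflife = 3,
                            cycle_length_fn = c(intercept = 220, slope = -12),
                            post_anaphase_duration = 20,
                            growth_rate = 0.06,
                            birth_length_mean = 7,
                            cell_width = 3.8,
                            nuclear_radius = 1.2,
                            conc_scale = 3000,
                            spb_rate = 400,
                            spb_max = 1600,
                            import_rate = 0.08,
                            nuclear_fraction = 0.30,
                            cv = list(export_onset_offset = 0.04,
                                      spb_separation_offset = 0.04,
                                      plo1_onset_offset = 0.05,
                                      synthesis_rate = 0.10,
                                      export_fraction = 0.10,
                                      degradation_halflife = 0.10,
                                      nuclear_fraction = 0.08,
                                      spb_rate = 0.10,
                                      birth_length = 0.08,
                                      cycle_length = 0.03),
                            ...) {
  p <- c(as.list(environment()), list(...))
  p <- p[!duplicated(names(p))]
  extra <- setdiff(names(list(...)), names(formals(timeline_params)))
  if (length(extra))
    stop_config("unknown timeline parameter(s): %s", paste(extra, collapse = ", "))
  class(p) <- "timeline_params"
  validate_timeline_params(p)
  p
}

#' @rdname timeline_params
#' @param p a `timeline_params` object.
#' @export
validate_timeline_params <- function(p) {
  if (!(p$export_onset_offset > p$spb_separation_offset))
    stop_config("export_onset_offset (%.3g) must exceed spb_separation_offset (%.3g)",
                p$export_onset_offset, p$spb_separation_offset)
  if (!(p$spb_separation_offset > 0))
    stop_config("spb_separation_offset (%.3g) must be > 0", p$spb_separation_offset)
  if (!(p$transition_width > 0))
    stop_config("transition_width (%.3g) must be > 0", p$transition_width)
  if (p$export_fraction < 0 || p$export_fraction >= 1)
    stop_config("export_fraction (%.3g) must lie in [0, 1)", p$export_fraction)
  for (nm in c("synthesis_rate", "growth_rate", "spb_rate", "import_rate",
               "conc_scale", "degradation_halflife"))
    if (p[[nm]] < 0) stop_config("%s (%.3g) must be >= 0", nm, p[[nm]])
  if (p$plo1_onset_offset <= 0)
    stop_config("plo1_onset_offset (%.3g) must be > 0", p$plo1_onset_offset)
  invisible(p)
}

# Species-specific kinetic switches. `synth_mult` scales synthesis and
# the initial pool (used for the overexpressed N-terminal fragment).
species_kinetics <- function(species, p) {
  base <- list(export = FALSE, import = FALSE, degrade = FALSE,
               spb_rate = 0, nuclear_fraction = p$nuclear_fraction,
               synth_mult = 1)
  mod <- switch(species,
    cdc13 = list(export = TRUE, degrade = TRUE, spb_rate = 0.15 * p$spb_rate),
    cdc2 = list(export = TRUE),
    cut2 = list(import = TRUE, degrade = TRUE),
    mad3 = list(),
    plo1 = list(spb_rate = p$spb_rate, nuclear_fraction = 0.2),
    cdc13_1_177_OE = list(export = TRUE, synth_mult = 20),
    cdc13_NLS_KK = list(export = TRUE, degrade = TRUE, nuclear_fraction = 0.15),
    stop_config("unknown species '%s'", species))
  utils::modifyList(base, mod)
}

resolve_cell_params <- function(params, birth_length, species,
                                overrides = list()) {
  p <- utils::modifyList(unclass(params), overrides[setdiff(names(overrides),
                                                            "cycle_length")])
  class(p) <- "timeline_params"
  validate_timeline_params(p)
  kin <- species_kinetics(species, p)
  cyc <- unname(p$cycle_length_fn["intercept"] +
                p$cycle_length_fn["slope"] * birth_length)
  cyc <- cyc * (overrides$cycle_length %||% 1)
  if (cyc <= p$post_anaphase_duration + p$export_onset_offset + 5)
    stop_config("cycle length %.1f min too short for the mitotic timeline", cyc)
  ev <- c(birth = 0,
          division = cyc,
          anaphase = cyc - p$post_anaphase_duration)
  ev["spb_separation"] <- ev["anaphase"] - p$spb_separation_offset
  ev["export_onset"] <- ev["anaphase"] - p$export_onset_offset
  ev["plo1_onset"] <- ev["spb_separation"] - p$plo1_onset_offset
  ev["degradation_onset"] <- ev["anaphase"] + p$degradation_onset_offset
  list(p = p, kin = kin, events = ev, cycle_length = cyc,
       birth_length = birth_length)
}

cell_length_at <- function(cell, t_local) {
  rp <- cell$resolved
  t_freeze <- rp$events[["spb_separation"]]
  pmax(rp$birth_length,
       rp$birth_length + rp$p$growth_rate * pmin(pmax(t_local, 0), t_freeze))
}

#' Simulate one ground-truth cell trace
#'
#' Integrates the compartment amounts (nucleus, cytoplasm, SPB focus) of
#' one reporter species over one cell cycle. The dynamics are an ODE
#' with logistic smooth switches: synthesis into the compartments in
#' their interphase proportions; during the export window a constant
#' flux sized to relocate `export_fraction` of the nuclear amount at
#' onset moves nuclear reporter to the cytoplasm (so the nuclear trace
#' falls linearly, as observed traces do); degradation is first-order
#' after the degradation onset; focus-forming species accrue reporter
#' at the SPB by first-order binding to a finite site pool. Total
#' amount is conserved up to synthesis and degradation by construction.
#'
#' @param params a [timeline_params()] object.
#' @param birth_length birth length, um.
#' @param species one of `"cdc13"`, `"cdc2"`, `"cut2"`, `"mad3"`,
#'   `"plo1"`, `"cdc13_1_177_OE"`, `"cdc13_NLS_KK"`.
#' @param seed accepted for interface symmetry; the single-cell model is
#'   deterministic, so it is unused.
#' @param dt output time step, min.
#' @param cell_id identifier carried into the trace table.
#' @param overrides named list of per-cell parameter overrides (used by
#'   [sample_population()] for cell-to-cell variability).
#' @return a `gt_cell` object with fields `trace` (tidy data frame),
#'   `events` (named times, min, relative to birth at 0), `resolved`
#'   (per-cell parameters) and a dense solution used by [amounts_at()].
#' @export
simulate_cell <- function(params, birth_length, species = "cdc13",
                          seed = NULL, dt = 0.25, cell_id = "cell001",
                          overrides = list()) {
  if (birth_length <= 0) stop_config("birth_length must be > 0")
  rp <- resolve_cell_params(params, birth_length, species, overrides)
  p <- rp$p; kin <- rp$kin; ev <- rp$events
  tau <- switch_tau(p$transition_width)
  W <- p$export_onset_offset - p$spb_separation_offset
  kd <- if (kin$degrade) log(2) / p$degradation_halflife else 0

  A0 <- capsule_area(birth_length, p$cell_width)
  T0 <- p$conc_scale * A0 * kin$synth_mult
  pn <- kin$nuclear_fraction
  y0 <- c(N = pn * T0, C = (1 - pn) * T0, S = 0)
  # constant export flux moving export_fraction of the (predicted)
  # nuclear amount at onset over the window
  N_on <- pn * (T0 + p$synthesis_rate * kin$synth_mult * ev[["export_onset"]])
  J0 <- if (kin$export) p$export_fraction * N_on / W else 0

  deriv <- function(t, y, parms) {
    s_deg <- smooth_step(t, ev[["degradation_onset"]], tau)
    syn <- p$synthesis_rate * kin$synth_mult * (1 - s_deg)
    J <- J0 * (smooth_step(t, ev[["export_onset"]], tau) -
                 smooth_step(t, ev[["spb_separation"]], tau))
    imp <- if (kin$import)
      p$import_rate * smooth_step(t, ev[["spb_separation"]], tau) * y[["C"]]
    else 0
    spb_in <- if (kin$spb_rate > 0)
      kin$spb_rate * smooth_step(t, ev[["plo1_onset"]], tau) *
        max(0, 1 - y[["S"]] / p$spb_max)
    else 0
    deg <- kd * s_deg
    list(c(pn * syn - J + imp - deg * y[["N"]],
           (1 - pn) * syn + J - imp - spb_in - deg * y[["C"]],
           spb_in - deg * y[["S"]]))
  }

  dense_t <- seq(0, rp$cycle_length, by = 0.05)
  sol <- deSolve::ode(y0, dense_t, deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-8)
  dense <- as.matrix(sol)

  cell <- structure(list(cell_id = cell_id, species = species,
                         resolved = rp, events = ev, dense = dense),
                    class = "gt_cell")
  tg <- seq(0, rp$cycle_length, by = dt)
  cell$trace <- gt_trace_table(cell, tg)
  cell
}

#' Interpolate ground-truth amounts at arbitrary times
#'
#' @param cell a `gt_cell`.
#' @param t times in minutes relative to the cell's birth.
#' @return data frame with `nuclear_amount`, `cytoplasmic_amount`,
#'   `spb_amount`, `total_amount` (a.u.).
#' @export
amounts_at <- function(cell, t) {
  d <- cell$dense
  t <- pmin(pmax(t, d[1, "time"]), d[nrow(d), "time"])
  out <- data.frame(
    nuclear_amount = stats::approx(d[, "time"], d[, "N"], t)$y,
    cytoplasmic_amount = stats::approx(d[, "time"], d[, "C"], t)$y,
    spb_amount = stats::approx(d[, "time"], d[, "S"], t)$y)
  out$total_amount <- out$nuclear_amount + out$cytoplasmic_amount +
    out$spb_amount
  out
}

gt_trace_table <- function(cell, t) {
  rp <- cell$resolved
  am <- amounts_at(cell, t)
  len <- cell_length_at(cell, t)
  data.frame(cell_id = cell$cell_id, species = cell$species, t_min = t,
             am,
             nuclear_area_um2 = pi * rp$p$nuclear_radius^2,
             cell_area_um2 = capsule_area(len, rp$p$cell_width),
             length_um = len,
             birth_time = cell$events[["birth"]],
             plo1_onset = cell$events[["plo1_onset"]],
             export_onset = cell$events[["export_onset"]],
             spb_separation = cell$events[["spb_separation"]],
             anaphase = cell$events[["anaphase"]],
             division = cell$events[["division"]],
             birth_length_um = rp$birth_length,
             division_length_um = cell_length_at(cell, cell$events[["division"]]),
             row.names = NULL)
}

#' Sample a population of ground-truth cells
#'
#' Draws `n` cells with independent cell-to-cell jitter on the timeline
#' parameters (multiplicative, normal with the CVs in `params$cv`).
#' Each cell uses a counter-derived substream of the master seed, so the
#' population is order-independent and reproducible.
#'
#' @param params a [timeline_params()] object.
#' @param n number of cells (>= 1).
#' @param seed integer master seed.
#' @param species reporter species label for all cells.
#' @param birth_lengths optional fixed birth lengths (recycled to `n`);
#'   when `NULL` they are drawn around `birth_length_mean`.
#' @param dt output grid step, min.
#' @return a `gt_population`: list of `gt_cell`s plus the shared params.
#' @export
sample_population <- function(params, n, seed, species = "cdc13",
                              birth_lengths = NULL, dt = 0.25) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  validate_timeline_params(params)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, i))
    for (attempt in 1:100) {
      bl <- if (!is.null(birth_lengths))
        rep_len(birth_lengths, n)[i]
      else {
        cvb <- params$cv$birth_length %||% 0
        params$birth_length_mean * (1 + cvb * stats::rnorm(1))
      }
      ov <- list()
      for (nm in setdiff(names(params$cv), "birth_length")) {
        cvv <- params$cv[[nm]]
        mult <- 1 + cvv * stats::rnorm(1)
        if (nm == "cycle_length") ov[[nm]] <- mult
        else ov[[nm]] <- params[[nm]] * mult
      }
      ok <- bl > params$cell_width + 0.5 &&
        tryCatch({
          resolve_cell_params(params, bl, species, ov); TRUE
        }, error = function(e) FALSE)
      if (ok) break
    }
    if (!ok) stop_config("could not draw valid parameters for cell %d", i)
    cells[[i]] <- simulate_cell(params, bl, species = species, dt = dt,
                                cell_id = sprintf("cell%03d", i),
                                overrides = ov)
  }
  structure(list(cells = cells, params = params, species = species,
                 seed = seed), class = "gt_population")
}

#' Bind all per-cell trace tables of a population
#' @param pop a `gt_population`.
#' @return one tidy data frame, one row per cell per time point.
#' @export
pop_traces <- function(pop) {
  do.call(rbind, lapply(pop$cells, function(cl) cl$trace))
}

#' Write / read ground-truth trace tables as CSV
#' @param traces data frame from [pop_traces()] (or one cell's `trace`).
#' @param path file path.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Round-trip timeline parameters through YAML
#' @param params a `timeline_params` object.
#' @param path file path ending in `.yaml`/`.yml` (or `.json`).
#' @export
write_timeline_params <- function(params, path) {
  x <- unclass(params)
  x$cycle_length_fn <- as.list(x$cycle_length_fn)
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_timeline_params
#' @export
read_timeline_params <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  x$cycle_length_fn <- unlist(x$cycle_length_fn)
  do.call(timeline_params, x)
}
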