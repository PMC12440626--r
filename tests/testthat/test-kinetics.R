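# Ground-truth kinetic generator.

test_that("compartment amounts match a fine-step RK4 integration of the same fluxes", {
  p <- timeline_params()
  bl <- 7
  cell <- simulate_cell(p, bl)

  # independent integrator: events and fluxes written out from the
  # parameter definitions, fixed-step RK4 at a 100x finer step
  cyc <- 220 - 12 * bl
  ana <- cyc - p$post_anaphase_duration
  t_on <- ana - p$export_onset_offset
  t_spb <- ana - p$spb_separation_offset
  t_plo <- t_spb - p$plo1_onset_offset
  t_deg <- ana
  tau <- p$transition_width / (2 * log(9))
  A0 <- (bl - p$cell_width) * p$cell_width + pi * (p$cell_width / 2)^2
  T0 <- p$conc_scale * A0
  pn <- p$nuclear_fraction
  J0 <- p$export_fraction * pn * (T0 + p$synthesis_rate * t_on) /
    (p$export_onset_offset - p$spb_separation_offset)
  kd <- log(2) / p$degradation_halflife
  spb_rate <- 0.15 * p$spb_rate
  f <- function(t, y) {
    sdeg <- plogis((t - t_deg) / tau)
    syn <- p$synthesis_rate * (1 - sdeg)
    J <- J0 * (plogis((t - t_on) / tau) - plogis((t - t_spb) / tau))
    spb <- spb_rate * plogis((t - t_plo) / tau) * max(0, 1 - y[3] / p$spb_max)
    c(pn * syn - J - kd * sdeg * y[1],
      (1 - pn) * syn + J - spb - kd * sdeg * y[2],
      spb - kd * sdeg * y[3])
  }
  h <- 0.25 / 100
  y <- c(pn * T0, (1 - pn) * T0, 0)
  tt <- 0
  out <- matrix(NA_real_, nrow(cell$trace), 3)
  out[1, ] <- y
  row <- 2
  nsteps <- round(cyc / h)
  for (s in seq_len(nsteps)) {
    k1 <- f(tt, y); k2 <- f(tt + h / 2, y + h / 2 * k1)
    k3 <- f(tt + h / 2, y + h / 2 * k2); k4 <- f(tt + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    tt <- tt + h
    if (row <= nrow(cell$trace) &&
        abs(tt - cell$trace$t_min[row]) < h / 2) {
      out[row, ] <- y
      row <- row + 1
    }
  }
  got <- as.matrix(cell$trace[, c("nuclear_amount", "cytoplasmic_amount",
                                  "spb_amount")])
  scale <- pmax(abs(out), T0 * 1e-3)
  expect_lt(max(abs(got - out) / scale), 0.01)
})

test_that("amounts are conserved and non-negative, with ordered events", {
  p <- timeline_params()
  for (sp in c("cdc13", "cdc2", "cut2", "mad3", "plo1", "cdc13_NLS_KK")) {
    cell <- simulate_cell(p, 7.5, species = sp)
    tr <- cell$trace
    expect_lt(max(abs(tr$total_amount -
                        (tr$nuclear_amount + tr$cytoplasmic_amount +
                           tr$spb_amount)) / tr$total_amount), 1e-9)
    expect_true(all(tr$nuclear_amount >= 0 & tr$cytoplasmic_amount >= 0 &
                      tr$spb_amount >= -1e-9))
    ev <- cell$events
    expect_true(ev[["plo1_onset"]] <= ev[["export_onset"]] + 1e-9)
    expect_lt(ev[["export_onset"]], ev[["spb_separation"]])
    expect_lt(ev[["spb_separation"]], ev[["anaphase"]])
    expect_lt(ev[["anaphase"]], ev[["division"]])
    # total non-decreasing before degradation onset
    pre <- tr$t_min < ev[["degradation_onset"]] - 1
    expect_true(all(diff(tr$total_amount[pre]) >= -1e-6))
  }
})

test_that("nuclear amount falls strictly during export and the exported share matches", {
  p <- timeline_params()
  cell <- simulate_cell(p, 7)
  tr <- cell$trace; ev <- cell$events
  win <- tr$t_min > ev[["export_onset"]] + 1 &
    tr$t_min < ev[["spb_separation"]] - 1
  expect_true(all(diff(tr$nuclear_amount[win]) < 0))
  # amount relocated ~ export_fraction of the nuclear pool at onset
  n_on <- tr$nuclear_amount[which.min(abs(tr$t_min - ev[["export_onset"]]))]
  n_off <- tr$nuclear_amount[which.min(abs(tr$t_min - ev[["spb_separation"]]))]
  synth_gain <- p$nuclear_fraction * p$synthesis_rate *
    (ev[["spb_separation"]] - ev[["export_onset"]])
  exported <- n_on + synth_gain - n_off
  expect_equal(exported / n_on, p$export_fraction, tolerance = 0.05)
})

test_that("export_fraction 0 reproduces the flat-ratio species shape", {
  p0 <- timeline_params(export_fraction = 0, degradation_halflife = Inf)
  a <- simulate_cell(p0, 7, species = "cdc2") # export machinery, zero flux
  b <- simulate_cell(p0, 7, species = "mad3")
  r <- a$trace$nuclear_amount / b$trace$nuclear_amount
  expect_lt(diff(range(r)), 1e-9)
  r2 <- a$trace$cytoplasmic_amount / b$trace$cytoplasmic_amount
  expect_lt(diff(range(r2)), 1e-9)
})

test_that("a narrow switch localizes the slope change to the breakpoints", {
  p <- timeline_params(transition_width = 0.02, cv = list())
  cell <- simulate_cell(p, 7, dt = 0.05)
  tr <- cell$trace; ev <- cell$events
  sl <- diff(tr$nuclear_amount) / diff(tr$t_min)
  mid <- tr$t_min[-1] - 0.025
  # slopes are constant away from the two switch times
  away <- abs(mid - ev[["export_onset"]]) > 0.5 &
    abs(mid - ev[["spb_separation"]]) > 0.5 &
    mid > 1 & mid < ev[["anaphase"]] - 1
  pre <- away & mid < ev[["export_onset"]]
  during <- away & mid > ev[["export_onset"]] & mid < ev[["spb_separation"]]
  expect_lt(diff(range(sl[pre])), 1e-3 * abs(mean(sl[during])))
  expect_lt(diff(range(sl[during])), 1e-2 * abs(mean(sl[during])))
  expect_lt(mean(sl[during]), 0)
})

test_that("cut2 imports after SPB separation instead of exporting", {
  p <- timeline_params()
  cell <- simulate_cell(p, 7, species = "cut2")
  tr <- cell$trace; ev <- cell$events
  c_nuc <- tr$nuclear_amount / tr$nuclear_area_um2
  pre <- tr$t_min > ev[["export_onset"]] & tr$t_min < ev[["spb_separation"]]
  imp <- tr$t_min > ev[["spb_separation"]] + 0.5 &
    tr$t_min < ev[["anaphase"]] - 0.5
  # no drop before separation (concentration keeps its interphase trend)
  expect_true(min(diff(c_nuc[pre])) > -1e-6)
  expect_true(all(diff(tr$nuclear_amount[imp]) > 0))
})

test_that("invalid parameter orderings raise configuration errors naming the inequality", {
  expect_error(timeline_params(export_onset_offset = 5),
               "export_onset_offset.*spb_separation_offset")
  expect_error(timeline_params(transition_width = 0), "transition_width")
  expect_error(timeline_params(export_fraction = 1), "export_fraction")
  expect_error(timeline_params(spb_separation_offset = -1),
               "spb_separation_offset|export_onset_offset")
  expect_error(simulate_cell(timeline_params(), -1), "birth_length")
})

test_that("population sampling is seeded, order-independent and honors CVs", {
  p <- timeline_params()
  pop1 <- sample_population(p, 5, seed = 7)
  pop2 <- sample_population(p, 5, seed = 7)
  expect_equal(pop_traces(pop1), pop_traces(pop2))
  # cell i does not depend on how many cells precede it
  pop3 <- sample_population(p, 3, seed = 7)
  expect_equal(pop1$cells[[2]]$trace, pop3$cells[[2]]$trace)
  expect_error(sample_population(p, 0, seed = 1), "n")

  p0 <- timeline_params(cv = list())
  popc <- sample_population(p0, 4, seed = 1, birth_lengths = 7)
  offs <- vapply(popc$cells, function(cl)
    cl$events[["anaphase"]] - cl$events[["export_onset"]], 0)
  expect_true(all(offs == offs[1]))
  expect_equal(popc$cells[[1]]$trace[, -1],
               simulate_cell(p0, 7, cell_id = "x")$trace[, -1])
})

test_that("sampled export-onset offsets center on the configured 15 min", {
  pop <- fx_pop200()
  offs <- vapply(pop$cells, function(cl)
    cl$events[["anaphase"]] - cl$events[["export_onset"]], 0)
  se <- sd(offs) / sqrt(length(offs))
  expect_lt(abs(mean(offs) - 15), 2 * se)
})

test_that("size homeostasis: birth length anti-correlates with cycle length", {
  pop <- fx_pop200()
  bl <- vapply(pop$cells, function(cl) cl$resolved$birth_length, 0)
  cyc <- vapply(pop$cells, function(cl) cl$events[["division"]], 0)
  expect_lt(cor(bl, cyc), 0)
})

test_that("timeline parameters and traces round-trip through YAML/CSV", {
  p <- timeline_params(export_fraction = 0.33, cv = list(birth_length = 0.1))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_timeline_params(p, f)
  p2 <- read_timeline_params(f)
  expect_equal(unclass(p2), unclass(p))

  pop <- sample_population(timeline_params(), 2, seed = 1)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_traces(pop_traces(pop), tf)
  back <- read_traces(tf)
  expect_equal(back$nuclear_amount, pop_traces(pop)$nuclear_amount,
               tolerance = 1e-12)
  expect_identical(names(back), names(pop_traces(pop)))
})
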