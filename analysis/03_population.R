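#!/usr/bin/env Rscript
# Stage 3: population comparisons on trace-level simulations.
#
# Wild-type vs NLS-mutant reporter populations imaged at 5 min
# intervals over two full cycles: N/C ratios normalized to the
# wild-type mean, cycle length and pre-division length with Wilcoxon
# rank-sum tests, and the size-homeostasis regression of cycle length
# on birth length.
#
# Run from the repository root: Rscript analysis/03_population.R

suppressMessages(library(nucexport))

out <- "results/population"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- run_config()

n <- 44 # cells per strain, the scale of the pooled ensembles
wt <- sample_population(timeline_params(), n, seed = 21, species = "cdc13",
                        dt = 5)
kk <- sample_population(timeline_params(), n, seed = 22,
                        species = "cdc13_NLS_KK", dt = 5)

interphase_ratio <- function(pop) {
  vapply(pop$cells, function(cl) {
    d <- cl$trace
    i <- which(d$t_min < cl$events[["export_onset"]] - 5)
    mean((d$nuclear_amount[i] / d$nuclear_area_um2[i]) /
           (d$cytoplasmic_amount[i] /
              (d$cell_area_um2[i] - d$nuclear_area_um2[i])))
  }, 0)
}
r_wt <- interphase_ratio(wt)
r_kk <- interphase_ratio(kk)
nc <- data.frame(
  strain = rep(c("wild_type", "NLS_KK"), each = n),
  nc_ratio_normalized = c(normalize_to_reference(r_wt, r_wt),
                          normalize_to_reference(r_kk, r_wt)))
utils::write.csv(nc, file.path(out, "nc_ratios.csv"), row.names = FALSE)

metrics <- function(pop, strain) {
  tr <- pop_traces(pop)
  cm <- cycle_metrics(tr, window = c(-1, max(tr$division) + 1))
  cbind(strain = strain, cm$cells)
}
cyc <- rbind(metrics(wt, "wild_type"), metrics(kk, "NLS_KK"))
utils::write.csv(cyc, file.path(out, "cycle_metrics.csv"), row.names = FALSE)

x <- cyc$cycle_length_min[cyc$strain == "wild_type"]
y <- cyc$cycle_length_min[cyc$strain == "NLS_KK"]
wt_len <- cyc$predivision_length_um[cyc$strain == "wild_type"]
kk_len <- cyc$predivision_length_um[cyc$strain == "NLS_KK"]
tests <- data.frame(
  quantity = c("cycle_length", "predivision_length"),
  p_value = c(wilcoxon_rank_sum(x, y)$p_value,
              wilcoxon_rank_sum(wt_len, kk_len)$p_value))
utils::write.csv(tests, file.path(out, "wilcoxon_tests.csv"),
                 row.names = FALSE)

hf <- homeostasis_fit(cyc$birth_length_um[cyc$strain == "wild_type"], x)
utils::write.csv(data.frame(slope = hf$slope, intercept = hf$intercept,
                            pearson_r = hf$r, n = hf$n),
                 file.path(out, "homeostasis_fit.csv"), row.names = FALSE)

bs <- box_summary(x)
message(sprintf("wild-type cycle length: median %.0f min [%0.f, %.0f] (n = %d)",
                bs$median, bs$q1, bs$q3, bs$n))
message(sprintf("normalized N/C ratio, NLS mutant vs wild type: %.2f vs %.2f",
                mean(nc$nc_ratio_normalized[nc$strain == "NLS_KK"]),
                mean(nc$nc_ratio_normalized[nc$strain == "wild_type"])))
message(sprintf("Wilcoxon p (cycle length): %.3f; homeostasis slope %.1f min/um (R = %.2f)",
                tests$p_value[1], hf$slope, hf$r))
message("tables in ", out)
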