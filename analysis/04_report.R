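#!/usr/bin/env Rscript
# Stage 4: figures and a markdown summary from the stage-2/3 tables.
#
# Every number in the report comes from a CSV written by an earlier
# stage; nothing is computed only inside plotting code.
#
# Run from the repository root after 02_analyze.R and 03_population.R.

suppressMessages({
  library(nucexport)
  library(ggplot2)
})

run_dir <- "results/run1"
pop_dir <- "results/population"
out <- "results/report"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meas <- utils::read.csv(file.path(run_dir, "measurements.csv"))
wins <- utils::read.csv(file.path(run_dir, "export_windows.csv"))

# event-aligned ensemble of nuclear concentration (anaphase = 0)
ok <- wins$valid & is.finite(wins$anaphase_time)
traces <- lapply(wins$track[ok], function(tr) {
  d <- meas[meas$track == tr, ]
  data.frame(t = d$t_min, value = d$c_nuc)
})
names(traces) <- as.character(wins$track[ok])
anchors <- stats::setNames(wins$anaphase_time[ok], wins$track[ok])
ens <- align_and_pool(traces, anchors, interval = 0.25)
ens_df <- data.frame(t = ens$grid, mean = ens$mean, sd = ens$sd, n = ens$n)
ens_df <- ens_df[ens_df$n >= 2, ]
utils::write.csv(ens_df, file.path(out, "ensemble_nuclear_concentration.csv"),
                 row.names = FALSE)

thin <- do.call(rbind, lapply(names(traces), function(id)
  data.frame(track = id, t = traces[[id]]$t - anchors[id],
             value = traces[[id]]$value)))
p1 <- ggplot() +
  geom_line(data = thin, aes(t, value, group = track),
            linewidth = 0.2, alpha = 0.35) +
  geom_ribbon(data = ens_df, aes(t, ymin = mean - sd, ymax = mean + sd),
              fill = "steelblue", alpha = 0.3) +
  geom_line(data = ens_df, aes(t, mean), color = "steelblue",
            linewidth = 0.9) +
  geom_vline(xintercept = c(-15, -7), linetype = "dashed") +
  labs(x = "time relative to anaphase (min)",
       y = "nuclear concentration (a.u./px^2)",
       title = "Nuclear reporter concentration aligned to anaphase") +
  theme_classic()
ggsave(file.path(out, "ensemble_nuclear_concentration.png"), p1,
       width = 7, height = 4.5, dpi = 150)

# per-cell export windows
p2 <- ggplot(wins[ok, ]) +
  geom_segment(aes(x = -onset_before_anaphase, xend = -stop_before_anaphase,
                   y = reorder(factor(track), onset_before_anaphase),
                   yend = reorder(factor(track), onset_before_anaphase)),
               linewidth = 2, color = "grey40") +
  geom_vline(xintercept = c(-15, -7), linetype = "dashed") +
  labs(x = "time relative to anaphase (min)", y = "cell",
       title = "Per-cell export windows") +
  theme_classic()
ggsave(file.path(out, "export_windows.png"), p2, width = 6, height = 5,
       dpi = 150)

# a kymograph of one analyzed cell, rebuilt from the run config
cfg <- read_run_config(file.path(run_dir, "run_config.yaml"))
movie <- simulate_run(cfg)
ky <- build_kymograph(movie, 1, "reporter", subsample = 4)
write_kymograph(ky, file.path(out, "kymograph_cell1.csv"),
                file.path(out, "kymograph_cell1.tif"))

# population panels
cyc <- utils::read.csv(file.path(pop_dir, "cycle_metrics.csv"))
tests <- utils::read.csv(file.path(pop_dir, "wilcoxon_tests.csv"))
hf <- utils::read.csv(file.path(pop_dir, "homeostasis_fit.csv"))
nc <- utils::read.csv(file.path(pop_dir, "nc_ratios.csv"))

p3 <- ggplot(cyc, aes(strain, cycle_length_min)) +
  geom_boxplot(outlier.shape = NA, width = 0.5) +
  geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
  labs(y = "cycle length (min)", x = NULL,
       subtitle = sprintf("Wilcoxon rank sum p = %.3f",
                          tests$p_value[tests$quantity == "cycle_length"])) +
  theme_classic()
ggsave(file.path(out, "cycle_length.png"), p3, width = 4, height = 4,
       dpi = 150)

wtc <- cyc[cyc$strain == "wild_type", ]
p4 <- ggplot(wtc, aes(birth_length_um, cycle_length_min)) +
  geom_point(alpha = 0.6) +
  geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
  labs(x = "birth length (um)", y = "cycle length (min)",
       subtitle = sprintf("slope %.1f min/um, Pearson R = %.2f",
                          hf$slope, hf$pearson_r)) +
  theme_classic()
ggsave(file.path(out, "homeostasis.png"), p4, width = 4.5, height = 4,
       dpi = 150)

# markdown summary
okw <- wins$valid & is.finite(wins$onset_before_anaphase)
iv <- wins$spb_separation_time - wins$plo1_onset_time
lines <- c(
  "# Export-timing report",
  "",
  sprintf("- cells analyzed: %d (%d with a valid export window)",
          nrow(wins), sum(okw)),
  sprintf("- export onset: median %.2f min before anaphase",
          median(wins$onset_before_anaphase[okw])),
  sprintf("- export stop: median %.2f min before anaphase",
          median(wins$stop_before_anaphase[okw])),
  sprintf("- Plo1 onset to SPB separation: median %.2f min (n = %d)",
          median(iv, na.rm = TRUE), sum(is.finite(iv))),
  sprintf("- onset transition width: median %.2f min",
          median(wins$onset_width_min[okw], na.rm = TRUE)),
  sprintf("- wild-type homeostasis: slope %.1f min/um, R = %.2f (n = %d)",
          hf$slope, hf$pearson_r, hf$n),
  sprintf("- normalized N/C ratio (NLS mutant / wild type): %.2f",
          mean(nc$nc_ratio_normalized[nc$strain == "NLS_KK"])),
  "",
  "Figures: ensemble_nuclear_concentration.png, export_windows.png,",
  "cycle_length.png, homeostasis.png, kymograph_cell1.csv/.tif")
writeLines(lines, file.path(out, "report.md"))
message("report in ", out)
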