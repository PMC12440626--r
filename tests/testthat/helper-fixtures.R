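# Shared fixtures, built in code and cached for the duration of a suite
# run. Movies are small (few cells, reduced field) except where a test
# explicitly needs the full study conditions.

.fx_cache <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (!exists(key, envir = .fx_cache)) assign(key, builder(), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

# 6-cell noisy movie at 15 s frames with all four channels.
fx_movie6 <- function() fx_cached("movie6", function() {
  cfg <- run_config(seed = 11, n_cells = 6, t_end = 30,
                    optics = optics_config(frame_interval = 0.25,
                                           field = c(256L, 512L)))
  mv <- simulate_run(cfg)
  list(movie = mv, config = cfg)
})

fx_movie6_analysis <- function() fx_cached("movie6_analysis", function() {
  fx <- fx_movie6()
  analyze_movie(fx$movie, fx$config)
})

# Tiny noise-free movie (1 static cell, 5 frames) for geometry and
# kymograph tests.
fx_movie1 <- function() fx_cached("movie1", function() {
  p <- timeline_params(cv = list(), growth_rate = 0)
  pop <- sample_population(p, 1, seed = 3, birth_lengths = 8)
  opt <- optics_config(frame_interval = 0.25, field = c(128L, 196L),
                       psf_sigma = 1)
  render_movie(pop, opt, seed = 3, t_end = 1,
               channels = c("outline", "nucmarker", "reporter", "spb"),
               noise = FALSE)
})

# 200-cell sampled population shared by sampler/homeostasis tests.
fx_pop200 <- function() fx_cached("pop200", function() {
  sample_population(timeline_params(), 200, seed = 5)
})

# Deterministic disc painter for segmentation fixtures.
fx_disc_image <- function(dim = c(64, 64), centers, radius = 6,
                          fg = 10, bg = 0) {
  img <- matrix(bg, dim[1], dim[2])
  lab <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(nrow(centers))) {
    for (r in seq_len(dim[1])) for (c in seq_len(dim[2])) {
      if ((r - centers[i, 1])^2 + (c - centers[i, 2])^2 <= radius^2) {
        img[r, c] <- fg
        lab[r, c] <- i
      }
    }
  }
  list(img = img, labels = lab)
}

# Three-segment export-like trace on a 15 s grid with optional noise.
fx_export_trace <- function(onset = 15, stop = 7, noise_frac = 0,
                            interval = 0.25, lookback = 25,
                            slopes = c(0.5, -3, 0.2), level = 100) {
  t <- seq(-lookback, -interval, by = interval)
  y <- ifelse(t < -onset, level + slopes[1] * (t + onset),
              ifelse(t < -stop, level + slopes[2] * (t + onset),
                     level + slopes[2] * (onset - stop) +
                       slopes[3] * (t + stop)))
  if (noise_frac > 0)
    y <- y + stats::rnorm(length(t), 0, noise_frac * diff(range(y)))
  list(t = t, y = y)
}
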