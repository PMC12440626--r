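# Quantification: background, compartment measurements, top-k, ROIs,
# ratios, normalization, loess.

test_that("background estimation recovers off-cell levels and is linear", {
  img <- matrix(7, 80, 80)
  cells <- matrix(0L, 80, 80); cells[30:50, 30:50] <- 1L
  img[cells == 1L] <- 99
  expect_equal(estimate_background(img, cells), 7)
  expect_equal(estimate_background(2 * img, cells), 14)
  expect_error(estimate_background(img, matrix(1L, 80, 80)), "background")
})

test_that("background matches the configured level on a noise-free frame within 0.5%", {
  mv <- fx_movie1()
  b <- estimate_background(mv$frames[[1]]$reporter, mv$cell_labels[[1]])
  expect_equal(b, mv$optics$background_level,
               tolerance = 0.005 * mv$optics$background_level)
})

test_that("measure_cell implements the subtraction formulas exactly", {
  # arithmetic of the quantification rule: c_cyt = (1000-600)/(200-50)
  img <- matrix(0, 20, 20)
  cell <- matrix(FALSE, 20, 20); cell[1:10, 1:20] <- TRUE # 200 px
  nuc <- matrix(FALSE, 20, 20); nuc[1:5, 1:10] <- TRUE    # 50 px
  img[nuc] <- 12               # I_nuc = 600
  img[cell & !nuc] <- 400 / 150 # I_cyt = 400
  m <- measure_cell(img, cell, nuc, b = 0)
  expect_equal(m$I_cell, 1000)
  expect_equal(m$I_nuc, 600)
  expect_equal(m$c_cyt, (1000 - 600) / (200 - 50))
  expect_equal(m$c_cyt, 2 + 2 / 3)
  # identities hold exactly
  expect_identical(m$I_cell, m$I_nuc + m$I_cyt)
  expect_identical(m$A_cell, m$A_nuc + m$A_cyt)
})

test_that("a uniform cell has equal nuclear and cytoplasmic concentration", {
  img <- matrix(0, 30, 30)
  cell <- matrix(FALSE, 30, 30); cell[5:25, 5:25] <- TRUE
  nuc <- matrix(FALSE, 30, 30); nuc[10:15, 10:15] <- TRUE
  img[cell] <- 3.5
  m <- measure_cell(img, cell, nuc, b = 0)
  expect_equal(m$c_nuc, 3.5)
  expect_equal(m$c_cyt, 3.5)
  # background subtraction shifts concentrations, identity survives
  m2 <- measure_cell(img + 2, cell, nuc, b = 2)
  expect_equal(m2$c_nuc, 3.5)
  expect_equal(m2$I_cell, m2$I_nuc + m2$I_cyt)
  # A_cyt = 0: c_cyt missing, no error
  m3 <- measure_cell(img, nuc, nuc, b = 0)
  expect_true(is.na(m3$c_cyt))
  # negative integrals clamp at zero with a flag
  m4 <- measure_cell(img, cell, nuc, b = 100)
  expect_true(m4$clamped)
  expect_gte(m4$I_cell, 0)
})

test_that("measured concentration ratio matches generator truth on noise-free frames", {
  mv <- fx_movie1()
  img <- mv$frames[[1]]$reporter
  cell <- mv$cell_labels[[1]] == 1
  nuc <- mv$nucleus_labels[[1]] == 1
  m <- measure_cell(img, cell, nuc, b = mv$optics$background_level)
  tf <- mv$truth$frames[mv$truth$frames$t_abs == mv$times[1], ]
  truth_ratio <- (tf$nuclear_amount / sum(nuc)) /
    (tf$cytoplasmic_amount / (sum(cell) - sum(nuc)))
  expect_equal(m$c_nuc / m$c_cyt, truth_ratio, tolerance = 0.02)
})

test_that("top-k mean equals the full-sort oracle and is monotone in k", {
  img <- matrix(c(9, 5, 5, 2, 1, 0), 2, 3)
  mask <- matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), 2, 3)
  expect_equal(topk_mean(img, mask, 3), (9 + 5 + 5) / 3)
  expect_equal(topk_mean(img, mask, 5), mean(c(9, 5, 5, 2, 1)))
  expect_error(topk_mean(img, mask, 6, cell_id = "c7"), "c7")
  set.seed(31)
  for (rep in 1:20) {
    v <- rnorm(200)
    img <- matrix(v, 10, 20)
    msk <- matrix(sample(c(TRUE, FALSE), 200, TRUE), 10, 20)
    k <- sample.int(sum(msk), 1)
    oracle <- mean(sort(img[msk], decreasing = TRUE)[1:k])
    expect_identical(topk_mean(img, msk, k), oracle)
  }
  v <- rpois(100, 50)
  img <- matrix(v, 10, 10); msk <- matrix(TRUE, 10, 10)
  tk <- vapply(1:100, function(k) topk_mean(img, msk, k), 0)
  expect_true(all(diff(tk) <= 1e-12)) # decreasing k never decreases it
  expect_equal(tk[100], mean(v))
})

test_that("two-ROI cytoplasmic mean is exact on uniform cytoplasm and symmetric", {
  img <- matrix(0, 40, 60)
  cell <- matrix(FALSE, 40, 60); cell[15:25, 5:55] <- TRUE
  nuc <- matrix(FALSE, 40, 60); nuc[17:23, 27:33] <- TRUE
  img[cell] <- 4; img[nuc] <- 11
  expect_equal(two_roi_cytoplasm(img, cell, nuc), 4)
  # mirrored cell gives the same answer
  expect_equal(two_roi_cytoplasm(img[, 60:1], cell[, 60:1], nuc[, 60:1]), 4)
})

test_that("two-ROI estimate matches truth cytoplasmic concentration on a rendered frame", {
  mv <- fx_movie1()
  img <- mv$frames[[1]]$reporter - mv$optics$background_level
  cell <- mv$cell_labels[[1]] == 1
  nuc <- mv$nucleus_labels[[1]] == 1
  tf <- mv$truth$frames[mv$truth$frames$t_abs == mv$times[1], ]
  truth_c <- tf$cytoplasmic_amount / (sum(cell) - sum(nuc))
  expect_equal(two_roi_cytoplasm(img, cell, nuc), truth_c, tolerance = 0.02)
})

test_that("N/C ratios and wild-type normalization behave as defined", {
  m <- data.frame(c_nuc = c(3, 4, 2), c_cyt = c(3, 2, 0))
  r <- nc_ratio(m)
  expect_equal(r[1], 1)
  expect_equal(r[2], 2)
  expect_true(is.na(r[3]))
  ref <- c(2, 2, 2, 2)
  expect_equal(mean(normalize_to_reference(ref, ref)), 1)
  expect_error(normalize_to_reference(1, numeric(0)), "empty")
})

test_that("min-max normalization attains 0 and 1 and is affine-invariant", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_error(minmax_normalize(rep(3, 5)), "constant")
  set.seed(32)
  for (rep in 1:1000) {
    x <- rnorm(sample(5:30, 1))
    nx <- minmax_normalize(x)
    expect_identical(range(nx), c(0, 1))
  }
  x <- rnorm(20)
  expect_equal(minmax_normalize(3 * x - 7), minmax_normalize(x))
})

test_that("loess smoothing reproduces polynomials and matches a direct tricube WLS oracle", {
  t <- seq(0, 10, by = 0.25)
  quad <- 2 - 0.5 * t + 0.3 * t^2
  expect_equal(loess_smooth(t, quad, 0.3), quad, tolerance = 1e-8)
  expect_equal(loess_smooth(t, rep(4, length(t)), 0.5), rep(4, length(t)),
               tolerance = 1e-10)

  # independent implementation: tricube-weighted local quadratic WLS
  direct_loess <- function(t, y, span) {
    n <- length(t); q <- floor(n * span)
    vapply(t, function(x0) {
      d <- abs(t - x0)
      h <- sort(d)[q]
      w <- pmax(0, 1 - (d / h)^3)^3
      use <- w > 0
      X <- cbind(1, t[use] - x0, (t[use] - x0)^2)
      W <- w[use]
      beta <- solve(crossprod(X * sqrt(W)), crossprod(X * W, y[use]))
      beta[1]
    }, 0)
  }
  set.seed(33)
  y <- sin(t) + rnorm(length(t), 0, 0.1)
  expect_equal(loess_smooth(t, y, 0.3), direct_loess(t, y, 0.3),
               tolerance = 1e-6)
  expect_equal(loess_smooth(t, y, 0.6), direct_loess(t, y, 0.6),
               tolerance = 1e-6)

  expect_warning(loess_smooth(t[1:8], y[1:8], 0.3), "degree 1")
  expect_error(loess_smooth(t[1:4], y[1:4], 0.3), "5 points")
  expect_error(loess_smooth(t, y, 0), "span")
})
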