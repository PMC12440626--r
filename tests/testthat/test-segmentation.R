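# Segmentation: Otsu thresholding, labeling, assignment, border
# filtering, tracking.

otsu_bruteforce_8bit <- function(v) {
  # exhaustive search over all 255 cut points of an 8-bit histogram,
  # maximizing between-class variance; ties -> lower cut
  h <- tabulate(v + 1L, 256)
  best <- -Inf; kbest <- NA
  for (k in 1:255) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum((0:(k - 1)) * h[1:k]) / w0
    m1 <- sum((k:255) * h[(k + 1):256]) / w1
    bcv <- w0 * w1 * (m0 - m1)^2
    if (bcv > best + 1e-9) { best <- bcv; kbest <- k }
  }
  kbest
}

test_that("Otsu equals exhaustive between-class-variance search on 8-bit data", {
  set.seed(21)
  for (rep in 1:20) {
    v <- as.integer(c(rpois(300, sample(30:80, 1)),
                      rpois(100, sample(120:220, 1))))
    v <- pmin(v, 255L)
    v <- c(0L, 255L, v) # span the full 8-bit range so bins = grey levels
    thr <- otsu_threshold(v)
    k <- otsu_bruteforce_8bit(v)
    # implementation threshold separates bins [0..k-1] from [k..255]
    expect_true(all(v[v <= thr] <= k - 1))
    expect_true(all(v[v > thr] >= k))
    # and classifies every value exactly as the brute-force cut does
    expect_identical(v > thr, v >= k)
  }
})

test_that("Otsu warns on constant images and breaks ties toward the lower threshold", {
  expect_warning(thr <- otsu_threshold(matrix(5, 4, 4)), "constant")
  expect_true(is.na(thr))
  # two-level data: any cut between the levels is a tie on real data;
  # symmetric four-level data exercises the tie-break
  v <- rep(c(0L, 85L, 170L, 255L), each = 10)
  thr <- otsu_threshold(v)
  vb <- otsu_bruteforce_8bit(v)
  expect_identical(v > thr, v >= vb)
})

test_that("perfect two-level discs are recovered exactly without blur", {
  fx <- fx_disc_image(centers = rbind(c(20, 20), c(40, 45)))
  lab <- segment_nuclei(fx$img, blur_sigma = 0, min_area = 5)
  expect_equal(sort(unique(as.integer(lab))), c(0L, 1L, 2L))
  expect_true(all((lab > 0) == (fx$img > 0)))
  expect_warning(empty <- segment_nuclei(matrix(3, 16, 16)), "constant")
  expect_true(all(empty == 0))
})

test_that("two disjoint synthetic capsules give exactly two cell labels", {
  img <- matrix(0, 80, 120)
  img[30:40, 10:50] <- 60
  img[55:65, 60:110] <- 60
  lab <- segment_cells(img, blur_sigma = 1, min_area = 50)
  expect_equal(max(lab), 2)
})

test_that("segmentation of a rendered 20-cell frame overlaps truth (IoU)", {
  p <- timeline_params()
  pop <- sample_population(p, 20, seed = 9)
  opt <- optics_config(frame_interval = 0.25)
  fr <- render_frame(pop, t = 100, opt, seed = 9,
                     channels = c("outline", "nucmarker"))
  cells <- segment_cells(fr$images$outline, blur_sigma = 1, min_area = 200)
  nucs <- segment_nuclei(fr$images$nucmarker, blur_sigma = 1.5)
  iou <- function(a, b) sum(a & b) / sum(a | b)
  for (i in 1:20) {
    truth <- fr$cell_labels == i
    hit <- as.integer(names(sort(table(cells[truth & cells > 0]),
                                 decreasing = TRUE))[1])
    expect_gte(iou(cells == hit, truth), 0.9)
    truth_n <- fr$nucleus_labels == i
    hitn <- as.integer(names(sort(table(nucs[truth_n & nucs > 0]),
                                  decreasing = TRUE))[1])
    expect_gte(iou(nucs == hitn, truth_n), 0.85)
  }
  # intensity-scale invariance up to histogram binning
  nucs2 <- segment_nuclei(fr$images$nucmarker * 3.7, blur_sigma = 1.5)
  expect_lt(mean((nucs > 0) != (nucs2 > 0)), 0.01)
})

test_that("nucleus assignment follows the centroid rule and matches overlap", {
  cells <- matrix(0L, 40, 40); cells[5:35, 5:20] <- 1L; cells[5:35, 25:38] <- 2L
  nuc <- matrix(0L, 40, 40); nuc[10:14, 8:12] <- 1L
  asg <- assign_nuclei(cells, nuc)
  expect_equal(asg$cell[asg$nucleus == 1], 1L)
  # centroid on background -> dropped with reason
  nuc2 <- matrix(0L, 40, 40); nuc2[1:3, 22:24] <- 1L
  cells0 <- matrix(0L, 40, 40)
  asg2 <- assign_nuclei(cells0, nuc2)
  expect_equal(asg2$cell, 0L)
  expect_match(asg2$reason, "background")
  expect_error(assign_nuclei(cells, matrix(0L, 10, 10)), "shape")

  # oracle: maximal-pixel-overlap assignment agrees whenever overlap >= 50%
  set.seed(22)
  for (rep in 1:50) {
    fx <- fx_disc_image(dim = c(60, 60),
                        centers = rbind(c(15, 15), c(15, 45), c(45, 30)),
                        radius = 9)
    nucc <- rbind(c(15 + sample(-4:4, 1), 15 + sample(-4:4, 1)),
                  c(45 + sample(-4:4, 1), 30 + sample(-4:4, 1)))
    nx <- fx_disc_image(dim = c(60, 60), centers = nucc, radius = 3)
    asg <- assign_nuclei(fx$labels, nx$labels)
    for (i in seq_len(nrow(asg))) {
      ov <- fx$labels[nx$labels == asg$nucleus[i]]
      tb <- table(ov[ov > 0])
      if (length(tb) && max(tb) / sum(nx$labels == asg$nucleus[i]) >= 0.5)
        expect_equal(asg$cell[i],
                     as.integer(names(tb)[which.max(tb)]))
    }
  }
})

test_that("border-cell removal equals the direct edge-pixel set", {
  set.seed(23)
  for (rep in 1:20) {
    lab <- matrix(0L, 30, 30)
    for (i in 1:4) {
      r <- sample(1:26, 1); c <- sample(1:26, 1)
      lab[r:(r + 4), c:(c + 4)] <- i
    }
    out <- filter_border_cells(lab)
    edge <- unique(c(lab[1, ], lab[30, ], lab[, 1], lab[, 30]))
    edge <- sort(edge[edge > 0])
    expect_equal(out$excluded, edge)
    expect_true(all(!(out$labels %in% edge) | out$labels == 0))
    expect_true(all(out$labels[!(lab %in% edge)] == lab[!(lab %in% edge)]))
  }
  interior <- matrix(0L, 20, 20); interior[8:12, 8:12] <- 1L
  expect_identical(filter_border_cells(interior)$labels, interior)
})

test_that("tracking keeps one id for static cells and handles splits", {
  lab <- matrix(0L, 20, 20); lab[5:10, 5:10] <- 1L
  tr <- track_cells(replicate(10, lab, simplify = FALSE))
  expect_equal(unique(tr$track), 1L)
  # split at frame 3: parent ends, two children with recorded parent
  lab2 <- matrix(0L, 20, 20); lab2[5:10, 3:6] <- 1L; lab2[5:10, 9:12] <- 2L
  tr2 <- track_cells(list(lab, lab, lab2, lab2))
  ch <- tr2[tr2$frame == 3, ]
  expect_equal(nrow(ch), 2)
  expect_true(all(ch$parent == 1))
  expect_true(all(ch$track != 1))
  expect_equal(tr2$track[tr2$frame == 4], ch$track)
})

test_that("truth-mask tracking of a rendered movie agrees with generator ids", {
  fx <- fx_movie6()
  mv <- fx$movie
  tr <- track_cells(mv$cell_labels)
  # truth labels are constant: every link must stay on one track
  agree <- tapply(tr$track, tr$label, function(x) mean(x == x[1]))
  expect_gte(mean(unlist(agree)), 0.99)
})
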