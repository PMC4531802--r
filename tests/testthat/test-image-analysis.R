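# Helpers to build tiny deterministic images ------------------------------

disk_image <- function(h, w, cx, cy, r, amp = 100) {
  gx <- outer(rep(1, h), seq_len(w) - 1)
  gy <- outer(seq_len(h) - 1, rep(1, w))
  amp * stats::plogis((r - sqrt((gx - cx)^2 + (gy - cy)^2)) / 0.5)
}

add_gauss_spot <- function(img, x, y, amp = 400, sigma = 0.45) {
  gx <- exp(-((seq_len(ncol(img)) - 1) - x)^2 / (2 * sigma^2))
  gy <- exp(-((seq_len(nrow(img)) - 1) - y)^2 / (2 * sigma^2))
  img + amp * outer(gy, gx)
}

test_that("max projection equals the pixelwise maximum", {
  one <- array(runif(64 * 64), dim = c(64, 64, 1))
  expect_equal(max_project(one), one[, , 1])
  two <- array(0, dim = c(8, 8, 2))
  two[, , 2] <- matrix(runif(64), 8)
  expect_equal(max_project(two), two[, , 2])
  st <- array(rnorm(20 * 30 * 3), dim = c(20, 30, 3))
  mp <- max_project(st)
  for (r in seq_len(20)) {
    for (c in seq_len(30)) {
      expect_identical(mp[r, c], max(st[r, c, 1], st[r, c, 2], st[r, c, 3]))
    }
  }
  expect_error(max_project(array(0, dim = c(4, 4, 0))), "plane")
})

test_that("a centered disk segments as one round, admitted nucleus", {
  img <- disk_image(100, 100, 50, 50, 18)
  seg <- segment_nuclei(img)
  expect_equal(nrow(seg$nuclei), 1L)
  n <- seg$nuclei
  expect_false(n$excluded)
  expect_false(n$touches_border)
  expect_gt(n$roundness, 0.9)
  expect_equal(n$x, 50, tolerance = 1)
  expect_equal(n$y, 50, tolerance = 1)
  expect_equal(n$area_px, pi * 18^2, tolerance = 0.15 * pi * 18^2)
})

test_that("nuclei touching the image border are flagged and excluded", {
  img <- disk_image(100, 100, 50, 50, 18) + disk_image(100, 100, 4, 70, 18)
  seg <- segment_nuclei(img)
  expect_equal(nrow(seg$nuclei), 2L)
  border <- seg$nuclei[seg$nuclei$touches_border, ]
  expect_equal(nrow(border), 1L)
  expect_true(border$excluded)
  expect_equal(border$exclude_reason, "touches_border")
  expect_equal(sum(!seg$nuclei$excluded), 1L)
})

test_that("blank or object-free images yield an empty nucleus list", {
  expect_equal(nrow(segment_nuclei(matrix(0, 50, 50))$nuclei), 0L)
})

test_that("morphology filters exclude small and rough objects", {
  img <- disk_image(120, 120, 30, 30, 18) + disk_image(120, 120, 90, 90, 8)
  seg <- segment_nuclei(img)  # default area range starts at 500 px^2
  small <- seg$nuclei[seg$nuclei$area_px < 500, ]
  expect_equal(nrow(small), 1L)
  expect_true(small$excluded)
  expect_equal(small$exclude_reason, "area_out_of_range")
})

test_that("isolated spots are detected at sub-pixel accuracy", {
  nuc <- disk_image(80, 80, 40, 40, 25, amp = 1)  # mask source
  seg <- segment_nuclei(nuc * 100)
  truth <- data.frame(x = c(30.3, 40.0, 48.7), y = c(42.1, 28.6, 47.2))
  ch <- matrix(0, 80, 80)
  for (i in seq_len(nrow(truth))) {
    ch <- add_gauss_spot(ch, truth$x[i], truth$y[i])
  }
  det <- detect_spots(ch, seg$labels, seg$nuclei$nucleus_id[1])
  expect_equal(nrow(det), 3L)
  dm <- sqrt(outer(truth$x, det$x, "-")^2 + outer(truth$y, det$y, "-")^2)
  expect_lt(max(apply(dm, 1, min)), 0.5)
})

test_that("a uniform nucleus yields zero spots", {
  nuc <- disk_image(80, 80, 40, 40, 25)
  seg <- segment_nuclei(nuc)
  det <- detect_spots(matrix(5, 80, 80), seg$labels,
                      seg$nuclei$nucleus_id[1])
  expect_equal(nrow(det), 0L)
})

test_that("adding a spot never removes previously detected spots", {
  nuc <- disk_image(90, 90, 45, 45, 30, amp = 100)
  seg <- segment_nuclei(nuc)
  pts <- data.frame(x = c(33, 52, 45, 58.5, 38.2),
                    y = c(40, 36, 57, 50.5, 52.8))
  ch <- matrix(0, 90, 90)
  prev <- NULL
  for (i in seq_len(nrow(pts))) {
    ch <- add_gauss_spot(ch, pts$x[i], pts$y[i])
    det <- detect_spots(ch, seg$labels, seg$nuclei$nucleus_id[1])
    expect_equal(nrow(det), i)
    if (!is.null(prev)) {
      dm <- sqrt(outer(prev$x, det$x, "-")^2 + outer(prev$y, det$y, "-")^2)
      expect_lt(max(apply(dm, 1, min)), 0.3)
    }
    prev <- det
  }
})

test_that("analyze_field recovers simulated nuclei and spot counts", {
  cm <- cell_model("M2A", p_break = 0.1)
  sim <- simulate_field(cm, 12, seed = 41, noise = "none",
                        imaging = imaging_config(field_shape_px = c(256, 256)))
  res <- analyze_field(sim$field)
  expect_equal(sum(!res$nuclei$excluded), 12L)
  # centroids close to placed nucleus centers
  ce <- sim$truth$cells
  dm <- sqrt(outer(ce$x, res$nuclei$x, "-")^2 +
               outer(ce$y, res$nuclei$y, "-")^2)
  expect_lt(max(apply(dm, 1, min)), 2)
  # per-nucleus spot counts equal ground truth on noise-free input
  acc <- detection_accuracy(sim$truth$spots, res$spots)
  expect_true(all(acc$accuracy == 1))
  expect_equal(sum(acc$n_truth), nrow(res$spots))
})

test_that("every detected spot lies inside its parent nucleus mask", {
  sim <- simulate_field(cell_model("M2A"), 8, seed = 43,
                        imaging = test_imaging(c(192L, 192L)))
  res <- analyze_field(sim$field)
  seg <- segment_nuclei(max_project(sim$field$stacks$DAPI))
  for (i in seq_len(nrow(res$spots))) {
    r <- round(res$spots$y[i]) + 1
    c <- round(res$spots$x[i]) + 1
    expect_equal(seg$labels[r, c], res$spots$nucleus_id[i])
  }
})

test_that("detection is equivariant under integer translation", {
  sim <- simulate_field(cell_model("M2A"), 2, seed = 47,
                        imaging = test_imaging(c(96L, 96L)))
  dy <- 4L; dx <- 7L
  shift <- function(st) {
    out <- array(0, dim = dim(st))
    out[(1 + dy):96, (1 + dx):96, ] <- st[1:(96 - dy), 1:(96 - dx), ]
    out
  }
  shifted <- sim$field
  shifted$stacks <- lapply(sim$field$stacks, shift)
  a <- analyze_field(sim$field)$spots
  b <- analyze_field(shifted)$spots
  expect_equal(nrow(a), nrow(b))
  a <- a[order(a$channel, a$x, a$y), ]
  b <- b[order(b$channel, b$x, b$y), ]
  expect_equal(b$x, a$x + dx, tolerance = 0.1)
  expect_equal(b$y, a$y + dy, tolerance = 0.1)
})

test_that("a field without the required channels is rejected", {
  sim <- simulate_field(cell_model(), 2, seed = 3,
                        imaging = test_imaging(c(96L, 96L)))
  broken <- sim$field
  broken$stacks$Red <- NULL
  expect_error(analyze_field(broken), "Red")
})
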