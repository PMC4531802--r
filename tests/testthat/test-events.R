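test_that("the QC filter admits exactly the documented configurations", {
  expect_true(qc_filter(3, 3, 2)$qc_pass)   # modal intact cell
  expect_true(qc_filter(2, 2, 2)$qc_pass)
  f1 <- qc_filter(3, 2, 2)
  expect_false(f1$qc_pass)
  expect_equal(f1$qc_reason, "unequal_red_green")
  f2 <- qc_filter(2, 2, 1)
  expect_false(f2$qc_pass)
  expect_equal(f2$qc_reason, "farred_lt_2")
  f3 <- qc_filter(1, 2, 2)
  expect_equal(f3$qc_reason, "green_lt_2")
  f4 <- qc_filter(2, 1, 2)
  expect_equal(f4$qc_reason, "red_lt_2")
  v <- qc_filter(c(3, 3), c(3, 2), c(2, 2))
  expect_equal(v$qc_pass, c(TRUE, FALSE))
})

test_that("pairwise distances follow Euclidean geometry and take minima", {
  d <- pairwise_distances(data.frame(x = 0, y = 0),
                          data.frame(x = 3, y = 4),
                          data.frame(x = 0, y = 2))
  expect_equal(d$rg_min, 5)
  expect_equal(d$rfr_min, 2)
  d2 <- pairwise_distances(data.frame(x = 0, y = 0),
                           data.frame(x = c(1, 2), y = c(0, 0)),
                           data.frame(x = c(0, 6), y = c(2, 0)))
  expect_equal(d2$rg_min, 1)
  expect_equal(d2$rfr_min, 2)
  expect_equal(d2$rg_dists[[1]], c(1, 2))
  expect_error(pairwise_distances(data.frame(x = 0, y = 0),
                                  data.frame(x = numeric(0), y = numeric(0)),
                                  data.frame(x = 1, y = 1)),
               "QC")
})

test_that("classification matches the distance-threshold definitions", {
  th <- ba_thresholds(4)
  expect_equal(classify_red_signal(5, 3, th), "translocation")
  expect_equal(classify_red_signal(5, 6, th), "breakage")
  # exactly at the threshold counts as proximal: intact
  expect_equal(classify_red_signal(4.0, 0.5, th), "intact")
  expect_equal(classify_red_signal(4 + 1e-9, 4.0, th), "translocation")
  expect_equal(classify_red_signal(c(1, 10), c(1, 10), th),
               c("intact", "breakage"))
})

test_that("per-Red minima and classes agree with brute force on random nuclei", {
  set.seed(202)
  th <- ba_thresholds(4)
  for (i in 1:200) {
    ns <- random_nucleus_spots(sample(2:5, 1), sample(2:5, 1),
                               sample(2:4, 1))
    got <- pairwise_distances(ns$red, ns$green, ns$farred)
    want <- brute_force_minima(ns$red, ns$green, ns$farred)
    expect_equal(got$rg_min, want$rg_min)
    expect_equal(got$rfr_min, want$rfr_min)
    expect_identical(classify_red_signal(got$rg_min, got$rfr_min, th),
                     brute_force_class(want$rg_min, want$rfr_min, 4))
  }
})

test_that("nucleus summaries respect the event hierarchy", {
  qc_ok <- qc_filter(3, 3, 2)
  rec <- data.frame(red_spot_id = 1:3,
                    rg_min = c(1, 6, 7), rfr_min = c(1, 2, 9))
  rec$event_class <- classify_red_signal(rec$rg_min, rec$rfr_min,
                                         ba_thresholds(4))
  s <- summarize_nucleus(rec, qc_ok)
  expect_equal(s$n_breakage_events, 2L)        # translocation counts too
  expect_equal(s$n_translocation_events, 1L)
  expect_true(s$breakage_positive)
  expect_true(s$translocation_positive)

  rec2 <- rec; rec2$event_class <- "intact"
  s2 <- summarize_nucleus(rec2, qc_ok)
  expect_false(s2$breakage_positive || s2$translocation_positive)

  s3 <- summarize_nucleus(NULL, qc_filter(3, 2, 2))
  expect_false(s3$qc_pass)
  expect_equal(s3$n_breakage_events, 0L)

  bad <- rec; bad$nucleus_id <- c(1, 1, 2)
  expect_error(summarize_nucleus(bad, qc_ok), "one nucleus")
})

test_that("raising the threshold is monotone in both event directions", {
  set.seed(303)
  ns <- lapply(1:50, function(i) random_nucleus_spots(3, 3, 2, span = 12))
  minima <- do.call(rbind, lapply(ns, function(n)
    pairwise_distances(n$red, n$green, n$farred)[, c("rg_min", "rfr_min")]))
  prev_break <- Inf; prev_prox <- -Inf
  for (t in 2:8) {
    cls <- classify_red_signal(minima$rg_min, minima$rfr_min,
                               ba_thresholds(t))
    n_break <- sum(cls != "intact")
    n_prox <- sum(minima$rfr_min <= t)
    expect_lte(n_break, prev_break)
    expect_gte(n_prox, prev_prox)
    prev_break <- n_break; prev_prox <- n_prox
  }
})

test_that("call_events joins tables, applies QC, and converts units", {
  nuclei <- data.frame(field_id = "f1", nucleus_id = 1:3)
  mk <- function(nid, ch, x, y) data.frame(field_id = "f1", nucleus_id = nid,
                                           channel = ch, x = x, y = y)
  spots <- rbind(
    # nucleus 1: one broken allele (rg_min 6 px), FarRed nearby ->
    # translocation
    mk(1, "Green", c(0, 12), c(0, 0)), mk(1, "Red", c(6, 12.1), c(0, 0)),
    mk(1, "FarRed", c(6.5, 20), c(0, 0)),
    # nucleus 2: all intact
    mk(2, "Green", c(30, 40), c(0, 0)), mk(2, "Red", c(30.5, 40.2), c(0, 0)),
    mk(2, "FarRed", c(35, 45), c(0, 0)),
    # nucleus 3: QC failure (unequal counts)
    mk(3, "Green", c(60, 70, 75), c(0, 0, 0)), mk(3, "Red", c(60, 70), c(0, 0)),
    mk(3, "FarRed", c(65, 72), c(0, 0)))
  ev <- call_events(nuclei, spots, ba_thresholds(4))
  expect_equal(nrow(ev$nuclei), 3L)
  n1 <- ev$nuclei[ev$nuclei$nucleus_id == 1, ]
  expect_true(n1$translocation_positive && n1$breakage_positive)
  n2 <- ev$nuclei[ev$nuclei$nucleus_id == 2, ]
  expect_true(n2$qc_pass)
  expect_false(n2$breakage_positive)
  n3 <- ev$nuclei[ev$nuclei$nucleus_id == 3, ]
  expect_false(n3$qc_pass)
  expect_equal(nrow(ev$alleles), 4L)  # two QC-passing nuclei x two reds

  # same coordinates expressed in micrometers give identical calls
  spots_um <- spots
  spots_um$x <- spots_um$x * 0.32
  spots_um$y <- spots_um$y * 0.32
  ev_um <- call_events(nuclei, spots_um, ba_thresholds(4, 0.32),
                       coord_units = "um")
  expect_equal(ev_um$alleles$event_class, ev$alleles$event_class)
  expect_equal(ev_um$alleles$rg_min, ev$alleles$rg_min, tolerance = 1e-12)
})

test_that("excluded nuclei take no part in event calling", {
  nuclei <- data.frame(field_id = "f1", nucleus_id = 1:2,
                       excluded = c(FALSE, TRUE))
  spots <- data.frame(field_id = "f1", nucleus_id = rep(1:2, each = 6),
                      channel = rep(c("Green", "Green", "Red", "Red",
                                      "FarRed", "FarRed"), 2),
                      x = rep(c(0, 10, 0.5, 10.5, 3, 12), 2),
                      y = 0)
  ev <- call_events(nuclei, spots)
  expect_equal(nrow(ev$nuclei), 1L)
  expect_equal(ev$nuclei$nucleus_id, 1L)
})
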