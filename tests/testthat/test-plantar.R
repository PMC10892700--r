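test_that("zero calibration subtracts baseline means and clamps at zero", {
  set.seed(2)
  rec <- random_recording(8, 50)
  # a steady recording equal to the baseline zeroes out completely
  steady <- rec
  steady$pressures[] <- rep(runif(8, 1, 3), each = 50)
  expect_true(all(zero_calibrate(steady, steady)$pressures == 0))

  zero_base <- rec
  zero_base$pressures[] <- 0
  expect_equal(zero_calibrate(rec, zero_base)$pressures, rec$pressures)

  const <- rec; const$pressures[] <- 2
  half <- rec; half$pressures[] <- 0.5
  expect_true(all(zero_calibrate(const, half)$pressures == 1.5))

  other <- random_recording(7, 50)
  expect_error(zero_calibrate(rec, other), "layout")
})

test_that("rear-lateral exclusion is size-dependent and removes the right sensors", {
  layout <- simulate_layout(43)
  n <- nrow(layout)
  rec <- insole_recording(c(0, 0.01), matrix(1, 2, n, dimnames = list(NULL, layout$sensor_id)),
                          layout, session = session("t", "pre", 0.02, 100))
  for (cfg in list(c(39, 3), c(41, 4), c(43, 4), c(45, 5))) {
    ex <- exclude_rear_lateral(rec, cfg[1])
    expect_length(ex$excluded, cfg[2])
  }
  expect_error(exclude_rear_lateral(rec, 42), "unsupported")

  # excluded sensors are the most posterior, ties broken laterally
  ex <- exclude_rear_lateral(rec, 45)
  ord <- order(layout$length_pct, -layout$width_pct)
  expect_setequal(ex$excluded, ord[1:5])

  # excluded sensors contribute nothing: scribbling junk on them does not
  # change any region metric
  set.seed(7)
  rec2 <- random_recording(30, 80)
  rec2$layout$length_pct <- runif(30, 0, 100)
  ex2 <- exclude_rear_lateral(rec2, 45)
  m1 <- region_metrics(ex2)
  junk <- ex2
  junk$pressures[, junk$excluded] <- 0.123
  expect_equal(region_metrics(junk), m1)
})

test_that("region assignment uses the published bounds with upper-closed intervals", {
  layout <- data.frame(sensor_id = paste0("s", 1:8),
                       length_pct = c(15, 30, 30.001, 60, 70, 80, 80.001, 100),
                       width_pct = c(10, 60, 60.001, 100, 50, 50, 50, 50))
  masks <- assign_regions(layout)
  lab <- function(i) names(masks)[1:4][vapply(masks[1:4], function(m) i %in% m, TRUE)]
  expect_identical(lab(1), "rearfoot")
  expect_identical(lab(2), "rearfoot")       # exactly 30% stays rearfoot
  expect_identical(lab(3), "midfoot")
  expect_identical(lab(4), "midfoot")
  expect_identical(lab(5), "metatarsal_heads")
  expect_identical(lab(6), "metatarsal_heads")
  expect_identical(lab(7), "forefoot")
  expect_identical(lab(8), "forefoot")
  wlab <- function(i) names(masks)[5:6][vapply(masks[5:6], function(m) i %in% m, TRUE)]
  expect_identical(wlab(2), "inner_foot")    # exactly 60% width stays inner
  expect_identical(wlab(3), "outer_foot")

  # the longitudinal and width masks each partition the non-excluded sensors
  set.seed(9)
  lay2 <- data.frame(sensor_id = paste0("s", 1:50),
                     length_pct = runif(50, 0, 100), width_pct = runif(50, 0, 100))
  m2 <- assign_regions(lay2, excluded = c(3L, 17L))
  long_members <- unlist(m2[1:4])
  expect_setequal(long_members, setdiff(1:50, c(3L, 17L)))
  expect_identical(anyDuplicated(long_members), 0L)
  width_members <- unlist(m2[5:6])
  expect_setequal(width_members, setdiff(1:50, c(3L, 17L)))
})

test_that("sensor impulse is the pressure-time product, linear and additive", {
  expect_equal(sensor_impulse(rep(2, 300), 0.01), 6)
  expect_equal(sensor_impulse(numeric(10), 0.5), 0)
  expect_equal(sensor_impulse(c(0, 4, 2), 0.01), 0.06)
  set.seed(4)
  x <- runif(500, 0, 10)
  acc <- 0
  for (v in x) acc <- acc + v * 0.02
  expect_equal(sensor_impulse(x, 0.02), acc, tolerance = 1e-12)
  expect_equal(sensor_impulse(3 * x, 0.02), 3 * sensor_impulse(x, 0.02))
  expect_equal(sensor_impulse(x, 0.04), 2 * sensor_impulse(x, 0.02))
  expect_error(sensor_impulse(x, 0), "positive")
})

test_that("region metrics match the naive loop oracle and its invariants", {
  # hand-checked single-sensor region: rearfoot holds only sensor "a" with
  # trace [0, 4, 2] at dt = 0.01; the other regions are anchored by
  # constant-1 sensors
  layout <- data.frame(sensor_id = c("a", "b", "c", "d"),
                       length_pct = c(15, 45, 70, 90), width_pct = c(30, 30, 80, 80))
  p <- cbind(a = c(0, 4, 2), b = 1, c = 1, d = 1)
  rec <- insole_recording((0:2) / 100, p, layout,
                          session = session("t", "pre", 0.03, 100))
  masks <- assign_regions(rec)
  m <- region_metrics(rec, masks)
  rf <- m[m$region == "rearfoot", ]
  expect_equal(rf$peak_pressure, 4)
  expect_equal(rf$impulse, 0.06)
  expect_equal(rf$mean_pressure, 3)             # loaded frames only (4, 2)
  expect_equal(rf$loaded_time_fraction, 2 / 3)

  # all-frames mean denominator as the configurable alternative
  expect_equal(region_metrics(rec, masks, mean_over = "all")[1, "mean_pressure"], 2)

  # uniform constant field: mean == peak == the constant everywhere
  recc <- rec; recc$pressures[] <- 5
  mc <- region_metrics(recc)
  expect_true(all(mc$mean_pressure == 5) && all(mc$peak_pressure == 5))

  set.seed(31)
  for (i in 1:5) {
    r <- random_recording(sample(10:40, 1), sample(30:120, 1))
    mk <- assign_regions(r)
    got <- region_metrics(r, mk)
    want <- oracle_region_metrics(r, mk)
    for (rn in got$region) {
      g <- got[got$region == rn, ]
      w <- want[[rn]]
      expect_equal(unlist(g[c("mean_pressure", "peak_pressure", "impulse",
                              "loaded_time_fraction", "loaded_sensor_pct")]),
                   w, tolerance = 1e-12, ignore_attr = TRUE)
    }
    expect_true(all(got$peak_pressure >= got$mean_pressure))
    expect_true(all(got$impulse >= 0))
  }

  # metrics are invariant to sensor ordering and to the side label
  r <- random_recording(20, 60)
  perm <- sample(20)
  rp <- insole_recording(r$time_s, r$pressures[, perm], r$layout[perm, ],
                         side = "right", session = r$session)
  expect_equal(region_metrics(rp), region_metrics(r))

  # a region without members is an explicit error
  lay_gap <- data.frame(sensor_id = c("a", "b"), length_pct = c(10, 20),
                        width_pct = c(30, 40))
  p2 <- matrix(1, 2, 2, dimnames = list(NULL, c("a", "b")))
  rec_gap <- insole_recording(c(0, 0.01), p2, lay_gap,
                              session = session("t", "pre", 0.02, 100))
  expect_error(region_metrics(rec_gap), "midfoot")
})

test_that("pre/post contrasts are signed post-minus-pre differences", {
  pre <- data.frame(region = c("x", "y"), impulse = c(2, 3), peak_pressure = c(1, 1))
  post <- data.frame(region = c("y", "x"), impulse = c(3.5, 1), peak_pressure = c(1, 1))
  d <- region_contrast(pre, post)
  expect_equal(d$impulse[d$region == "x"], -1)
  expect_equal(d$impulse[d$region == "y"], 0.5)
  expect_equal(d$peak_pressure, c(0, 0))
  expect_equal(region_contrast(pre, pre)$impulse, c(0, 0))
  expect_error(region_contrast(pre, post[1, ]), "region sets")
})
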