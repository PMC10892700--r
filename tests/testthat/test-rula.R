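test_that("hand-evaluated worksheet postures score correctly", {
  # resting posture: every partial 1, no modifiers -> grand 1
  neutral <- neutral_angle_matrix(1L)[1L, ]
  fs <- rula_score_frame(neutral)
  expect_identical(fs$grand, 1L)
  expect_identical(fs$upper_arm, 1L)
  expect_identical(fs$score_a, 1L)
  expect_identical(fs$score_b, 1L)

  # severe posture, hand-walked through the tables:
  # upper arm 100deg -> 4; lower arm 30 -> 2; wrist 20 + deviation 15 -> 4;
  # twist 50 -> 2; table A[4,2,4,2] = 5.  neck 25 + twisted -> 4; trunk 30
  # -> 3; legs unsupported -> 2; table B[4,3,2] = 7.  C[5,7] = 7.
  bad <- neutral
  bad[c("upper_arm_flexion_left", "upper_arm_flexion_right")] <- 100
  bad[c("lower_arm_flexion_left", "lower_arm_flexion_right")] <- 30
  bad[c("wrist_flexion_left", "wrist_flexion_right")] <- 20
  bad[c("wrist_deviation_left", "wrist_deviation_right")] <- 15
  bad[c("wrist_twist_left", "wrist_twist_right")] <- 50
  bad["neck_flexion"] <- 25
  bad["neck_twist"] <- 1
  bad["trunk_flexion"] <- 30
  bad["legs_supported"] <- 0
  fs2 <- rula_score_frame(bad)
  expect_identical(fs2$score_a, 5L)
  expect_identical(fs2$score_b, 7L)
  expect_identical(fs2$grand, 7L)

  # moderate lifting posture: upper arm 60 -> 3, lower arm 80 -> 1,
  # wrist 10 -> 2, twist mid -> 1, A = TableA[3,1,2,1] = 4;
  # neck 15 -> 2, trunk 10 -> 2, legs supported -> 1, B = TableB[2,2,1] = 2;
  # grand = C[4,2] = 3
  mid <- neutral
  mid[c("upper_arm_flexion_left", "upper_arm_flexion_right")] <- 60
  mid[c("wrist_flexion_left", "wrist_flexion_right")] <- 10
  mid["neck_flexion"] <- 15
  mid["trunk_flexion"] <- 10
  fs3 <- rula_score_frame(mid)
  expect_identical(fs3$score_a, 4L)
  expect_identical(fs3$score_b, 2L)
  expect_identical(fs3$grand, 3L)

  # force and muscle modifiers shift A/B before the C lookup:
  # 2-10 kg static adds 2 to both sides
  fs4 <- rula_score_frame(mid, force = force_spec("2-10kg", static = TRUE))
  expect_identical(fs4$score_a, 6L)
  expect_identical(fs4$score_b, 4L)
  expect_identical(fs4$grand, 6L)  # C[6,4]

  expect_error(rula_score_frame(neutral[-1]), "missing channel")
  bad_angle <- neutral
  bad_angle["trunk_flexion"] <- 200
  expect_error(rula_score_frame(bad_angle), "-180")
})

test_that("grand scores stay in 1..7 and never decrease under worsening", {
  tabs <- rula_tables()
  expect_identical(dim(tabs$A), c(6L, 3L, 4L, 2L))
  expect_identical(dim(tabs$B), c(6L, 6L, 2L))
  expect_identical(dim(tabs$C), c(8L, 7L))
  expect_true(all(tabs$C >= 1 & tabs$C <= 7))

  set.seed(101)
  n <- 2000L
  ua <- sample(1:6, n, TRUE); la <- sample(1:3, n, TRUE)
  wr <- sample(1:4, n, TRUE); wt <- sample(1:2, n, TRUE)
  nk <- sample(1:6, n, TRUE); tr <- sample(1:6, n, TRUE)
  lg <- sample(1:2, n, TRUE)
  ma <- sample(0:1, n, TRUE); fa <- sample(0:3, n, TRUE)
  mb <- sample(0:1, n, TRUE); fb <- sample(0:3, n, TRUE)
  g1 <- ergofield:::lookup_grand(ua, la, wr, wt, nk, tr, lg, ma, fa, mb, fb)$grand
  expect_true(all(g1 >= 1 & g1 <= 7))
  # element-wise worsened copy of every partial input
  worsen <- function(x, hi) pmin(x + sample(0:2, n, TRUE), hi)
  g2 <- ergofield:::lookup_grand(worsen(ua, 6L), worsen(la, 3L), worsen(wr, 4L),
                                 worsen(wt, 2L), worsen(nk, 6L), worsen(tr, 6L),
                                 worsen(lg, 2L), ma + sample(0:1, n, TRUE),
                                 fa + sample(0:1, n, TRUE),
                                 mb + sample(0:1, n, TRUE),
                                 fb + sample(0:1, n, TRUE))$grand
  expect_true(all(g2 >= g1))
})

test_that("trailing-window static detection matches a direct oracle", {
  rate <- 10
  n <- 1200L  # 120 s
  const <- rep(30, n)
  flags <- detect_static(const, rate)
  w <- 60 * rate
  expect_false(any(flags[seq_len(w - 1L)]))
  expect_true(all(flags[w:n]))

  t <- (seq_len(n) - 1L) / rate
  sine <- 40 * sin(2 * pi * t / 10)
  expect_false(any(detect_static(sine, rate)))

  # piecewise trace with one 90 s plateau: exactly the plateau tail flagged
  set.seed(3)
  x <- c(40 * sin(2 * pi * (1:300) / 40), rep(12, 900), 40 * sin(2 * pi * (1:300) / 40))
  got <- detect_static(x, rate, window_s = 60, range_thresh_deg = 10)
  expect_identical(got, oracle_static(x, w, 10))
  expect_true(any(got))

  # randomized trace against the oracle at a different window
  y <- cumsum(rnorm(800))
  expect_identical(detect_static(y, 5, window_s = 30, range_thresh_deg = 4),
                   oracle_static(y, 150L, 4))

  # shorter trace than the window: nothing is static
  expect_false(any(detect_static(rep(1, 50), 10)))
})

test_that("series scoring takes the worse body side and reacts to load removal", {
  n <- 60L
  m <- neutral_angle_matrix(n)
  # right arm heavily flexed on odd frames only
  odd <- seq(1L, n, 2L)
  m[odd, "upper_arm_flexion_right"] <- 100
  ser <- joint_angle_series((seq_len(n) - 1L) / 10, m,
                            session = session("t", "pre", n / 10, 10))
  sc <- rula_score_series(ser)
  expect_identical(unique(sc$grand_left), 1L)
  # hand evaluation: UA 4, rest neutral -> A = TableA[4,1,1,1] = 4, B = 1,
  # grand = C[4,1] = 3
  expect_identical(unique(sc$grand[odd]), 3L)
  expect_identical(unique(sc$grand[-odd]), 1L)
  expect_identical(sc$grand, pmax(sc$grand_left, sc$grand_right))

  withload <- rula_score_series(ser, force = force_spec(">10kg", static = TRUE))
  expect_true(all(withload$grand >= sc$grand))
})

test_that("action-level distribution and final score match direct counting", {
  expect_equal(action_level_distribution(rep(1L, 100))$proportions, c(1, 0, 0, 0))
  expect_equal(action_level_distribution(c(rep(3L, 50), rep(7L, 50)))$proportions,
               c(0, 0.5, 0, 0.5))

  set.seed(5)
  g <- sample(1:7, 500, TRUE)
  d <- action_level_distribution(g)
  counts <- c(sum(g <= 2), sum(g %in% 3:4), sum(g %in% 5:6), sum(g == 7))
  expect_equal(d$proportions, counts / 500)
  expect_equal(sum(d$proportions), 1)

  expect_equal(final_rula_score(rep(4L, 10)), 4)
  expect_equal(final_rula_score(c(rep(3L, 5), rep(5L, 5))), 4)
  expect_equal(final_rula_score(g), sum(g) / length(g))
  expect_true(final_rula_score(g) >= min(g) && final_rula_score(g) <= max(g))
  expect_equal(final_rula_score(c(2L, 2L, 7L), method = "mode"), 2)
  expect_equal(final_rula_score(g, method = "p90"), as.numeric(quantile(g, 0.9, type = 1)))
  expect_error(action_level_distribution(integer()), "empty")
})
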