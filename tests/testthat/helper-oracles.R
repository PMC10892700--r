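# Fixture builders and independent brute-force oracles shared by the tests.

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# frame x channel matrix of a resting posture (grand RULA score 1 by hand
# evaluation of the worksheet: all partials 1, no modifiers)
neutral_angle_matrix <- function(n = 1L) {
  m <- matrix(0, n, length(required_angle_channels()),
              dimnames = list(NULL, required_angle_channels()))
  m[, c("lower_arm_flexion_left", "lower_arm_flexion_right")] <- 80
  m[, "neck_flexion"] <- 5
  m[, "legs_supported"] <- 1
  m
}

neutral_series <- function(n = 10L, rate = 10) {
  joint_angle_series((seq_len(n) - 1L) / rate, neutral_angle_matrix(n),
                     session = session("t", "pre", n / rate, rate))
}

# random layout + recording; pressures uniform in [0, 8] N/cm^2. The first
# four sensors anchor every region so none is empty (n_sensors >= 4).
random_recording <- function(n_sensors, n_frames, rate = 100, side = "left") {
  stopifnot(n_sensors >= 4L)
  layout <- data.frame(sensor_id = sprintf("s%03d", seq_len(n_sensors)),
                       length_pct = c(15, 45, 70, 90, runif(n_sensors - 4L, 0, 100)),
                       width_pct = c(30, 30, 80, 80, runif(n_sensors - 4L, 0, 100)))
  p <- matrix(runif(n_frames * n_sensors, 0, 8), n_frames,
              dimnames = list(NULL, layout$sensor_id))
  insole_recording((seq_len(n_frames) - 1L) / rate, p, layout, side = side,
                   session = session("t", "pre", n_frames / rate, rate))
}

# naive per-sensor loop implementation of the region metric definitions
oracle_region_metrics <- function(recording, masks, load_thresh = 0.6,
                                  persistence = 0.01) {
  p <- recording$pressures
  dt <- 1 / recording$session$sample_rate_hz
  out <- list()
  for (rn in names(masks)) {
    idx <- masks[[rn]]
    means <- peaks <- imps <- ltfs <- numeric(length(idx))
    loaded_ct <- 0L
    for (j in seq_along(idx)) {
      tr <- p[, idx[j]]
      loaded <- tr >= load_thresh
      means[j] <- if (any(loaded)) mean(tr[loaded]) else 0
      peaks[j] <- max(tr)
      s <- 0
      for (v in tr) s <- s + v * dt
      imps[j] <- s
      ltfs[j] <- sum(loaded) / length(tr)
      if (ltfs[j] >= persistence) loaded_ct <- loaded_ct + 1L
    }
    out[[rn]] <- c(mean_pressure = mean(means), peak_pressure = mean(peaks),
                   impulse = mean(imps), loaded_time_fraction = mean(ltfs),
                   loaded_sensor_pct = 100 * loaded_ct / length(idx))
  }
  out
}

# brute-force cell-means SS decomposition for a two-way within design
oracle_two_way_ss <- function(arr) {
  n <- dim(arr)[1L]; a <- dim(arr)[2L]; b <- dim(arr)[3L]
  gm <- mean(arr)
  ss <- list(total = 0, subj = 0, A = 0, B = 0, AB = 0, AS = 0, BS = 0)
  m_s <- apply(arr, 1, mean); m_a <- apply(arr, 2, mean); m_b <- apply(arr, 3, mean)
  m_ab <- apply(arr, c(2, 3), mean); m_sa <- apply(arr, c(1, 2), mean)
  m_sb <- apply(arr, c(1, 3), mean)
  for (i in 1:n) for (j in 1:a) for (k in 1:b) {
    ss$total <- ss$total + (arr[i, j, k] - gm)^2
  }
  for (i in 1:n) ss$subj <- ss$subj + a * b * (m_s[i] - gm)^2
  for (j in 1:a) ss$A <- ss$A + n * b * (m_a[j] - gm)^2
  for (k in 1:b) ss$B <- ss$B + n * a * (m_b[k] - gm)^2
  for (j in 1:a) for (k in 1:b)
    ss$AB <- ss$AB + n * (m_ab[j, k] - m_a[j] - m_b[k] + gm)^2
  for (i in 1:n) for (j in 1:a)
    ss$AS <- ss$AS + b * (m_sa[i, j] - m_s[i] - m_a[j] + gm)^2
  for (i in 1:n) for (k in 1:b)
    ss$BS <- ss$BS + a * (m_sb[i, k] - m_s[i] - m_b[k] + gm)^2
  ss$ABS <- ss$total - ss$subj - ss$A - ss$B - ss$AB - ss$AS - ss$BS
  ss
}

# direct O(n*w) sliding-window range oracle for static detection
oracle_static <- function(x, w, thresh) {
  n <- length(x)
  out <- rep(FALSE, n)
  if (w > n) return(out)
  for (i in w:n) {
    win <- x[(i - w + 1L):i]
    out[i] <- (max(win) - min(win)) < thresh
  }
  out
}

long_two_level <- function(n, labels = c("pre", "post"), mu = 0, d = 0.5) {
  y1 <- rnorm(n, mu)
  y2 <- rnorm(n, mu + d)
  data.frame(subject = rep(seq_len(n), 2L),
             phase = rep(labels, each = n), value = c(y1, y2))
}
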