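test_that("the normality screen behaves under null, degenerate and bimodal input", {
  # under the null (normal draws, n = 24) the screen passes in >= 90% of seeds
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    shapiro_screen(rnorm(24))$normal
  }, TRUE)
  expect_gte(mean(ok), 0.9)

  expect_error(shapiro_screen(c(1, 2)), "n >= 3")

  const <- shapiro_screen(rep(1.5, 24))
  expect_false(const$computable)
  expect_true(is.na(const$W) && is.na(const$p))

  bimodal <- shapiro_screen(rep(c(0, 10), 12))
  expect_lt(bimodal$p, 0.05)
  expect_false(bimodal$normal)
})

test_that("two-level rmANOVA equals the squared paired t test with epsilon 1", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    d <- long_two_level(n, d = runif(1, -1, 1))
    res <- rm_anova(d, within = "phase")
    tt <- t.test(d$value[d$phase == "post"], d$value[d$phase == "pre"], paired = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p_gg, tt$p.value, tolerance = 1e-10)
    expect_identical(res$epsilon_gg, 1)
    expect_equal(res$p_uncorrected, res$p_gg)
    # partial eta^2 from reported F and dfs matches the SS-based value
    expect_equal(res$partial_eta_sq,
                 res$F * res$df_num / (res$F * res$df_num + res$df_den),
                 tolerance = 1e-10)
  }

  # identical conditions: F = 0, p = 1
  d0 <- data.frame(subject = rep(1:6, 2), phase = rep(c("a", "b"), each = 6),
                   value = rep(rnorm(6), 2))
  res0 <- rm_anova(d0, within = "phase")
  expect_equal(res0$F, 0)
  expect_equal(res0$p_gg, 1)

  # incomplete designs are refused, not imputed
  expect_error(rm_anova(d0[-1, ], within = "phase"), "balanced")
  expect_error(rm_anova(data.frame(subject = 1, phase = c("a", "b"), value = 1:2),
                        within = "phase"), "2 subjects")
})

test_that("two-factor SS decomposition matches the brute-force oracle", {
  set.seed(33)
  for (i in 1:5) {
    n <- sample(5:9, 1); a <- 2L; b <- sample(2:4, 1)
    arr <- array(rnorm(n * a * b, sd = 2), dim = c(n, a, b))
    long <- expand.grid(subject = 1:n, f1 = paste0("a", 1:a), f2 = paste0("b", 1:b))
    long$value <- arr[cbind(long$subject, as.integer(long$f1), as.integer(long$f2))]
    res <- rm_anova(long, within = c("f1", "f2"))
    want <- oracle_two_way_ss(arr)

    expect_equal(res$ss_effect[res$effect == "f1"], want$A, tolerance = 1e-10)
    expect_equal(res$ss_effect[res$effect == "f2"], want$B, tolerance = 1e-10)
    expect_equal(res$ss_effect[res$effect == "f1:f2"], want$AB, tolerance = 1e-10)
    expect_equal(res$ss_error[res$effect == "f1"], want$AS, tolerance = 1e-10)
    expect_equal(res$ss_error[res$effect == "f2"], want$BS, tolerance = 1e-10)
    expect_equal(res$ss_error[res$effect == "f1:f2"], want$ABS, tolerance = 1e-8)

    # conservation: SS_total = subjects + all effects + all errors
    expect_equal(attr(res, "ss_total"),
                 attr(res, "ss_subjects") + sum(res$ss_effect) + sum(res$ss_error),
                 tolerance = 1e-8)

    # epsilon bounds: (1/(k-1), 1] for the k-level factor, exactly 1 at k = 2
    eps_b <- res$epsilon_gg[res$effect == "f2"]
    expect_true(eps_b > 1 / (b - 1) - 1e-12 && eps_b <= 1 + 1e-12)
    expect_identical(res$epsilon_gg[res$effect == "f1"], 1)
    expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
    expect_true(res$informational[res$effect == "f1:f2"])
  }
})

test_that("Bonferroni post hocs adjust the CI level and the p value", {
  set.seed(41)
  d <- long_two_level(12, d = 0.8)
  # single pair: identical to the unadjusted paired t CI
  ph <- bonferroni_posthoc(d, within = "phase", pairs = list(c("pre", "post")))
  tt <- t.test(d$value[d$phase == "post"] - d$value[d$phase == "pre"])
  expect_equal(ph$mean_diff, unname(tt$estimate))
  expect_equal(c(ph$ci_low, ph$ci_high), as.numeric(tt$conf.int))
  expect_equal(ph$p_adj, tt$p.value)
  expect_true(ph$ci_low <= ph$mean_diff && ph$mean_diff <= ph$ci_high)

  # identical conditions: zero difference, CI spans 0
  d0 <- data.frame(subject = rep(1:6, 2), phase = rep(c("a", "b"), each = 6),
                   value = rep(rnorm(6), 2))
  ph0 <- bonferroni_posthoc(d0, within = "phase")
  expect_equal(ph0$mean_diff, 0)
  expect_true(ph0$ci_low <= 0 && ph0$ci_high >= 0)

  # three pairs: p_adj = min(1, 3p) and wider (1 - alpha/3) CIs
  d3 <- data.frame(subject = rep(1:10, 3), cond = rep(c("a", "b", "c"), each = 10),
                   value = rnorm(30))
  ph3 <- bonferroni_posthoc(d3, within = "cond")
  expect_identical(nrow(ph3), 3L)
  expect_equal(ph3$p_adj, pmin(1, 3 * ph3$p))
  expect_equal(unique(ph3$conf_level), 1 - 0.05 / 3)

  expect_error(bonferroni_posthoc(d, within = "phase", pairs = list()), "empty")
})

test_that("partial eta squared labels follow Cohen's inclusive bins", {
  expect_identical(effect_size_label(0.55), "large")
  expect_identical(effect_size_label(0.005), "negligible")
  expect_identical(effect_size_label(0.06), "medium")
  expect_identical(effect_size_label(0.01), "small")
  expect_identical(effect_size_label(0.14), "large")
  expect_identical(effect_size_label(c(0.02, 0.13)), c("small", "medium"))
  expect_error(effect_size_label(1.2), "0, 1")
})
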