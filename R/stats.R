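# Inferential layer: Shapiro-Wilk screening, one- and two-factor fully
# within-subject repeated-measures ANOVA with Greenhouse-Geisser correction
# and partial eta squared, and Bonferroni-adjusted paired post hoc contrasts
# with confidence intervals.
#
# The ANOVA uses the classical balanced within-subject sums-of-squares
# decomposition; each effect is tested against its own effect-by-subject
# interaction. The Greenhouse-Geisser epsilon is estimated from the sample
# covariance of orthonormally contrasted condition scores, so it is exactly 1
# for two-level factors and the correction is then a no-op.

#' Shapiro-Wilk normality screen
#'
#' @param x Numeric vector (e.g. per-subject pre/post differences), `n >= 3`.
#' @param alpha Significance level for the normality verdict.
#' @return List `W`, `p`, `normal` (`p > alpha`), `computable`. A constant
#'   vector is reported as non-computable (`W`, `p`, `normal` all `NA`)
#'   rather than an error.
#' @export
shapiro_screen <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop_ergo("Shapiro-Wilk screen needs n >= 3 values, got %d", length(x))
  res <- tryCatch(stats::shapiro.test(x), error = function(e) NULL)
  if (is.null(res))
    return(list(W = NA_real_, p = NA_real_, normal = NA, computable = FALSE))
  list(W = unname(res$statistic), p = res$p.value,
       normal = res$p.value > alpha, computable = TRUE)
}

# orthonormal contrast matrix (k x (k-1)); contr.poly columns are orthonormal
ortho_contrasts <- function(k) {
  if (k < 2L) stop_ergo("factor needs at least 2 levels")
  stats::contr.poly(k)
}

# GG epsilon from the covariance matrix of contrasted scores D (n x df)
gg_epsilon <- function(D) {
  df <- ncol(D)
  if (df == 1L) return(1)
  S <- stats::cov(D)
  tr <- sum(diag(S))
  (tr * tr) / (df * sum(S * S))
}

#' Repeated-measures ANOVA (within-subject factors only)
#'
#' Fits a one- or two-factor fully within-subject ANOVA on a complete,
#' balanced long table (every subject observed exactly once in every cell; no
#' imputation). For each effect the F statistic, Greenhouse-Geisser epsilon,
#' the epsilon-corrected p value and partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`) are reported. For a two-level
#' factor epsilon is exactly 1 and F equals the squared paired-t statistic.
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric outcome column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector of one or two within-factor column names.
#' @return Data frame of class `rm_anova` with one row per effect
#'   (interaction included for two factors, flagged informational) and
#'   columns `effect, df_num, df_den, ss_effect, ss_error, F, epsilon_gg,
#'   p_uncorrected, p_gg, partial_eta_sq`. The full SS decomposition
#'   (`ss_subjects`, `ss_total`) is attached as attributes.
#' @export
rm_anova <- function(data, dv = "value", subject = "subject", within) {
  data <- as.data.frame(data)
  cols <- c(dv, subject, within)
  missing <- setdiff(cols, names(data))
  if (length(missing)) stop_ergo("missing column(s): %s", paste(missing, collapse = ", "))
  if (length(within) < 1L || length(within) > 2L)
    stop_ergo("within must name 1 or 2 factors")
  y <- data[[dv]]
  if (any(!is.finite(y))) stop_ergo("non-finite values in '%s'", dv)
  subj <- factor(data[[subject]])
  n <- nlevels(subj)
  if (n < 2L) stop_ergo("need at least 2 subjects")
  f1 <- factor(data[[within[1L]]])
  f2 <- if (length(within) == 2L) factor(data[[within[2L]]]) else factor(rep("(1)", nrow(data)))
  a <- nlevels(f1); b <- nlevels(f2)
  counts <- table(subj, f1, f2)
  if (any(counts != 1L))
    stop_ergo("design is not complete/balanced: every subject must appear exactly once per cell")

  # subject x cell array, cells ordered with factor 1 slowest
  arr <- array(NA_real_, dim = c(n, a, b))
  arr[cbind(as.integer(subj), as.integer(f1), as.integer(f2))] <- y
  gm <- mean(arr)
  m_s <- apply(arr, 1L, mean)
  m_a <- apply(arr, 2L, mean)
  m_b <- apply(arr, 3L, mean)
  m_ab <- apply(arr, c(2L, 3L), mean)
  m_sa <- apply(arr, c(1L, 2L), mean)
  m_sb <- apply(arr, c(1L, 3L), mean)

  ss_total <- sum((arr - gm)^2)
  ss_subj <- a * b * sum((m_s - gm)^2)
  ss_a <- n * b * sum((m_a - gm)^2)
  ss_as <- b * sum(sweep(sweep(m_sa, 2L, m_a, "-"), 1L, m_s - gm, "-")^2)

  Ca <- ortho_contrasts(a)
  Ya <- matrix(m_sa, n, a) %*% Ca                    # n x (a-1) contrasted scores
  effects <- list(list(name = within[1L], ss = ss_a, ss_err = ss_as,
                       df1 = a - 1L, df2 = (a - 1L) * (n - 1L),
                       eps = gg_epsilon(Ya), informational = FALSE))

  if (b > 1L) {
    ss_b <- n * a * sum((m_b - gm)^2)
    ss_bs <- a * sum(sweep(sweep(m_sb, 2L, m_b, "-"), 1L, m_s - gm, "-")^2)
    ss_ab <- n * sum((sweep(sweep(m_ab, 1L, m_a, "-"), 2L, m_b, "-") + gm)^2)
    ss_abs <- ss_total - ss_subj - ss_a - ss_as - ss_b - ss_bs - ss_ab
    Cb <- ortho_contrasts(b)
    Yb <- matrix(m_sb, n, b) %*% Cb
    # columns of matrix(arr, n, a*b) vary factor 1 fastest, factor 2 slowest;
    # kronecker(Cb, Ca) rows follow the same ordering
    Yw <- matrix(arr, n, a * b)
    Tab <- kronecker(Cb, Ca)
    Yab <- Yw %*% Tab
    effects <- c(effects,
      list(list(name = within[2L], ss = ss_b, ss_err = ss_bs,
                df1 = b - 1L, df2 = (b - 1L) * (n - 1L),
                eps = gg_epsilon(Yb), informational = FALSE),
           list(name = paste(within, collapse = ":"), ss = ss_ab, ss_err = ss_abs,
                df1 = (a - 1L) * (b - 1L), df2 = (a - 1L) * (b - 1L) * (n - 1L),
                eps = gg_epsilon(Yab), informational = TRUE)))
  }

  rows <- lapply(effects, function(e) {
    if (e$ss <= .Machine$double.eps * abs(ss_total + 1)) {
      Fv <- 0; p <- 1; p_gg <- 1; pes <- 0
    } else if (e$ss_err <= 0) {
      Fv <- Inf; p <- 0; p_gg <- 0; pes <- 1
    } else {
      Fv <- (e$ss / e$df1) / (e$ss_err / e$df2)
      p <- stats::pf(Fv, e$df1, e$df2, lower.tail = FALSE)
      p_gg <- stats::pf(Fv, e$df1 * e$eps, e$df2 * e$eps, lower.tail = FALSE)
      pes <- e$ss / (e$ss + e$ss_err)
    }
    data.frame(effect = e$name, df_num = e$df1, df_den = e$df2,
               ss_effect = e$ss, ss_error = e$ss_err, F = Fv,
               epsilon_gg = e$eps, p_uncorrected = p, p_gg = p_gg,
               partial_eta_sq = pes, informational = e$informational)
  })
  out <- do.call(rbind, rows)
  attr(out, "ss_subjects") <- ss_subj
  attr(out, "ss_total") <- ss_total
  attr(out, "n_subjects") <- n
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Bonferroni-adjusted paired post hoc contrasts
#'
#' For each requested pair of factor levels, the paired mean difference
#' (second minus first level), a confidence interval at the adjusted level
#' `1 - alpha/m` (m = number of pairs) and the Bonferroni-adjusted p value
#' (`min(1, m * p)`) from a two-sided paired t test.
#'
#' @inheritParams rm_anova
#' @param within Single within-factor column name.
#' @param pairs List of length-2 character vectors of level names; default
#'   all pairwise combinations.
#' @param alpha Family-wise error level.
#' @return Data frame with columns `pair, level_1, level_2, mean_diff,
#'   ci_low, ci_high, p, p_adj, conf_level`.
#' @export
bonferroni_posthoc <- function(data, dv = "value", subject = "subject",
                               within, pairs = NULL, alpha = 0.05) {
  data <- as.data.frame(data)
  stopifnot(length(within) == 1L)
  f <- factor(data[[within]])
  subj <- factor(data[[subject]])
  if (is.null(pairs)) {
    cmb <- utils::combn(levels(f), 2L, simplify = FALSE)
    pairs <- cmb
  }
  if (!length(pairs)) stop_ergo("empty pair list")
  m <- length(pairs)
  conf <- 1 - alpha / m
  rows <- lapply(pairs, function(pr) {
    if (length(pr) != 2L || !all(pr %in% levels(f)))
      stop_ergo("invalid pair: %s", paste(pr, collapse = " vs "))
    y1 <- data[[dv]][f == pr[1L]][order(subj[f == pr[1L]])]
    y2 <- data[[dv]][f == pr[2L]][order(subj[f == pr[2L]])]
    if (length(y1) != length(y2)) stop_ergo("unbalanced pair %s", paste(pr, collapse = " vs "))
    d <- y2 - y1
    if (stats::sd(d) == 0) {
      md <- mean(d)
      ci <- c(md, md)
      p <- if (abs(md) < .Machine$double.eps) 1 else 0
    } else {
      tt <- stats::t.test(d, conf.level = conf)
      md <- mean(d); ci <- as.numeric(tt$conf.int); p <- tt$p.value
    }
    data.frame(pair = paste(pr[2L], "-", pr[1L]), level_1 = pr[1L], level_2 = pr[2L],
               mean_diff = md, ci_low = ci[1L], ci_high = ci[2L],
               p = p, p_adj = min(1, p * m), conf_level = conf)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("posthoc_contrasts", "data.frame")
  out
}

#' Cohen's effect-size label for partial eta squared
#'
#' Conventional bins: small from 0.01, medium from 0.06, large from 0.14
#' (boundaries inclusive at the lower edge); values below 0.01 are labelled
#' negligible.
#'
#' @param partial_eta_sq Value(s) in `[0, 1]`.
#' @return Character vector of labels.
#' @export
effect_size_label <- function(partial_eta_sq) {
  if (any(partial_eta_sq < 0 | partial_eta_sq > 1, na.rm = TRUE))
    stop_ergo("partial eta squared must lie in [0, 1]")
  ifelse(partial_eta_sq >= 0.14, "large",
  ifelse(partial_eta_sq >= 0.06, "medium",
  ifelse(partial_eta_sq >= 0.01, "small", "negligible")))
}
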