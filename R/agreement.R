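#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation between paired measurements with the standard
#' Fisher z-transform interval: z = atanh(r), SE = 1/sqrt(n - 3). At |r| = 1
#' the interval degenerates to the point estimate.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @param alpha two-sided type-I level (default 0.05 for a 95 percent CI).
#' @return A tibble: `r`, `conf_low`, `conf_high`, `n`.
#' @export
pearson_ci <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12) {
    lo <- hi <- r
  } else {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - alpha / 2)
    lo <- tanh(z - q * se)
    hi <- tanh(z + q * se)
  }
  tibble::tibble(r = r, conf_low = lo, conf_high = hi, n = n)
}

#' Absolute-agreement intraclass correlation (two-way random, single rater)
#'
#' ICC(A,1) in the McGraw-Wong taxonomy: two-way random effects, single
#' measurement, absolute agreement -- the form that, unlike Pearson r,
#' penalizes a systematic offset between the two measurement methods. The
#' point estimate comes from the two-way ANOVA mean squares and the
#' confidence interval from the McGraw-Wong F construction.
#'
#' @param x,y numeric vectors of equal length >= 3 (the two methods/raters).
#' @param alpha two-sided type-I level (default 0.05).
#' @return A tibble: `icc`, `conf_low`, `conf_high`, `n`.
#' @export
icc_agreement <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  k <- 2
  dat <- cbind(x, y)
  if (stats::var(as.vector(dat)) == 0) stop("zero total variance")
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  grand <- mean(dat)
  MSR <- k * sum((row_means - grand)^2) / (n - 1)
  MSC <- n * sum((col_means - grand)^2) / (k - 1)
  SSE <- sum((dat - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)

  # McGraw & Wong CI for ICC(A,1)
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  if (!is.finite(a) || !is.finite(b) || MSE == 0) {
    lo <- hi <- icc
  } else {
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  }
  tibble::tibble(icc = icc, conf_low = lo, conf_high = hi, n = n)
}

#' Bland-Altman bias and 95 percent limits of agreement
#'
#' Differences are taken as `mr - cta` (the second method subtracted from the
#' first argument), so a negative bias means MR reads lower than CTA. Limits
#' of agreement are bias +/- 1.96 SD of the differences (n-1 SD).
#'
#' @param mr,cta numeric vectors of equal length >= 2.
#' @return A tibble: `bias`, `loa_lower`, `loa_upper`, `sd_diff`, `n`.
#' @export
bland_altman <- function(mr, cta) {
  if (length(mr) != length(cta)) stop("`mr` and `cta` must have the same length")
  if (length(mr) < 2) stop("need at least 2 pairs")
  d <- mr - cta
  bias <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(bias = bias,
                 loa_lower = bias - 1.96 * s,
                 loa_upper = bias + 1.96 * s,
                 sd_diff = s, n = length(d))
}

#' Weighted Cohen's kappa for paired ordinal scores
#'
#' Chance-corrected inter-rater agreement on a fixed 1..`n_cat` ordinal scale
#' with distance weights. With linear weights the disagreement weight between
#' categories i and j is |i - j|/(n_cat - 1); quadratic weights square that.
#' kappa = 1 - sum(w O) / sum(w E), with the observed proportion table O and
#' the chance table E from the marginals. The confidence interval uses the
#' standard large-sample variance (Fleiss, Cohen and Everitt).
#'
#' @param r1,r2 integer vectors of scores in 1..`n_cat`, equal length >= 2.
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @param n_cat number of scale categories (default 5).
#' @param alpha two-sided type-I level (default 0.05).
#' @return A tibble: `kappa`, `conf_low`, `conf_high`, `se`, `n`.
#' @export
weighted_kappa <- function(r1, r2, weights = c("linear", "quadratic"),
                           n_cat = 5L, alpha = 0.05) {
  weights <- match.arg(weights)
  if (length(r1) != length(r2)) stop("score vectors must have the same length")
  n <- length(r1)
  if (n < 2) stop("need at least 2 paired scores")
  if (any(!(r1 %in% seq_len(n_cat))) || any(!(r2 %in% seq_len(n_cat)))) {
    stop("scores must be integers in 1..", n_cat)
  }
  O <- table(factor(r1, levels = seq_len(n_cat)),
             factor(r2, levels = seq_len(n_cat))) / n
  O <- as.matrix(O)
  p1 <- rowSums(O)
  p2 <- colSums(O)
  E <- outer(p1, p2)
  d <- abs(outer(seq_len(n_cat), seq_len(n_cat), "-")) / (n_cat - 1)
  w <- if (weights == "linear") d else d^2   # disagreement weights
  kappa <- 1 - sum(w * O) / sum(w * E)

  # large-sample variance in terms of agreement weights v = 1 - w
  v <- 1 - w
  po <- sum(v * O)
  pe <- sum(v * E)
  vi <- as.vector(v %*% p2)    # row-wise expected agreement weight
  vj <- as.vector(p1 %*% v)    # column-wise
  term <- outer(vi, vj, "+")
  var_k <- (sum(O * (v - term * (1 - kappa))^2) -
              (kappa - pe * (1 - kappa))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  q <- stats::qnorm(1 - alpha / 2)
  tibble::tibble(kappa = kappa,
                 conf_low = kappa - q * se,
                 conf_high = kappa + q * se,
                 se = se, n = n)
}

#' Interpret a correlation / agreement coefficient
#'
#' Maps a coefficient in [-1, 1] to the conventional qualitative scale:
#' below 0.40 poor, 0.40 to below 0.60 fair, 0.60 to below 0.75 good,
#' 0.75 and above excellent (half-open intervals, so every value receives
#' exactly one label).
#'
#' @param v numeric vector of finite coefficients.
#' @return Character vector of labels.
#' @examples
#' interpret_coefficient(c(0.39, 0.67, 0.80))
#' @export
interpret_coefficient <- function(v) {
  if (any(!is.finite(v))) stop("coefficient must be finite")
  cut(v, breaks = c(-Inf, 0.40, 0.60, 0.75, Inf),
      labels = c("poor", "fair", "good", "excellent"),
      right = FALSE) |> as.character()
}

#' Full agreement report for one set of paired volumes
#'
#' Computes every agreement quantity used for paired MR/CTA calcification
#' volumes: Pearson r with Fisher-z CI, absolute-agreement ICC with CI,
#' the MR-on-CTA regression line, Bland-Altman bias and limits of agreement
#' (MR minus CTA), and the qualitative interpretation of r and ICC.
#'
#' @param mr,cta numeric vectors of per-segment volumes in mm cubed.
#' @return An object of class `agreement_report` (list with the inputs and a
#'   one-row tibble of estimates); supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
agreement_report <- function(mr, cta) {
  pc <- pearson_ci(cta, mr)
  ic <- icc_agreement(cta, mr)
  ba <- bland_altman(mr, cta)
  fit <- stats::lm(mr ~ cta)
  est <- tibble::tibble(
    n = pc$n,
    r = pc$r, r_low = pc$conf_low, r_high = pc$conf_high,
    r_label = interpret_coefficient(pc$r),
    icc = ic$icc, icc_low = ic$conf_low, icc_high = ic$conf_high,
    icc_label = interpret_coefficient(ic$icc),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    bias = ba$bias, loa_lower = ba$loa_lower, loa_upper = ba$loa_upper)
  structure(list(mr = mr, cta = cta, estimates = est),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("<agreement_report>  n = %d segments\n", e$n))
  cat(sprintf("  Pearson r = %.3f (95%% CI %.3f-%.3f, %s)\n",
              e$r, e$r_low, e$r_high, e$r_label))
  cat(sprintf("  ICC(A,1)  = %.3f (95%% CI %.3f-%.3f, %s)\n",
              e$icc, e$icc_low, e$icc_high, e$icc_label))
  cat(sprintf("  MR = %.3f x CTA + %.2f\n", e$slope, e$intercept))
  cat(sprintf("  Bland-Altman bias %.1f mm^3, 95%% LoA [%.1f, %.1f] mm^3\n",
              e$bias, e$loa_lower, e$loa_upper))
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) {
  e <- x$estimates
  tibble::tibble(
    term = c("pearson_r", "icc", "slope", "intercept", "bias",
             "loa_lower", "loa_upper"),
    estimate = c(e$r, e$icc, e$slope, e$intercept, e$bias,
                 e$loa_lower, e$loa_upper),
    conf_low = c(e$r_low, e$icc_low, NA, NA, NA, NA, NA),
    conf_high = c(e$r_high, e$icc_high, NA, NA, NA, NA, NA),
    label = c(e$r_label, e$icc_label, NA, NA, NA, NA, NA))
}

#' @export
glance.agreement_report <- function(x, ...) x$estimates

#' @export
autoplot.agreement_report <- function(object, type = c("scatter", "bland_altman"),
                                      ...) {
  type <- match.arg(type)
  e <- object$estimates
  df <- tibble::tibble(cta = object$cta, mr = object$mr,
                       mean_v = (object$cta + object$mr) / 2,
                       diff_v = object$mr - object$cta)
  if (type == "scatter") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$cta, y = .data$mr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey50") +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                           colour = "black", linewidth = 0.5) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(
        x = expression(CTA~volume~(mm^3)), y = expression(MR~volume~(mm^3)),
        subtitle = sprintf("r = %.2f, ICC = %.2f, MR = %.2f CTA %+.1f",
                           e$r, e$icc, e$slope, e$intercept)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_v, y = .data$diff_v)) +
      ggplot2::geom_hline(yintercept = e$bias, colour = "steelblue") +
      ggplot2::geom_hline(yintercept = c(e$loa_lower, e$loa_upper),
                          linetype = "dashed", colour = "steelblue") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = expression(Mean~of~MR~and~CTA~(mm^3)),
                    y = expression(MR - CTA~(mm^3)),
                    subtitle = sprintf("bias %.1f, LoA [%.1f, %.1f]",
                                       e$bias, e$loa_lower, e$loa_upper)) +
      ggplot2::theme_minimal()
  }
}

#' Stratified agreement analysis of paired volumes
#'
#' Computes the pooled [agreement_report()] plus one report per stratum
#' (e.g. magnetic field strength or CTA severity group). Strata with fewer
#' than 3 pairs are reported with their n only.
#'
#' @param pairs tibble with columns `mr_mm3`, `cta_mm3` and the stratum
#'   column, e.g. from [paired_volumes()].
#' @param by name of the stratum column (string), or NULL for pooled only.
#' @return A tibble with one row per stratum plus `"pooled"`, carrying all
#'   [agreement_report()] estimate columns.
#' @export
stratified_agreement <- function(pairs, by = NULL) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("mr_mm3", "cta_mm3") %in% names(pairs)))
  report_row <- function(df, stratum) {
    if (nrow(df) < 3 || stats::sd(df$cta_mm3) == 0 || stats::sd(df$mr_mm3) == 0) {
      return(tibble::tibble(stratum = stratum, n = nrow(df)))
    }
    dplyr::bind_cols(tibble::tibble(stratum = stratum),
                     glance(agreement_report(df$mr_mm3, df$cta_mm3)))
  }
  out <- list(report_row(pairs, "pooled"))
  if (!is.null(by)) {
    if (!by %in% names(pairs)) stop("unknown stratum column: ", by)
    strata <- split(pairs, pairs[[by]])
    out <- c(out, purrr::imap(strata, report_row))
  }
  dplyr::bind_rows(out)
}
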