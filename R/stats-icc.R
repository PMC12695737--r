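#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC for
#' observer-reproducibility analysis, computed from the two-way ANOVA mean
#' squares:
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' with MSR the between-subject, MSC the between-rater and MSE the residual
#' mean square over n subjects and k raters (or occasions). The confidence
#' interval follows McGraw & Wong's F-based construction.
#'
#' @param measurements numeric matrix, subjects in rows, raters/occasions in
#'   columns; no missing cells.
#' @param level confidence level (default 0.95).
#' @return object of class `icc_result`: list with `estimate`, `ci`,
#'   `icc_type`, `n_subjects`, `n_raters`, `degenerate` (TRUE when the
#'   between-subject variance is zero).
#' @export
icc_agreement <- function(measurements, level = 0.95) {
  m <- as.matrix(measurements)
  if (anyNA(m)) stop("no missing cells allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 5) stop("need >= 5 subjects")
  if (k < 2) stop("need >= 2 raters/occasions")
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - gm)^2)            # between subjects
  ssc <- n * sum((col_m - gm)^2)            # between raters
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + gm)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  degenerate <- msr <= .Machine$double.eps * max(1, abs(gm))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  est <- if (denom == 0) NA_real_ else (msr - mse) / denom
  # McGraw & Wong (1996) CI for ICC(A,1)
  ci <- c(NA_real_, NA_real_)
  if (!degenerate && mse > 0) {
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    alpha <- 1 - level
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    ci[1] <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci[2] <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  } else if (!degenerate && mse == 0) {
    ci <- c(est, est)                       # perfect agreement, no noise
  }
  structure(list(estimate = est, ci = ci,
                 icc_type = "ICC(2,1): two-way random, absolute agreement, single measure",
                 n_subjects = n, n_raters = k, degenerate = degenerate),
            class = "icc_result")
}
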