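# Validation statistics for paired migration series: Bland-Altman mean
# difference and limits of agreement with 95% confidence intervals,
# two-way random-effects intraclass correlation with its F-based CI, and a
# Shapiro-Wilk normality check of the paired differences.

#' Paired measurement series
#'
#' Two measurements (methods or observers) of the same migration parameter on
#' the same subjects.
#'
#' @param labels subject identifiers.
#' @param series_a,series_b numeric vectors of equal length (mm or degrees).
#' @param parameter_name name of the migration parameter.
#' @return An object of class `paired_measurements`.
#' @export
paired_measurements <- function(series_a, series_b,
                                labels = seq_along(series_a),
                                parameter_name = "value") {
  if (length(series_a) != length(series_b) ||
      length(labels) != length(series_a))
    stop("series and labels must have equal length")
  if (length(series_a) < 3) stop("at least 3 paired measurements are required")
  if (anyNA(series_a) || anyNA(series_b))
    stop("missing values are not allowed after pairing")
  structure(list(labels = labels, series_a = as.numeric(series_a),
                 series_b = as.numeric(series_b),
                 parameter_name = parameter_name),
            class = "paired_measurements")
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences are `a - b`. Limits of agreement are the mean difference
#' plus/minus exactly 1.96 times the sample SD (n-1 denominator). The 95% CI
#' half-width of the mean difference uses the t distribution with n-1 df
#' (`t * sd / sqrt(n)`); the CI half-width of each limit of agreement uses
#' the standard `t * sd * sqrt(3/n)` approximation. The Shapiro-Wilk test of
#' the differences is included to support the normality assumption behind
#' the limits.
#'
#' @param data a [paired_measurements()] object.
#' @return An object of class `bland_altman_report`: list(`n`, `mean_diff`,
#'   `sd_diff`, `loa_lower`, `loa_upper`, `ci_mean_halfwidth`,
#'   `ci_loa_halfwidth`, `shapiro_w`, `shapiro_p`, `parameter_name`).
#' @export
bland_altman <- function(data) {
  stopifnot(inherits(data, "paired_measurements"))
  d <- data$series_a - data$series_b
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  tq <- qt(0.975, n - 1)
  if (s == 0) {
    warning("zero variance of differences: limits of agreement are degenerate")
    sw <- c(w = NA_real_, p = NA_real_)
  } else {
    sw <- shapiro_wilk(d)
  }
  structure(list(n = n, mean_diff = m, sd_diff = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 ci_mean_halfwidth = tq * s / sqrt(n),
                 ci_loa_halfwidth = tq * s * sqrt(3 / n),
                 shapiro_w = unname(sw[1]), shapiro_p = unname(sw[2]),
                 parameter_name = data$parameter_name),
            class = "bland_altman_report")
}

#' @export
print.bland_altman_report <- function(x, ...) {
  cat(sprintf("<bland_altman_report> %s, n = %d\n", x$parameter_name, x$n))
  cat(sprintf("  mean difference %.3f (95%% CI half-width %.3f)\n",
              x$mean_diff, x$ci_mean_halfwidth))
  cat(sprintf("  LOA [%.3f, %.3f] (CI half-width %.3f)\n",
              x$loa_lower, x$loa_upper, x$ci_loa_halfwidth))
  cat(sprintf("  Shapiro-Wilk W = %.4f, p = %.4f\n", x$shapiro_w, x$shapiro_p))
  invisible(x)
}

#' Shapiro-Wilk normality test (Royston's approximation)
#'
#' W statistic from the normal-scores coefficients with Royston's polynomial
#' corrections, and the p-value from his normalizing transformations
#' (3 <= n <= 5000).
#'
#' @param x numeric sample.
#' @return named numeric: `w`, `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 3 || n > 5000) stop("sample size must be in [3, 5000]")
  if (x[n] - x[1] == 0) stop("all observations are identical")

  m <- qnorm((1:n - 3 / 8) / (n + 1 / 4))
  ssm <- sum(m^2)
  a <- m / sqrt(ssm)
  u <- 1 / sqrt(n)
  if (n > 5) {
    an <- -2.706056 * u^5 + 4.434685 * u^4 - 2.071190 * u^3 -
      0.147981 * u^2 + 0.221157 * u + a[n]
    an1 <- -3.582633 * u^5 + 5.682633 * u^4 - 1.752461 * u^3 -
      0.293762 * u^2 + 0.042981 * u + a[n - 1]
    phi <- (ssm - 2 * m[n]^2 - 2 * m[n - 1]^2) / (1 - 2 * an^2 - 2 * an1^2)
    a <- m / sqrt(phi)
    a[n] <- an; a[1] <- -an
    a[n - 1] <- an1; a[2] <- -an1
  } else if (n > 3) {
    an <- -2.706056 * u^5 + 4.434685 * u^4 - 2.071190 * u^3 -
      0.147981 * u^2 + 0.221157 * u + a[n]
    phi <- (ssm - 2 * m[n]^2) / (1 - 2 * an^2)
    a <- m / sqrt(phi)
    a[n] <- an; a[1] <- -an
  }
  w <- sum(a * x)^2 / sum((x - mean(x))^2)
  w <- min(w, 1)

  if (n == 3) {
    p <- 6 / pi * (asin(sqrt(w)) - asin(sqrt(0.75)))
    p <- max(min(p, 1), 0)
  } else if (n <= 11) {
    g <- -2.273 + 0.459 * n
    mu <- 0.5440 - 0.39978 * n + 0.025054 * n^2 - 0.0006714 * n^3
    sig <- exp(1.3822 - 0.77857 * n + 0.062767 * n^2 - 0.0020322 * n^3)
    z <- (-log(g - log1p(-w)) - mu) / sig
    p <- pnorm(z, lower.tail = FALSE)
  } else {
    ln <- log(n)
    mu <- -1.5861 - 0.31082 * ln - 0.083751 * ln^2 + 0.0038915 * ln^3
    sig <- exp(-0.4803 - 0.082676 * ln + 0.0030302 * ln^2)
    z <- (log1p(-w) - mu) / sig
    p <- pnorm(z, lower.tail = FALSE)
  }
  c(w = w, p = p)
}

#' Intraclass correlation for two-rater agreement
#'
#' Single-measurement ICC from the two-way ANOVA mean squares. The default
#' `"ICC2"` is the two-way random-effects, absolute-agreement form -- the
#' form that answers whether two observers produce the same values, not
#' merely correlated ones. `"ICC3"` (two-way mixed, consistency) is exposed
#' for sensitivity analysis. 95% CIs follow the F-based method of McGraw and
#' Wong.
#'
#' @param data a [paired_measurements()] object (2 raters).
#' @param type `"ICC2"` or `"ICC3"`.
#' @param conf confidence level.
#' @return An object of class `icc_report`: list(`icc`, `ci_lower`,
#'   `ci_upper`, `model`, `n_subjects`, `n_raters`).
#' @export
icc <- function(data, type = c("ICC2", "ICC3"), conf = 0.95) {
  stopifnot(inherits(data, "paired_measurements"))
  type <- match.arg(type)
  Y <- cbind(data$series_a, data$series_b)
  n <- nrow(Y)
  k <- ncol(Y)
  grand <- mean(Y)
  row_m <- rowMeans(Y)
  col_m <- colMeans(Y)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((Y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (ssr <= .Machine$double.eps * sst || sst == 0)
    stop("zero between-subject variance: ICC is undefined")
  alpha <- 1 - conf
  if (type == "ICC2") {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    df2 <- (n - 1) * (k - 1)
    f_l <- f_obs / qf(1 - alpha / 2, n - 1, df2)
    f_u <- f_obs * qf(1 - alpha / 2, df2, n - 1)
    lower <- (f_l - 1) / (f_l + k - 1)
    upper <- (f_u - 1) / (f_u + k - 1)
  }
  # perfect agreement (MSE = 0) degenerates the F-based CI; pin it at the
  # estimate rather than returning NaN
  lower <- if (is.finite(lower)) min(lower, est) else est
  upper <- if (is.finite(upper)) max(upper, est) else est
  structure(list(icc = est, ci_lower = lower,
                 ci_upper = upper,
                 model = if (type == "ICC2")
                   "two-way random, absolute agreement, single measure"
                 else "two-way mixed, consistency, single measure",
                 n_subjects = n, n_raters = k),
            class = "icc_report")
}

#' @export
print.icc_report <- function(x, ...) {
  cat(sprintf("<icc_report> ICC = %.4f (95%% CI %.4f to %.4f)\n  %s; n = %d subjects, %d raters\n",
              x$icc, x$ci_lower, x$ci_upper, x$model, x$n_subjects,
              x$n_raters))
  invisible(x)
}

#' Full agreement analysis over all migration parameters
#'
#' Runs [bland_altman()] and [icc()] per migration parameter (MTPM, TT, TR,
#' Tx, Ty, Tz, Rx, Ry, Rz) on two per-subject result tables, and returns a
#' summary table (per-method mean and SD, ICC with CI, Bland-Altman fields)
#' plus per-parameter plot data (per-subject means and differences with the
#' mean/LOA/CI line positions).
#'
#' @param results_a,results_b data.frames with a `subject` column and one
#'   column per migration parameter (as from
#'   `as.data.frame(migration_result)` rows plus a subject label).
#' @param parameters parameters to analyse.
#' @return list(`summary` data.frame, `plot_data` named list of data.frames,
#'   `lines` named list).
#' @export
agreement_suite <- function(results_a, results_b,
                            parameters = c("MTPM", "TT", "TR", "Tx", "Ty",
                                           "Tz", "Rx", "Ry", "Rz")) {
  if (!"subject" %in% names(results_a) || !"subject" %in% names(results_b))
    stop("both result tables need a 'subject' column")
  only_a <- setdiff(results_a$subject, results_b$subject)
  only_b <- setdiff(results_b$subject, results_a$subject)
  if (length(only_a) || length(only_b))
    stop("unpaired subjects: ",
         paste(c(if (length(only_a)) paste0("only in A: ",
                                            paste(only_a, collapse = ", ")),
                 if (length(only_b)) paste0("only in B: ",
                                            paste(only_b, collapse = ", "))),
               collapse = "; "))
  results_b <- results_b[match(results_a$subject, results_b$subject), ,
                         drop = FALSE]
  rows <- list()
  plot_data <- list()
  lines <- list()
  for (par in parameters) {
    pm <- paired_measurements(results_a[[par]], results_b[[par]],
                              labels = results_a$subject,
                              parameter_name = par)
    ba <- bland_altman(pm)
    ic <- icc(pm)
    rows[[par]] <- data.frame(
      parameter = par, n = ba$n,
      mean_a = mean(pm$series_a), sd_a = sd(pm$series_a),
      mean_b = mean(pm$series_b), sd_b = sd(pm$series_b),
      icc = ic$icc, icc_ci_lower = ic$ci_lower, icc_ci_upper = ic$ci_upper,
      mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
      loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
      ci_mean_halfwidth = ba$ci_mean_halfwidth,
      ci_loa_halfwidth = ba$ci_loa_halfwidth,
      shapiro_w = ba$shapiro_w, shapiro_p = ba$shapiro_p)
    plot_data[[par]] <- data.frame(
      subject = results_a$subject,
      mean = (pm$series_a + pm$series_b) / 2,
      diff = pm$series_a - pm$series_b)
    lines[[par]] <- list(mean = ba$mean_diff,
                         loa = c(ba$loa_lower, ba$loa_upper),
                         ci_mean = ba$mean_diff +
                           c(-1, 1) * ba$ci_mean_halfwidth,
                         ci_loa_lower = ba$loa_lower +
                           c(-1, 1) * ba$ci_loa_halfwidth,
                         ci_loa_upper = ba$loa_upper +
                           c(-1, 1) * ba$ci_loa_halfwidth)
  }
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       plot_data = plot_data, lines = lines)
}
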