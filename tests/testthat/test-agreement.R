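test_that("Bland-Altman fields match longhand formulas exactly", {
  set.seed(51)
  a <- rnorm(24, 0.5, 0.4)
  b <- rnorm(24, 0.6, 0.5)
  ba <- bland_altman(paired_measurements(a, b, parameter_name = "MTPM"))
  d <- a - b
  m <- sum(d) / 24
  s <- sqrt(sum((d - m)^2) / 23)
  expect_equal(ba$mean_diff, m, tolerance = 1e-12)
  expect_equal(ba$sd_diff, s, tolerance = 1e-12)
  expect_equal(ba$loa_upper - ba$loa_lower, 2 * 1.96 * s, tolerance = 1e-12)
  expect_equal(ba$ci_mean_halfwidth, qt(0.975, 23) * s / sqrt(24),
               tolerance = 1e-12)
  expect_equal(ba$ci_loa_halfwidth, qt(0.975, 23) * s * sqrt(3 / 24),
               tolerance = 1e-12)
  expect_true(ba$loa_lower <= ba$mean_diff && ba$mean_diff <= ba$loa_upper)
})

test_that("Bland-Altman is translation-equivariant and handles degeneracy", {
  set.seed(52)
  a <- rnorm(15)
  b <- rnorm(15)
  ba0 <- bland_altman(paired_measurements(a, b))
  ba1 <- bland_altman(paired_measurements(a + 0.7, b))
  expect_equal(ba1$mean_diff, ba0$mean_diff + 0.7, tolerance = 1e-12)
  expect_equal(ba1$sd_diff, ba0$sd_diff, tolerance = 1e-12)
  # identical series: degenerate limits with a warning, not an error
  expect_warning(ba_eq <- bland_altman(paired_measurements(a, a)),
                 "zero variance")
  expect_equal(ba_eq$mean_diff, 0)
  expect_equal(c(ba_eq$loa_lower, ba_eq$loa_upper), c(0, 0))
  expect_error(paired_measurements(1:2, 1:2), "at least 3")
  expect_error(paired_measurements(c(1, NA, 3), c(1, 2, 3)), "missing")
})

test_that("ICC(2,1) matches a brute-force sum-of-squares oracle", {
  set.seed(53)
  for (rep in 1:5) {
    n <- sample(8:30, 1)
    subj <- rnorm(n, 0, 1)
    a <- subj + rnorm(n, 0, 0.3)
    b <- subj + 0.1 + rnorm(n, 0, 0.3)
    res <- icc(paired_measurements(a, b))
    # oracle: explicit two-way ANOVA sums of squares, element by element
    Y <- cbind(a, b); k <- 2
    grand <- mean(Y)
    ssr <- ssc <- sse <- 0
    for (i in 1:n) for (j in 1:k) {
      ri <- mean(Y[i, ]); cj <- mean(Y[, j])
      ssr <- ssr + (ri - grand)^2
      ssc <- ssc + (cj - grand)^2
      sse <- sse + (Y[i, j] - ri - cj + grand)^2
    }
    msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
    icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    expect_equal(res$icc, as.numeric(icc_oracle), tolerance = 1e-10)
    expect_true(res$ci_lower <= res$icc && res$icc <= res$ci_upper)
  }
})

test_that("ICC edge cases: duplicated series, invariances, degenerate input", {
  set.seed(54)
  a <- rnorm(12, 2, 1)
  dup <- icc(paired_measurements(a, a))
  expect_equal(dup$icc, 1, tolerance = 1e-12)
  # invariant to common shift and positive rescaling
  b <- a + rnorm(12, 0, 0.4)
  base <- icc(paired_measurements(a, b))
  shifted <- icc(paired_measurements(a + 5, b + 5))
  scaled <- icc(paired_measurements(3 * a, 3 * b))
  expect_equal(shifted$icc, base$icc, tolerance = 1e-12)
  expect_equal(scaled$icc, base$icc, tolerance = 1e-12)
  # no between-subject variance: undefined
  expect_error(icc(paired_measurements(rep(1, 5), rep(2, 5))),
               "between-subject")
})

test_that("ICC approaches the population value of the generative model", {
  # b = a + independent noise with variance ratio 9:1 -> population ICC 0.9
  set.seed(55)
  n <- 4000
  subj <- rnorm(n, 0, 3)
  a <- subj + rnorm(n, 0, 1)
  b <- subj + rnorm(n, 0, 1)
  res <- icc(paired_measurements(a, b))
  expect_equal(res$icc, 0.9, tolerance = 0.02)
})

test_that("Shapiro-Wilk matches the reference implementation to 1e-6", {
  set.seed(56)
  for (i in 1:20) {
    n <- sample(c(5, 8, 12, 24, 50, 200), 1)
    x <- rnorm(n) + sample(c(0, 2), 1) * rexp(n)
    ours <- shapiro_wilk(x)
    ref <- stats::shapiro.test(x)
    expect_equal(unname(ours["w"]), unname(ref$statistic), tolerance = 1e-6)
    expect_equal(unname(ours["p"]), ref$p.value, tolerance = 1e-4)
  }
  # near-perfect normal scores: W close to 1
  z <- qnorm(((1:40) - 3 / 8) / (40 + 1 / 4))
  expect_gt(shapiro_wilk(z)["w"], 0.99)
  expect_error(shapiro_wilk(rep(1, 10)), "identical")
  expect_error(shapiro_wilk(1:2), "sample size")
})

test_that("Shapiro-Wilk rejects a strongly bimodal alternative", {
  set.seed(57)
  rejections <- 0
  for (i in 1:50) {
    x <- c(rnorm(25, -3, 0.5), rnorm(25, 3, 0.5))
    if (shapiro_wilk(x)["p"] < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections, 45)  # high power under this alternative
})

test_that("the agreement suite produces the full per-parameter table", {
  set.seed(58)
  pars <- c("MTPM", "TT", "TR", "Tx", "Ty", "Tz", "Rx", "Ry", "Rz")
  mk <- function(shift) {
    df <- data.frame(subject = sprintf("P%02d", 1:24))
    for (p in pars) df[[p]] <- rnorm(24, 0.3, 0.5) + shift
    df
  }
  a <- mk(0)
  b <- a
  for (p in pars) b[[p]] <- b[[p]] + rnorm(24, 0.02, 0.1)
  out <- agreement_suite(a, b)
  expect_equal(nrow(out$summary), 9)
  expect_setequal(out$summary$parameter, pars)
  expect_true(all(c("mean_a", "sd_a", "mean_b", "sd_b", "icc",
                    "icc_ci_lower", "icc_ci_upper", "mean_diff",
                    "loa_lower", "loa_upper") %in% names(out$summary)))
  # plot data consistent with the report fields
  for (p in pars) {
    row <- out$summary[out$summary$parameter == p, ]
    expect_equal(mean(out$plot_data[[p]]$diff), row$mean_diff,
                 tolerance = 1e-12)
    expect_equal(out$lines[[p]]$loa, c(row$loa_lower, row$loa_upper),
                 tolerance = 1e-12)
  }
  # self-comparison: mean differences 0, ICC 1 (degenerate variance warns)
  self <- suppressWarnings(agreement_suite(a, a))
  expect_true(all(self$summary$mean_diff == 0))
  expect_true(all(self$summary$icc == 1))
  # unpaired subjects are named in the error
  b2 <- b[-3, ]
  expect_error(agreement_suite(a, b2), "P03")
})
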