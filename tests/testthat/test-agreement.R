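test_that("identity-line deviation is the relative vertical offset", {
  expect_equal(deviation_percent(100, 100), 0)
  expect_equal(deviation_percent(100, 108), 8)
  expect_equal(deviation_percent(200, 170), -15)
  expect_error(deviation_percent(0, 10), "zero reference")
  expect_equal(deviation_percent(100, 110, mode = "average"),
               100 * 10 / 105)
})

test_that("band percentages recompute exactly from the counts", {
  dev <- deviations_with_counts(97, 24, 5)
  br <- band_report(dev, group = rep("mandible", 126))
  expect_equal(br$n, 126)
  expect_equal(round(br$pct_within_10, 1), 77.0)
  expect_equal(round(br$pct_10_15, 1), 19.0)
  expect_equal(round(br$pct_15_20, 1), 4.0)

  # all-zero deviations: everything in the innermost band
  br0 <- band_report(rep(0, 10))
  expect_equal(br0$pct_within_10, 100)

  # band boundaries closed at the outer edge
  edge <- band_report(c(10, 15, 20, 20.0001))
  expect_equal(c(edge$n_within_10, edge$n_10_15, edge$n_15_20,
                 edge$n_over_20), c(1, 1, 1, 1))

  # counts always partition the sample
  set.seed(33)
  for (rep in 1:20) {
    d <- runif(sample(5:50, 1), -40, 40)
    b <- band_report(d)
    expect_equal(b$n_within_10 + b$n_10_15 + b$n_15_20 + b$n_over_20, b$n)
    expect_equal(b$pct_within_10 + b$pct_10_15 + b$pct_15_20 + b$pct_over_20,
                 100, tolerance = 1e-9)
  }
  expect_error(band_report(numeric()), "no deviations")
})

test_that("the normality gate behaves as specified", {
  set.seed(41)
  expect_true(shapiro_wilk(rnorm(50))$passes)
  set.seed(42)
  sw <- shapiro_wilk(rexp(500))
  expect_lt(sw$p_value, 0.001)
  expect_false(sw$passes)
  expect_error(shapiro_wilk(rep(1, 10)), "degenerate")
  expect_error(shapiro_wilk(1:2), "3 <= n")
})

test_that("percent difference is antisymmetric and guards its domain", {
  expect_equal(percent_difference(100, 100), 0)
  expect_equal(percent_difference(110, 90), 20)
  expect_equal(percent_difference(90, 110), -20)
  expect_error(percent_difference(10, -10), "non-positive")
})

test_that("Bland-Altman quantities follow their closed forms", {
  ba0 <- bland_altman(rep(0, 5))
  expect_equal(c(ba0$bias, ba0$sd, ba0$loa_low, ba0$loa_high), c(0, 0, 0, 0))

  d <- c(20, -20, 5, -5)
  ba <- bland_altman(d)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, sqrt(850 / 3), tolerance = 1e-12)  # n-1 denominator
  expect_equal(ba$gap, 1.96 * ba$sd, tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * sqrt(850 / 3), tolerance = 1e-9)
  expect_equal(ba$loa_high - ba$loa_low, 2 * ba$gap, tolerance = 1e-12)
  expect_equal(ba$ci_bias_halfwidth,
               stats::qt(0.975, 3) * ba$sd / 2, tolerance = 1e-12)
  expect_equal(ba$ci_loa_fullwidth, 2 * 1.96 * ba$sd * sqrt(3 / 4),
               tolerance = 1e-12)
  expect_error(bland_altman(c(1, 2)), "at least 3")
})

test_that("the AL confidence width shrinks as 1/sqrt(n)", {
  set.seed(55)
  base <- rnorm(10)
  for (n in c(10, 100, 10000)) {
    d <- scale(rnorm(n))[, 1] * 10    # sd exactly 10
    ba <- bland_altman(d)
    expect_equal(ba$ci_loa_fullwidth, 2 * 1.96 * 10 * sqrt(3 / n),
                 tolerance = 1e-9)
  }
})

test_that("counts outside the limits match direct comparison", {
  set.seed(77)
  d <- rnorm(1000)
  ba <- bland_altman(d)
  cnt <- count_outside(d, ba)
  # ~5% outside bias +/- 1.96 s, within 99% binomial bounds
  p0 <- 2 * stats::pnorm(-1.96)
  bounds <- stats::qbinom(c(0.005, 0.995), 1000, p0)
  expect_gte(cnt[["n_outside_loa"]], bounds[1])
  expect_lte(cnt[["n_outside_loa"]], bounds[2])
  expect_lte(cnt[["n_outside_outer_ci"]], cnt[["n_outside_loa"]])

  # a spike at bias + 3s is outside both intervals
  d2 <- c(scale(rnorm(200))[, 1] * 5, 5 * 3)
  ba2 <- bland_altman(d2)
  expect_gte(count_outside(5 * 3, ba2)[["n_outside_loa"]], 1)
  expect_gte(count_outside(5 * 3, ba2)[["n_outside_outer_ci"]], 1)
  expect_equal(unname(count_outside(rep(1, 5), bland_altman(rep(1, 5)))),
               c(0, 0))
})

test_that("group analyses merge consistently", {
  set.seed(91)
  pairs <- data.frame(
    label = sprintf("p%02d", 1:30),
    group = rep(c("mandible", "maxilla"), c(18, 12)),
    mean_mdct = runif(30, 400, 1600))
  pairs$mean_decbct <- pairs$mean_mdct * (1 + rnorm(30, 0.05, 0.03))
  rep_all <- agreement_report(pairs)
  expect_setequal(names(rep_all$groups), c("mandible", "maxilla", "combined"))

  d <- percent_difference(pairs)
  # combined row equals bland_altman on the concatenated diffs exactly
  ba_direct <- bland_altman(d)
  expect_equal(rep_all$groups$combined$ba$bias, ba_direct$bias)
  expect_equal(rep_all$groups$combined$ba$sd, ba_direct$sd)
  # combined bias is the size-weighted mean of the group biases
  w_mean <- (18 * rep_all$groups$mandible$ba$bias +
             12 * rep_all$groups$maxilla$ba$bias) / 30
  expect_equal(rep_all$groups$combined$ba$bias, w_mean, tolerance = 1e-9)
  # band counts in the report partition each group
  expect_equal(rep_all$bands$n, c(18, 12, 30))

  # swapping the modalities negates the bias, keeps the SD
  swapped <- pairs
  swapped$mean_mdct <- pairs$mean_decbct
  swapped$mean_decbct <- pairs$mean_mdct
  rep_sw <- agreement_report(swapped)
  expect_equal(rep_sw$groups$combined$ba$bias,
               -rep_all$groups$combined$ba$bias, tolerance = 1e-9)
  expect_equal(rep_sw$groups$combined$ba$sd, rep_all$groups$combined$ba$sd,
               tolerance = 1e-9)

  # non-positive averages are excluded and recorded
  pairs$mean_mdct[1] <- -pairs$mean_decbct[1] - 10
  rep_ex <- agreement_report(pairs)
  expect_equal(nrow(rep_ex$excluded), 1)
  expect_equal(rep_ex$groups$combined$ba$n, 29)
})

test_that("W and p match an independent reference implementation", {
  py <- Sys.which("python")
  expect_true(nzchar(py), label = "python interpreter available")
  script <- 'import sys, json
from scipy import stats
vals = json.load(sys.stdin)
out = [dict(zip(("W", "p"), map(float, stats.shapiro(v)))) for v in vals]
print(json.dumps(out))'
  set.seed(123)
  samples <- lapply(1:20, function(i) {
    n <- sample(10:200, 1)
    if (i %% 2) rnorm(n) else rexp(n)
  })
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  res <- system2(py, sf, input = jsonlite::toJSON(samples, digits = NA),
                 stdout = TRUE)
  ref <- jsonlite::fromJSON(paste(res, collapse = ""))
  for (i in seq_along(samples)) {
    got <- shapiro_wilk(samples[[i]])
    expect_equal(got$W, ref$W[i], tolerance = 1e-6)
    expect_equal(got$p_value, ref$p[i], tolerance = 1e-6)
  }
})
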