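# Cross-modality agreement statistics: identity-line deviation bands,
# Shapiro-Wilk normality gate, and Bland-Altman percent-difference analysis
# with confidence intervals of the limits of agreement.

as_pair_columns <- function(mean_mdct, mean_decbct) {
  if (is.data.frame(mean_mdct)) {
    df <- mean_mdct
    if (!all(c("mean_mdct", "mean_decbct") %in% names(df)))
      stop("pairs need `mean_mdct` and `mean_decbct` columns")
    list(mdct = df$mean_mdct, decbct = df$mean_decbct)
  } else list(mdct = as.numeric(mean_mdct), decbct = as.numeric(mean_decbct))
}

#' Percent deviation from the identity line
#'
#' Vertical offset of a scatter point from the identity line, relative to
#' the MDCT (x-axis) value: `100 * (mean_decbct - mean_mdct) / mean_mdct`.
#' With `mode = "average"` the deviation is taken relative to the pair mean
#' instead.
#'
#' @param mean_mdct MDCT ROI means (or a `measurement_pairs` data.frame).
#' @param mean_decbct DE-CBCT ROI means (ignored when a data.frame is given).
#' @param mode reference value: `"identity_x"` (default) or `"average"`.
#' @return numeric percent deviations.
#' @export
deviation_percent <- function(mean_mdct, mean_decbct = NULL,
                              mode = c("identity_x", "average")) {
  mode <- match.arg(mode)
  p <- as_pair_columns(mean_mdct, mean_decbct)
  ref <- if (mode == "identity_x") p$mdct else (p$mdct + p$decbct) / 2
  if (any(ref == 0)) stop("zero reference mean: deviation undefined")
  100 * (p$decbct - p$mdct) / ref
}

#' Identity-line deviation-band report
#'
#' Counts and percentages of paired ROIs in the bands |dev| <= 10,
#' 10 < |dev| <= 15, 15 < |dev| <= 20 and |dev| > 20 percent, per group and
#' combined. Bands are closed at their outer edge (|dev| = 15 falls in the
#' 10-15 band). Percentages are kept at full precision; the print method
#' applies one-decimal display rounding.
#'
#' @param deviations numeric percent deviations (see [deviation_percent()]),
#'   or a `measurement_pairs` data.frame (deviations computed from it).
#' @param group optional group label per observation; a `group` column is
#'   used when a data.frame is given.
#' @return data.frame of class `band_report`: one row per group plus
#'   `"combined"`, columns `group`, `n`, `n_within_10`, `n_10_15`,
#'   `n_15_20`, `n_over_20` and the matching `pct_*` columns.
#' @export
band_report <- function(deviations, group = NULL) {
  if (is.data.frame(deviations)) {
    if (is.null(group)) group <- deviations$group
    deviations <- deviation_percent(deviations)
  }
  if (length(deviations) == 0L) stop("no deviations to report")
  if (is.null(group)) group <- rep("all", length(deviations))
  one <- function(g, d) {
    a <- abs(d)
    n <- c(sum(a <= 10), sum(a > 10 & a <= 15), sum(a > 15 & a <= 20),
           sum(a > 20))
    data.frame(group = g, n = length(d),
               n_within_10 = n[1], n_10_15 = n[2], n_15_20 = n[3],
               n_over_20 = n[4],
               pct_within_10 = 100 * n[1] / length(d),
               pct_10_15 = 100 * n[2] / length(d),
               pct_15_20 = 100 * n[3] / length(d),
               pct_over_20 = 100 * n[4] / length(d),
               stringsAsFactors = FALSE)
  }
  groups <- unique(group)
  rows <- lapply(groups, function(g) one(g, deviations[group == g]))
  if (length(groups) > 1L)
    rows <- c(rows, list(one("combined", deviations)))
  out <- do.call(rbind, rows)
  class(out) <- c("band_report", "data.frame")
  out
}

#' @export
print.band_report <- function(x, ...) {
  cat("Identity-line deviation bands (percent of paired ROIs)\n")
  disp <- data.frame(group = x$group, n = x$n,
                     `<=10%` = sprintf("%d (%.1f%%)", x$n_within_10, x$pct_within_10),
                     `10-15%` = sprintf("%d (%.1f%%)", x$n_10_15, x$pct_10_15),
                     `15-20%` = sprintf("%d (%.1f%%)", x$n_15_20, x$pct_15_20),
                     `>20%` = sprintf("%d (%.1f%%)", x$n_over_20, x$pct_over_20),
                     check.names = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' The normality gate applied to each group of percent differences before
#' Bland-Altman analysis; the gate passes when p > 0.01.
#'
#' @param values numeric sample, 3 <= n <= 5000, non-constant.
#' @param alpha gate significance level (default 0.01).
#' @return list: `W`, `p_value`, `n`, `passes` (p > alpha).
#' @export
shapiro_wilk <- function(values, alpha = 0.01) {
  values <- as.numeric(values)
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("degenerate input: all values identical")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value, n = length(values),
       passes = sw$p.value > alpha)
}

#' Percent difference of a measurement pair
#'
#' Bland-Altman difference axis: `100 * (mean_mdct - mean_decbct) / average`,
#' the difference as a percentage of the pair average. Pairs with a
#' non-positive average are invalid (errors; the report layer records them
#' as excluded).
#'
#' @inheritParams deviation_percent
#' @return numeric percent differences.
#' @export
percent_difference <- function(mean_mdct, mean_decbct = NULL) {
  p <- as_pair_columns(mean_mdct, mean_decbct)
  avg <- (p$mdct + p$decbct) / 2
  if (any(avg <= 0))
    stop("excluded pair(s): non-positive pair average at index ",
         paste(which(avg <= 0), collapse = ", "))
  100 * (p$mdct - p$decbct) / avg
}

#' Bland-Altman analysis of percent differences
#'
#' Bias is the mean difference; the limits of agreement (AL) are
#' `bias -/+ z * s` with `s` the sample SD and `z = 1.96` (covering ~95% of
#' differences under normality). The bias CI half-width uses the Student-t
#' quantile, `t(0.975, n-1) * s / sqrt(n)`; the CI of each AL is reported as
#' the full width `2 * z * s * sqrt(3/n)` (the classical large-sample
#' variance `3 s^2 / n` of an agreement limit).
#'
#' @param diffs numeric percent differences (n >= 3).
#' @param z agreement-limit multiplier (default 1.96).
#' @param loa_ci `"z"` (default) or `"t"`: quantile used in the AL CI width.
#' @return object of class `bland_altman`: `n`, `bias`, `sd`, `loa_low`,
#'   `loa_high`, `gap` (= z*s), `ci_bias_halfwidth`, `ci_loa_fullwidth`,
#'   `n_outside_loa`, `n_outside_outer_ci`, `diffs`.
#' @examples
#' print(bland_altman(c(20, -20, 5, -5)))
#' @export
bland_altman <- function(diffs, z = 1.96, loa_ci = c("z", "t")) {
  loa_ci <- match.arg(loa_ci)
  diffs <- as.numeric(diffs)
  n <- length(diffs)
  if (n < 3L) stop("Bland-Altman requires at least 3 differences")
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  gap <- z * s
  q <- if (loa_ci == "z") z else stats::qt(0.975, n - 1)
  ba <- structure(list(n = n, bias = bias, sd = s,
                       loa_low = bias - gap, loa_high = bias + gap, gap = gap,
                       ci_bias_halfwidth = stats::qt(0.975, n - 1) * s / sqrt(n),
                       ci_loa_fullwidth = 2 * q * s * sqrt(3 / n),
                       z = z, diffs = diffs),
                  class = "bland_altman")
  cnt <- count_outside(diffs, ba)
  ba$n_outside_loa <- cnt[["n_outside_loa"]]
  ba$n_outside_outer_ci <- cnt[["n_outside_outer_ci"]]
  ba
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d, percent differences)\n", x$n))
  cat(sprintf("  bias %.2f%%  (95%% CI half-width %.2f)\n",
              x$bias, x$ci_bias_halfwidth))
  cat(sprintf("  SD %.2f%%, gap bias<->AL %.2f%%\n", x$sd, x$gap))
  cat(sprintf("  limits of agreement [%.2f, %.2f], CI of AL (full width) %.2f\n",
              x$loa_low, x$loa_high, x$ci_loa_fullwidth))
  cat(sprintf("  outside AL: %d; outside AL outer CI edge: %d\n",
              x$n_outside_loa, x$n_outside_outer_ci))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, means = NULL, ...) {
  xs <- if (is.null(means)) seq_along(x$diffs) else means
  xl <- if (is.null(means)) "pair index" else "pair mean (HU)"
  hw <- x$ci_loa_fullwidth / 2
  graphics::plot(xs, x$diffs, pch = 19, xlab = xl,
                 ylab = "difference ((MDCT - DE-CBCT)/average, %)",
                 ylim = range(x$diffs, x$loa_low - hw, x$loa_high + hw), ...)
  for (lv in c(x$loa_low, x$loa_high)) {
    graphics::rect(graphics::par("usr")[1], lv - hw,
                   graphics::par("usr")[2], lv + hw,
                   col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  }
  graphics::abline(h = x$bias, col = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Count differences outside the agreement limits
#'
#' `n_outside_loa` counts differences strictly beyond `[loa_low, loa_high]`;
#' `n_outside_outer_ci` counts those beyond the outer CI edges of the
#' limits, `[loa_low - w/2, loa_high + w/2]` with `w` the AL CI full width.
#'
#' @param diffs the percent differences the result was computed from.
#' @param ba a `bland_altman` result.
#' @return named numeric: `n_outside_loa`, `n_outside_outer_ci`.
#' @export
count_outside <- function(diffs, ba) {
  hw <- ba$ci_loa_fullwidth / 2
  c(n_outside_loa = sum(diffs < ba$loa_low | diffs > ba$loa_high),
    n_outside_outer_ci = sum(diffs < ba$loa_low - hw | diffs > ba$loa_high + hw))
}

#' Full cross-modality agreement report
#'
#' For each group (e.g. mandible, maxilla) and for all pairs combined:
#' Shapiro-Wilk normality gate on the percent differences, identity-line
#' deviation-band counts, and Bland-Altman analysis with outside counts.
#' Pairs with a non-positive average are excluded and recorded. Groups
#' failing the normality gate are flagged; their analysis is still emitted.
#'
#' @param pairs `measurement_pairs` data.frame (columns `label`, `group`,
#'   `mean_mdct`, `mean_decbct`).
#' @param z agreement-limit multiplier.
#' @param deviation_mode passed to [deviation_percent()].
#' @param sw_alpha normality-gate significance level.
#' @return object of class `agreement_report`: `bands` (a [band_report()]),
#'   `groups` (named list with `shapiro`, `ba` per group and `"combined"`),
#'   `excluded`, `pairs`.
#' @export
agreement_report <- function(pairs, z = 1.96,
                             deviation_mode = c("identity_x", "average"),
                             sw_alpha = 0.01) {
  deviation_mode <- match.arg(deviation_mode)
  if (nrow(pairs) == 0L) stop("no measurement pairs")
  avg <- (pairs$mean_mdct + pairs$mean_decbct) / 2
  bad <- avg <= 0
  excluded <- pairs[bad, , drop = FALSE]
  pairs <- pairs[!bad, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("all pairs excluded (non-positive averages)")
  diffs <- percent_difference(pairs)
  dev <- deviation_percent(pairs, mode = deviation_mode)
  bands <- band_report(dev, group = pairs$group)
  grp_names <- unique(pairs$group)
  sets <- c(stats::setNames(lapply(grp_names, function(g) diffs[pairs$group == g]),
                            grp_names),
            if (length(grp_names) > 1L) list(combined = diffs))
  groups <- lapply(sets, function(d) {
    sw <- if (length(d) >= 3L && stats::sd(d) > 0) shapiro_wilk(d, sw_alpha)
          else list(W = NA_real_, p_value = NA_real_, n = length(d),
                    passes = NA)
    list(shapiro = sw, ba = bland_altman(d, z = z))
  })
  structure(list(bands = bands, groups = groups, excluded = excluded,
                 pairs = pairs, deviation_mode = deviation_mode,
                 sw_alpha = sw_alpha),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  print(x$bands)
  for (g in names(x$groups)) {
    gr <- x$groups[[g]]
    cat(sprintf("\n[%s]  Shapiro-Wilk W = %.4f, p = %.4g (%s)\n", g,
                gr$shapiro$W, gr$shapiro$p_value,
                if (isTRUE(gr$shapiro$passes)) "normality gate passed"
                else "normality gate FAILED"))
    print(gr$ba)
  }
  if (nrow(x$excluded))
    cat(sprintf("\n%d pair(s) excluded (non-positive average)\n",
                nrow(x$excluded)))
  invisible(x)
}

#' @export
plot.agreement_report <- function(x, which = c("scatter", "ba"), ...) {
  which <- match.arg(which)
  p <- x$pairs
  if (which == "scatter") {
    rng <- range(p$mean_mdct, p$mean_decbct)
    graphics::plot(p$mean_mdct, p$mean_decbct, pch = 19,
                   col = as.integer(factor(p$group)),
                   xlim = rng, ylim = rng, xlab = "MDCT ROI mean (HU)",
                   ylab = "DE-CBCT ROI mean (HU)",
                   main = "Paired ROI means and identity line", ...)
    graphics::abline(0, 1)
    for (b in c(10, 15, 20))
      graphics::abline(0, c(1 + b / 100, 1 - b / 100),
                       lty = c(2, 2) + (b > 10), col = "grey40")
    graphics::legend("topleft", legend = levels(factor(p$group)), pch = 19,
                     col = seq_along(unique(p$group)), bty = "n")
  } else {
    comb <- x$groups[[length(x$groups)]]$ba
    plot(comb, means = (p$mean_mdct + p$mean_decbct) / 2, ...)
  }
  invisible(x)
}
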