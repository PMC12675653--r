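# Statistical layer: paired and one-sample t tests, Bonferroni correction,
# paired Cohen's d with interpretation bins, and the per-device summary
# table. Degenerate (zero-variance) inputs are flagged explicitly, never
# reported as silent zeros.

t_result <- function(t, df, p, degenerate = FALSE) {
  list(t = t, df = df, p = p, degenerate = degenerate)
}

#' Paired-sample t test (dark vs. bright)
#'
#' Computed on the differences `dark - bright` with the sample SD (n - 1)
#' and a two-sided p value. Zero-variance differences make the statistic
#' undefined (0/0); such inputs return `degenerate = TRUE` with NaN
#' statistics rather than raising.
#'
#' @param bright,dark Equal-length participant-aligned value vectors,
#'   n >= 2.
#' @return List: `t`, `df`, `p`, `degenerate`.
#' @export
paired_t <- function(bright, dark) {
  if (length(bright) != length(dark)) abort_config("paired vectors must have equal length")
  one_sample_t_vs_zero(dark - bright)
}

#' One-sample t test against zero
#'
#' Used for the shift-greater-than-zero question: apparent gaze shifts are
#' non-negative magnitudes, so a mean above zero indicates a systematic
#' artifact. Two-sided p value.
#'
#' @param x Value vector, n >= 2.
#' @return List: `t`, `df`, `p`, `degenerate`.
#' @export
one_sample_t_vs_zero <- function(x) {
  n <- length(x)
  if (n < 2L) abort_insufficient("t test needs n >= 2")
  if (anyNA(x)) abort_config("t test input contains missing values")
  s <- stats::sd(x)
  if (s == 0) return(t_result(NaN, n - 1L, NA_real_, degenerate = TRUE))
  t <- mean(x) / (s / sqrt(n))
  t_result(t, n - 1L, 2 * stats::pt(-abs(t), df = n - 1), degenerate = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies each p value by the family size and caps at 1. The family is
#' by default the vector itself (`m = length(p_values)`); pass `m`
#' explicitly when the family spans several calls (e.g. one metric tested
#' across all devices).
#'
#' @param p_values Vector of p values in [0, 1] (NA passes through).
#' @param m Family size; default `length(p_values)`.
#' @return Adjusted p values, same length.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort_domain("p values must lie in [0, 1]")
  }
  if (m < 1) abort_config("`m` must be >= 1")
  pmin(1, p_values * m)
}

#' Paired Cohen's d with interpretation bins
#'
#' Difference-score form: `d = mean(dark - bright) / sd(dark - bright)`,
#' which satisfies `d = t / sqrt(n)` with the paired t statistic. The
#' averaged-SD variant (`method = "av"`) divides instead by the mean of the
#' two condition SDs. Interpretation of |d|: negligible < 0.2 <= small
#' < 0.5 <= medium < 0.8 <= large.
#'
#' @param bright,dark Equal-length participant-aligned value vectors.
#' @param method `"dz"` (difference-score, default) or `"av"`
#'   (averaged-SD).
#' @return List: `d`, `interpretation`, `degenerate`.
#' @export
cohens_d_paired <- function(bright, dark, method = c("dz", "av")) {
  method <- match.arg(method)
  if (length(bright) != length(dark)) abort_config("paired vectors must have equal length")
  diffs <- dark - bright
  if (length(diffs) < 2L) abort_insufficient("Cohen's d needs n >= 2")
  denom <- if (method == "dz") stats::sd(diffs)
           else (stats::sd(bright) + stats::sd(dark)) / 2
  if (!is.finite(denom) || denom == 0) {
    return(list(d = NaN, interpretation = NA_character_, degenerate = TRUE))
  }
  d <- mean(diffs) / denom
  list(d = d, interpretation = interpret_d(d), degenerate = FALSE)
}

#' Effect-size interpretation bins for Cohen's d
#'
#' Left-closed bins on |d|: negligible (< 0.2), small (0.2 to < 0.5),
#' medium (0.5 to < 0.8), large (>= 0.8).
#'
#' @param d Effect size (vectorized).
#' @return Character vector of bin labels.
#' @export
interpret_d <- function(d) {
  a <- abs(d)
  out <- rep(NA_character_, length(d))
  out[a < 0.2] <- "negligible"
  out[a >= 0.2 & a < 0.5] <- "small"
  out[a >= 0.5 & a < 0.8] <- "medium"
  out[a >= 0.8] <- "large"
  out
}

#' Summary table of bright-vs-dark comparisons across devices
#'
#' Input is tidy participant-level data: one value per participant x
#' device x condition x metric. Per device and metric the function
#' computes condition means, SDs, medians and IQRs, the paired t test,
#' Bonferroni-adjusted p (family = the devices testing that metric, i.e.
#' `m` = number of devices, configurable via `family`), and paired
#' Cohen's d with its interpretation. Participants missing one condition
#' are dropped pairwise with a warning.
#'
#' @param data Data frame with columns `participant`, `device`, `metric`,
#'   `condition` (`"bright"`/`"dark"`), `value`.
#' @param family `"per-metric"` (default; m = number of devices per
#'   metric), `"none"` (m = 1) or a positive integer used as m directly.
#' @param d_method Cohen's d variant, see [cohens_d_paired()].
#' @return Data frame of class `psaqc_comparison` with one row per
#'   device x metric.
#' @export
summarize_comparisons <- function(data, family = "per-metric",
                                  d_method = "dz") {
  need <- c("participant", "device", "metric", "condition", "value")
  if (!all(need %in% names(data))) {
    abort_config(sprintf("data must have columns: %s", paste(need, collapse = ", ")))
  }
  rows <- list()
  for (met in unique(data$metric)) {
    sub_m <- data[data$metric == met, ]
    devices <- unique(sub_m$device)
    m <- if (identical(family, "per-metric")) length(devices)
         else if (identical(family, "none")) 1L
         else as.integer(family)
    for (dev in devices) {
      sub <- sub_m[sub_m$device == dev, ]
      wide <- merge(
        sub[sub$condition == "bright", c("participant", "value")],
        sub[sub$condition == "dark", c("participant", "value")],
        by = "participant", suffixes = c("_bright", "_dark"))
      n_all <- length(unique(sub$participant))
      if (nrow(wide) < n_all) {
        warning(sprintf("%s/%s: %d participant(s) missing a condition, dropped pairwise",
                        dev, met, n_all - nrow(wide)), call. = FALSE)
      }
      if (nrow(wide) < 2L) {
        abort_insufficient(sprintf("%s/%s: need >= 2 complete participants", dev, met))
      }
      b <- wide$value_bright; d <- wide$value_dark
      tt <- paired_t(b, d)
      es <- cohens_d_paired(b, d, method = d_method)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = met, device = dev, n = nrow(wide),
        mean_bright = mean(b), sd_bright = stats::sd(b),
        median_bright = stats::median(b), iqr_bright = stats::IQR(b),
        mean_dark = mean(d), sd_dark = stats::sd(d),
        median_dark = stats::median(d), iqr_dark = stats::IQR(d),
        t = tt$t, df = tt$df, p_raw = tt$p,
        p_adjusted = if (is.na(tt$p)) NA_real_ else bonferroni(tt$p, m = m),
        cohens_d = es$d, d_interpretation = es$interpretation,
        degenerate = tt$degenerate || es$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("psaqc_comparison", "data.frame")
  out
}

#' Shift-greater-than-zero tests per device
#'
#' One-sample t tests of per-participant mean apparent gaze shifts against
#' zero, Bonferroni-adjusted across devices, with one-sample Cohen's d
#' (`mean / sd`).
#'
#' @param shifts Data frame with columns `participant`, `device`, `shift`
#'   (one mean shift per participant x device).
#' @return Data frame, one row per device: n, mean, sd, t, df, p_raw,
#'   p_adjusted, cohens_d, d_interpretation, degenerate.
#' @export
shift_vs_zero_table <- function(shifts) {
  need <- c("participant", "device", "shift")
  if (!all(need %in% names(shifts))) {
    abort_config("shifts must have columns participant, device, shift")
  }
  devices <- unique(shifts$device)
  rows <- lapply(devices, function(dev) {
    x <- shifts$shift[shifts$device == dev]
    tt <- one_sample_t_vs_zero(x)
    d <- if (stats::sd(x) > 0) mean(x) / stats::sd(x) else NaN
    data.frame(device = dev, n = length(x), mean_shift = mean(x),
               sd_shift = stats::sd(x), t = tt$t, df = tt$df, p_raw = tt$p,
               cohens_d = d,
               d_interpretation = if (is.finite(d)) interpret_d(d) else NA_character_,
               degenerate = tt$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p_raw, m = length(devices))
  rownames(out) <- NULL
  out
}

#' Plain-text report of a comparison table
#'
#' @param comparison Result of [summarize_comparisons()].
#' @param digits Significant digits.
#' @return Character vector of report lines (invisibly printed).
#' @export
format_comparison_report <- function(comparison, digits = 3) {
  fmt <- function(x) formatC(x, digits = digits, format = "fg")
  lines <- c(sprintf("%-12s %-14s %-16s %-16s %-12s %-8s %s",
                     "metric", "device", "bright (M+-SD)", "dark (M+-SD)",
                     "t (df)", "adj. p", "Cohen's d"))
  for (i in seq_len(nrow(comparison))) {
    r <- comparison[i, ]
    lines <- c(lines, sprintf(
      "%-12s %-14s %-16s %-16s %-12s %-8s %s",
      r$metric, r$device,
      paste0(fmt(r$mean_bright), "+-", fmt(r$sd_bright)),
      paste0(fmt(r$mean_dark), "+-", fmt(r$sd_dark)),
      if (r$degenerate) "degenerate" else sprintf("%s (%d)", fmt(r$t), r$df),
      if (is.na(r$p_adjusted)) "-" else fmt(r$p_adjusted),
      if (r$degenerate) "-" else sprintf("%s (%s)", fmt(r$cohens_d), r$d_interpretation)))
  }
  lines
}
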