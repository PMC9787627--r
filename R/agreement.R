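# Method-agreement statistics: Pearson correlation (product-moment sums
# form), Bland-Altman mean difference and limits of agreement, relative and
# absolute mean absolute error, and percentage-change arithmetic.

#' Pearson correlation (product-moment sums form)
#'
#' The product-moment coefficient
#' `r = (n*S_xy - S_x*S_y) / sqrt((n*S_xx - S_x^2) (n*S_yy - S_y^2))`,
#' evaluated in the numerically stable centred form.
#'
#' @param device,reference Numeric vectors of paired measurements, equal
#'   length `n >= 2`.
#' @return `r` in `[-1, 1]`, or `NA` with a warning if either series has
#'   zero variance.
#' @export
pearson_r <- function(device, reference) {
  n <- length(device)
  stopifnot(n == length(reference), n >= 2)
  # centred two-pass evaluation: algebraically identical to the raw-sums
  # product-moment form but immune to the cancellation that form suffers
  # under large shifts
  dx <- device - sum(device) / n
  dy <- reference - sum(reference) / n
  den2 <- sum(dx^2) * sum(dy^2)
  if (den2 <= 0) {
    warning("zero variance in one series; correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  r <- sum(dx * dy) / sqrt(den2)
  min(max(r, -1), 1)
}

#' Bland-Altman mean difference and limits of agreement
#'
#' Differences are `device - reference`; `MD` is their mean and the limits
#' of agreement are `MD +/- 1.96 * SD` with the sample SD (`n - 1`
#' denominator), the standard Bland-Altman convention.
#'
#' @param device,reference Numeric vectors of paired measurements.
#' @return list `MD`, `LoA_upper`, `LoA_lower`, `SD_d`, `n`. With `n < 2`
#'   the limits are `NA`.
#' @export
bland_altman <- function(device, reference) {
  n <- length(device)
  stopifnot(n == length(reference), n >= 1)
  d <- device - reference
  md <- mean(d)
  if (n < 2) {
    warning("need n >= 2 for limits of agreement", call. = FALSE)
    return(list(MD = md, LoA_upper = NA_real_, LoA_lower = NA_real_,
                SD_d = NA_real_, n = n))
  }
  sdd <- sqrt(sum((d - md)^2) / (n - 1))
  list(MD = md, LoA_upper = md + 1.96 * sdd, LoA_lower = md - 1.96 * sdd,
       SD_d = sdd, n = n)
}

#' Relative mean absolute error, percent
#'
#' `mean(|device - reference| / reference) * 100`. All reference values
#' must be nonzero.
#'
#' @param device,reference Numeric vectors of paired measurements.
#' @return MAE as a percentage of the reference.
#' @export
mae_percent <- function(device, reference) {
  n <- length(device)
  stopifnot(n == length(reference), n >= 1)
  if (any(reference == 0))
    stop("relative MAE undefined: reference contains zeros", call. = FALSE)
  mean(abs(device - reference) / abs(reference)) * 100
}

#' Absolute mean absolute error
#'
#' `mean(|device - reference|)`, in the units of the measurements (e.g.,
#' BrPM for respiration rates).
#'
#' @param device,reference Numeric vectors of paired measurements.
#' @return MAE in measurement units.
#' @export
mae_abs <- function(device, reference) {
  stopifnot(length(device) == length(reference), length(device) >= 1)
  mean(abs(device - reference))
}

#' Percentage change between two values
#'
#' `(new - old) / denom * 100`, with the denominator chosen explicitly:
#' `"old"` (the usual convention) or `"new"` (change expressed relative to
#' the newer value). With `use_magnitudes = TRUE` absolute values are taken
#' first, for comparing signed quantities such as mean differences by size.
#'
#' @param new,old Numeric scalars; the denominator value must be nonzero.
#' @param denominator `"old"` or `"new"`.
#' @param use_magnitudes Compare `|new|` and `|old|` instead.
#' @return The change, percent.
#' @export
percent_change <- function(new, old, denominator = c("old", "new"),
                           use_magnitudes = FALSE) {
  denominator <- match.arg(denominator)
  if (use_magnitudes) { new <- abs(new); old <- abs(old) }
  den <- if (denominator == "old") old else new
  if (den == 0) stop("zero denominator in percentage change", call. = FALSE)
  (new - old) / den * 100
}

#' Full agreement report between a device and a reference series
#'
#' Bundles [pearson_r()], [bland_altman()], [mae_percent()] and [mae_abs()]
#' into the report used to characterise the device against a reference.
#' Pairs with a missing value in either series are dropped first.
#'
#' @param device,reference Numeric vectors of paired measurements.
#' @return list of class `agreement_report`: `r`, `MD`, `LoA_upper`,
#'   `LoA_lower`, `MAE_pct`, `MAE_abs`, `n`.
#' @export
agreement_report <- function(device, reference) {
  stopifnot(length(device) == length(reference))
  ok <- !is.na(device) & !is.na(reference)
  device <- device[ok]; reference <- reference[ok]
  if (length(device) < 2)
    stop("need at least 2 complete pairs for an agreement report",
         call. = FALSE)
  ba <- bland_altman(device, reference)
  structure(list(r = pearson_r(device, reference),
                 MD = ba$MD, LoA_upper = ba$LoA_upper,
                 LoA_lower = ba$LoA_lower,
                 MAE_pct = if (all(reference != 0))
                   mae_percent(device, reference) else NA_real_,
                 MAE_abs = mae_abs(device, reference),
                 n = length(device)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> n =", x$n, "\n")
  cat(sprintf("  r = %.4f | MD = %+.3f | LoA = %+.3f / %+.3f | MAE = %.2f%% (%.3f abs)\n",
              x$r, x$MD, x$LoA_upper, x$LoA_lower, x$MAE_pct, x$MAE_abs))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Plots the per-pair differences against the per-pair means with the mean
#' difference and 1.96-SD limits of agreement as horizontal lines.
#'
#' @param device,reference Numeric vectors of paired measurements.
#' @param xlab,ylab,main Plot annotations.
#' @return The [bland_altman()] list, invisibly.
#' @export
bland_altman_plot <- function(device, reference,
                              xlab = "Mean of methods",
                              ylab = "Difference (device - reference)",
                              main = "Bland-Altman") {
  ba <- bland_altman(device, reference)
  m <- (device + reference) / 2
  d <- device - reference
  plot(m, d, pch = 19, col = "steelblue", xlab = xlab, ylab = ylab,
       main = main,
       ylim = range(c(d, ba$LoA_lower, ba$LoA_upper), na.rm = TRUE))
  graphics::abline(h = ba$MD, col = "darkgreen", lwd = 2)
  graphics::abline(h = c(ba$LoA_lower, ba$LoA_upper), col = "red",
                   lty = 2, lwd = 2)
  invisible(ba)
}
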