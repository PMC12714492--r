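# Seasonality of monthly conflict events.
#
# Rescue dates are aggregated by calendar month across the analysis window
# and a single-harmonic sinusoid (period fixed at 12 months) is fitted by
# ordinary least squares on the sin/cos basis at month midpoints -
# algebraically the same as minimizing mean squared error over amplitude
# and phase.

#' Read rescue records from CSV
#'
#' @param file CSV with columns `date` (ISO-8601), `subgrid_id`, `sex`,
#'   `age_class`.
#' @return data.frame with a parsed `Date` column.
#' @export
read_rescues <- function(file) {
  r <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("date", "subgrid_id", "sex", "age_class") %in% names(r)))
  r$date <- as.Date(r$date)
  if (anyNA(r$date)) stop("unparseable date(s) in rescue file")
  r
}

#' Monthly counts of events within a window
#'
#' Counts events per calendar month (January..December), summed across the
#' years of the window. Events outside the window are excluded and logged
#' in the `"excluded"` attribute.
#'
#' @param dates Date vector (or a rescue data.frame with a `date` column).
#' @param window length-2 Date vector `c(start, end)`, inclusive.
#' @return named integer vector of length 12 with attribute `"excluded"`.
#' @export
monthly_counts <- function(dates, window) {
  if (is.data.frame(dates)) dates <- dates$date
  dates <- as.Date(dates)
  window <- as.Date(window)
  stopifnot(length(window) == 2, window[1] <= window[2])
  keep <- dates >= window[1] & dates <= window[2]
  m <- as.integer(format(dates[keep], "%m"))
  counts <- tabulate(m, nbins = 12L)
  names(counts) <- month.abb
  attr(counts, "excluded") <- sum(!keep)
  counts
}

#' Fit a period-12 sinusoid to monthly counts
#'
#' Least-squares fit of `a0 + a1*sin(2*pi*m/12) + a2*cos(2*pi*m/12)` with
#' the twelve counts placed at month midpoints `m = 0.5, 1.5, ..., 11.5`
#' (so "start of" and "end of" a month are expressible in the recovered
#' phase). The fit is exact for any pure period-12 sinusoid; amplitude is
#' `sqrt(a1^2 + a2^2)`, and peak and trough are 6 months apart.
#'
#' @param counts numeric vector of length 12 (January..December).
#' @return object of class `sinusoid_fit`: coefficients `a0`, `a1`, `a2`,
#'   `amplitude`, `peak` and `trough` (month fraction in [0, 12)),
#'   `fitted_max`, `fitted_min`, `mse`, `degenerate` flag, and the `lm`
#'   fit.
#' @export
fit_sinusoid <- function(counts) {
  stopifnot(length(counts) == 12, is.numeric(counts))
  m <- seq(0.5, 11.5, by = 1)
  s <- sin(2 * pi * m / 12); cc <- cos(2 * pi * m / 12)
  fit <- stats::lm(counts ~ s + cc)
  a <- unname(stats::coef(fit))
  amp <- sqrt(a[2]^2 + a[3]^2)
  degenerate <- amp < 1e-9
  peak <- if (degenerate) NA_real_
          else (12 * atan2(a[2], a[3]) / (2 * pi)) %% 12
  structure(list(a0 = a[1], a1 = a[2], a2 = a[3], amplitude = amp,
                 peak = peak,
                 trough = if (degenerate) NA_real_ else (peak + 6) %% 12,
                 fitted_max = a[1] + amp, fitted_min = a[1] - amp,
                 mse = mean(stats::residuals(fit)^2),
                 degenerate = degenerate, counts = counts, lm = fit),
            class = "sinusoid_fit")
}

# turn a month fraction in [0,12) into "early/mid/late <Month>"
.month_label <- function(frac) {
  mo <- floor(frac) + 1L
  part <- frac - floor(frac)
  desc <- if (part < 1 / 3) "early" else if (part < 2 / 3) "mid" else "late"
  paste(desc, month.name[mo])
}

#' Peak and trough of a fitted seasonal sinusoid
#'
#' @param fit a non-degenerate [fit_sinusoid()] result.
#' @return list with numeric `peak`/`trough` month fractions, readable
#'   `peak_label`/`trough_label` (e.g. "early July"), and the fitted
#'   extreme values `fitted_max` and `fitted_min`.
#' @export
peak_trough <- function(fit) {
  stopifnot(inherits(fit, "sinusoid_fit"))
  if (fit$degenerate)
    stop("degenerate fit (zero amplitude): no seasonal peak")
  list(peak = fit$peak, peak_label = .month_label(fit$peak),
       fitted_max = fit$fitted_max,
       trough = fit$trough, trough_label = .month_label(fit$trough),
       fitted_min = fit$fitted_min)
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat("Period-12 sinusoid fit to monthly counts\n")
  cat(sprintf("  level %.3f, amplitude %.3f, residual MSE %.4g\n",
              x$a0, x$amplitude, x$mse))
  if (x$degenerate) {
    cat("  degenerate: no seasonal signal\n")
  } else {
    pt <- peak_trough(x)
    cat(sprintf("  peak %.2f (%s), fitted max %.2f\n", pt$peak,
                pt$peak_label, pt$fitted_max))
    cat(sprintf("  trough %.2f (%s), fitted min %.2f\n", pt$trough,
                pt$trough_label, pt$fitted_min))
  }
  invisible(x)
}

#' @export
plot.sinusoid_fit <- function(x, ...) {
  m <- seq(0.5, 11.5, by = 1)
  graphics::plot(m, x$counts, xlab = "month", ylab = "events",
                 xaxt = "n", ...)
  graphics::axis(1, at = m, labels = month.abb)
  mm <- seq(0, 12, length.out = 241)
  graphics::lines(mm, x$a0 + x$a1 * sin(2 * pi * mm / 12) +
                    x$a2 * cos(2 * pi * mm / 12), lty = 2)
  invisible(x)
}

#' Seasonality report for rescue records
#'
#' Convenience wrapper: aggregate to monthly counts within the window, fit
#' the sinusoid, and return counts, fit and peak/trough summary.
#'
#' @param rescues rescue data.frame (see [read_rescues()]) or Date vector.
#' @param window length-2 Date vector.
#' @return list with `counts`, `fit`, and `peaks` (NULL when degenerate).
#' @export
rescue_seasonality <- function(rescues, window) {
  counts <- monthly_counts(rescues, window)
  fit <- fit_sinusoid(as.numeric(counts))
  list(counts = counts, fit = fit,
       peaks = if (fit$degenerate) NULL else peak_trough(fit))
}
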