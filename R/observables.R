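#' Construct an observable time series
#'
#' A labelled scalar time series extracted from a trajectory (or built
#' synthetically), with an analysis window.
#'
#' @param times Strictly increasing times (s).
#' @param values Values (rad), same length as `times`.
#' @param label Short label, e.g. `"mean_angular_deviation_strand1"`.
#' @param window Length-2 numeric `[t_start, t_end]`; defaults to the full
#'   span.
#' @return An object of class `observable_series`.
#' @export
observable_series <- function(times, values, label = "observable",
                              window = range(times)) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length", call. = FALSE)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be strictly increasing with length >= 2", call. = FALSE)
  structure(list(times = times, values = values, label = label,
                 window = as.numeric(window)),
            class = "observable_series")
}

#' @export
print.observable_series <- function(x, ...) {
  cat(sprintf("<observable_series> '%s': %d points on [%.3g, %.3g] s\n",
              x$label, length(x$times), x$window[1], x$window[2]))
  invisible(x)
}

#' @export
as.data.frame.observable_series <- function(x, ...) {
  data.frame(time = x$times, value = x$values, label = x$label,
             stringsAsFactors = FALSE)
}

#' Mean angular deviation of one strand
#'
#' The strand-averaged rotation angle
#' \deqn{\bar\varphi(t) = n^{-1} \sum_{i=1}^n \varphi_{ji}(t),}
#' the model's stability observable. Strand 1 is the default.
#'
#' @param traj A [integrate_chain()] result.
#' @param strand 1 or 2.
#' @return An [observable_series()].
#' @export
mean_angular_deviation <- function(traj, strand = 1) {
  stopifnot(inherits(traj, "trajectory"))
  if (!length(strand) == 1L || !strand %in% c(1, 2))
    stop("'strand' must be 1 or 2", call. = FALSE)
  phi <- if (strand == 1) traj$phi1 else traj$phi2
  observable_series(traj$times, rowMeans(phi),
                    label = sprintf("mean_angular_deviation_strand%d", strand))
}

# Constant steady offset: mean over the final quarter of the window.
steady_offset <- function(series) {
  w <- series$window
  sel <- series$times >= w[2] - diff(w) / 4 & series$times <= w[2]
  mean(series$values[sel])
}

# Local maxima of y (first sample of any plateau), then greedy thinning so
# kept peaks are at least min_sep apart (the larger peak wins a conflict).
find_peaks <- function(times, y, min_sep) {
  m <- length(y)
  if (m < 3L) return(integer(0))
  d <- diff(y)
  cand <- integer(0)
  i <- 1L
  while (i < m) {
    if (d[i] > 0) {
      j <- i + 1L
      while (j < m && d[j] == 0) j <- j + 1L
      if (j >= m || d[j] < 0) cand <- c(cand, i + 1L)
      i <- j
    } else i <- i + 1L
  }
  if (!length(cand)) return(cand)
  kept <- cand[1]
  for (k in cand[-1]) {
    last <- kept[length(kept)]
    if (times[k] - times[last] >= min_sep) {
      kept <- c(kept, k)
    } else if (y[k] > y[last]) {
      kept[length(kept)] <- k
    }
  }
  kept
}

# Dominant period estimated from zero crossings of the detrended signal:
# two crossings per period.
dominant_period <- function(times, detrended) {
  s <- sign(detrended)
  s[s == 0] <- 1
  crossings <- sum(diff(s) != 0)
  if (crossings < 2) return(diff(range(times)))
  2 * diff(range(times)) / crossings
}

#' Oscillation envelope of an observable
#'
#' Removes the steady offset (mean over the final quarter of the window —
#' a constant drive induces a nonzero mean) and returns the upper envelope:
#' the local maxima of the absolute detrended signal, thinned to a minimum
#' separation of half the dominant period (estimated from zero crossings).
#' The envelope is reported as a series at the peak times; interpolate
#' linearly between them for a continuous envelope.
#'
#' @param series An [observable_series()].
#' @return An [observable_series()] of peak magnitudes at peak times, with
#'   attribute `offset` (the removed steady offset).
#' @export
envelope <- function(series) {
  stopifnot(inherits(series, "observable_series"))
  off <- steady_offset(series)
  det <- series$values - off
  if (all(det == 0))
    stop("constant series: no extrema to build an envelope from", call. = FALSE)
  per <- dominant_period(series$times, det)
  idx <- find_peaks(series$times, abs(det), min_sep = per / 2)
  if (length(idx) < 3L)
    stop(sprintf("too few local extrema (%d) to build an envelope; need >= 3",
                 length(idx)), call. = FALSE)
  out <- observable_series(series$times[idx], abs(det)[idx],
                           label = paste0(series$label, "_envelope"),
                           window = series$window)
  attr(out, "offset") <- off
  out
}

#' Damping metrics of an oscillating observable
#'
#' Quantifies how fast the oscillation settles: an exponential decay rate
#' fitted by least squares to the log of the envelope peaks, and the maximal
#' deviations from the steady offset inside an early and a late window.
#' A late/early amplitude ratio near or above 1 means no attenuation over
#' the span (the low-viscosity regime); a small ratio means rapid
#' stabilization (the high-viscosity regime).
#'
#' @param series An [observable_series()].
#' @param early_window,late_window Length-2 numeric windows (s) inside the
#'   series' span, early preceding late. Defaults: first and last sixth of
#'   the span.
#' @return An object of class `damping_metrics`: `decay_rate` (s^-1),
#'   `early_amplitude`, `late_amplitude` (rad), `amplitude_ratio`
#'   (late/early; `NA` and flagged when the early amplitude is zero),
#'   `ratio_defined`, `fit_quality` (R^2 of the log-linear fit, in [0, 1]),
#'   `n_peaks`.
#' @export
damping_metrics <- function(series, early_window = NULL, late_window = NULL) {
  stopifnot(inherits(series, "observable_series"))
  span <- range(series$times)
  if (is.null(early_window)) early_window <- c(span[1], span[1] + diff(span) / 6)
  if (is.null(late_window)) late_window <- c(span[2] - diff(span) / 6, span[2])
  check_win <- function(w, what) {
    if (length(w) != 2L || w[1] >= w[2] || w[1] < span[1] - 1e-15 ||
        w[2] > span[2] + diff(span) * 1e-9)
      stop(sprintf("'%s' must be an increasing interval inside the series span",
                   what), call. = FALSE)
  }
  check_win(early_window, "early_window"); check_win(late_window, "late_window")
  if (early_window[1] > late_window[1])
    stop("'early_window' must precede 'late_window'", call. = FALSE)
  off <- steady_offset(series)
  det <- series$values - off
  amp_in <- function(w) {
    sel <- series$times >= w[1] & series$times <= w[2]
    if (!any(sel)) stop("empty analysis window", call. = FALSE)
    max(abs(det[sel]))
  }
  early <- amp_in(early_window); late <- amp_in(late_window)
  if (all(series$values == series$values[1])) {
    return(structure(list(decay_rate = 0, early_amplitude = early,
                          late_amplitude = late, amplitude_ratio = NA_real_,
                          ratio_defined = FALSE, fit_quality = 0, n_peaks = 0L),
                     class = "damping_metrics"))
  }
  env <- envelope(series)
  pos <- env$values > 0
  if (sum(pos) < 3L)
    stop("too few positive envelope peaks for a decay fit", call. = FALSE)
  fit <- stats::lm(log(env$values[pos]) ~ env$times[pos])
  rate <- -unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  structure(list(decay_rate = rate,
                 early_amplitude = early, late_amplitude = late,
                 amplitude_ratio = if (early > 0) late / early else NA_real_,
                 ratio_defined = early > 0,
                 fit_quality = max(0, min(1, r2)),
                 n_peaks = length(env$values)),
            class = "damping_metrics")
}

#' @export
print.damping_metrics <- function(x, ...) {
  cat(sprintf(
    "<damping_metrics> decay_rate = %.4g s^-1 (R^2 = %.3f, %d peaks)\n",
    x$decay_rate, x$fit_quality, x$n_peaks))
  cat(sprintf(" early amplitude %.4g rad, late %.4g rad, late/early = %s\n",
              x$early_amplitude, x$late_amplitude,
              if (x$ratio_defined) sprintf("%.4g", x$amplitude_ratio)
              else "undefined"))
  invisible(x)
}

#' Write an observable series to CSV
#'
#' @param series An [observable_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observable_csv <- function(series, path) {
  stopifnot(inherits(series, "observable_series"))
  utils::write.csv(as.data.frame(series)[, c("time", "value")], path,
                   row.names = FALSE)
  invisible(path)
}
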