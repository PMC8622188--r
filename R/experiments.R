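#' Viscosity sweep
#'
#' Runs the identical simulation across a set of viscosity scales `lambda`
#' and computes the strand-1 mean angular deviation and its damping metrics
#' for each. This is the experiment behind the model's central result: the
#' envelope decay rate grows with viscosity (rapid stabilization), and at
#' low viscosity the late/early amplitude ratio stays high (no attenuation).
#'
#' @param seq First-strand sequence string.
#' @param lambdas Positive, unique viscosity scales; results are ordered by
#'   increasing lambda.
#' @param forcing A [forcing_spec()].
#' @param t_end,dt,n_out,strand2_sign Passed to [integrate_chain()].
#' @param strand Strand for the observable (default 1).
#' @param keep_trajectories Keep the full trajectories (default `FALSE`;
#'   they are large).
#' @return An object of class `sweep_result`: `lambdas`, `series` (list of
#'   [observable_series()]), `metrics` (list of [damping_metrics()]),
#'   `sequence` metadata (n, GC fraction, source label), and optionally
#'   `trajectories`.
#' @export
viscosity_sweep <- function(seq, lambdas = c(0.1, 0.5, 1, 2, 4),
                            forcing = forcing_spec("constant", M0 = 1e-22),
                            t_end = 2e-9, dt = 1e-14, n_out = 1000,
                            strand = 1,
                            strand2_sign = c("symmetric", "as_printed"),
                            keep_trajectories = FALSE) {
  strand2_sign <- match.arg(strand2_sign)
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) < 1L || any(!is.finite(lambdas)) || any(lambdas <= 0))
    stop("'lambdas' must be positive numbers", call. = FALSE)
  if (anyDuplicated(lambdas)) stop("'lambdas' must be unique", call. = FALSE)
  lambdas <- sort(lambdas)
  bases <- check_sequence(seq)
  series <- vector("list", length(lambdas))
  metrics <- vector("list", length(lambdas))
  trajs <- if (keep_trajectories) vector("list", length(lambdas)) else NULL
  for (k in seq_along(lambdas)) {
    res <- tryCatch({
      sys <- build_system(seq, lambda = lambdas[k])
      tr <- integrate_chain(sys, forcing, t_end = t_end, dt = dt,
                            n_out = n_out, strand2_sign = strand2_sign)
      s <- mean_angular_deviation(tr, strand = strand)
      list(series = s, metrics = damping_metrics(s),
           traj = if (keep_trajectories) tr)
    }, error = function(e)
      stop(sprintf("simulation failed at lambda = %g: %s",
                   lambdas[k], conditionMessage(e)), call. = FALSE))
    series[[k]] <- res$series
    metrics[[k]] <- res$metrics
    if (keep_trajectories) trajs[[k]] <- res$traj
  }
  structure(list(
    lambdas = lambdas, series = series, metrics = metrics,
    trajectories = trajs,
    sequence = list(n = length(bases),
                    gc_fraction = mean(bases %in% c("G", "C")),
                    source = attr(seq, "spec")$kind %||% "user"),
    config = list(forcing = unclass(forcing), t_end = t_end, dt = dt,
                  strand = strand, strand2_sign = strand2_sign)),
    class = "sweep_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a viscosity sweep
#'
#' @param object A [viscosity_sweep()] result.
#' @param ... Unused.
#' @return A data.frame with one row per lambda: decay rate, early/late
#'   amplitudes, amplitude ratio and fit quality.
#' @export
summary.sweep_result <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$lambdas), function(k) {
    m <- object$metrics[[k]]
    data.frame(lambda = object$lambdas[k], decay_rate = m$decay_rate,
               early_amplitude = m$early_amplitude,
               late_amplitude = m$late_amplitude,
               amplitude_ratio = m$amplitude_ratio,
               fit_quality = m$fit_quality)
  }))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> n = %d pairs (GC %.1f%%), %d lambda values\n",
              x$sequence$n, 100 * x$sequence$gc_fraction, length(x$lambdas)))
  print(summary(x))
  invisible(x)
}

#' Long-window single run
#'
#' Full pipeline on one configuration: integrate, extract the strand-1 mean
#' angular deviation, and compute damping metrics with the early window
#' defaulting to the first sixth and the late window to the last sixth of
#' the span — the proportional analogue of comparing the onset of a 6 ns
#' run with its final 0.1-1 ns.
#'
#' @inheritParams viscosity_sweep
#' @param lambda Single positive viscosity scale.
#' @return List with `trajectory`, `series`, `metrics`.
#' @export
long_window_run <- function(seq, lambda = 0.1,
                            forcing = forcing_spec("constant", M0 = 1e-22),
                            t_end = 6e-9, dt = 1e-14, n_out = 2000,
                            strand = 1,
                            strand2_sign = c("symmetric", "as_printed")) {
  sys <- build_system(seq, lambda = lambda)
  tr <- integrate_chain(sys, forcing, t_end = t_end, dt = dt, n_out = n_out,
                        strand2_sign = match.arg(strand2_sign))
  s <- mean_angular_deviation(tr, strand = strand)
  span <- range(s$times)
  m <- damping_metrics(s,
                       early_window = c(span[1], span[1] + diff(span) / 6),
                       late_window = c(span[2] - diff(span) / 6, span[2]))
  list(trajectory = tr, series = s, metrics = m)
}

#' Write a trajectory to CSV with a JSON sidecar
#'
#' Writes `<prefix>.csv` with columns `t`, `phi_1_1 ... phi_1_n`,
#' `phi_2_1 ... phi_2_n` (and velocities when requested) and
#' `<prefix>.json` recording the sequence, lambda, forcing and solver
#' settings.
#'
#' @param traj A [integrate_chain()] result.
#' @param prefix Output path prefix.
#' @param velocities Include angular velocity columns (default `FALSE`).
#' @return The CSV path, invisibly.
#' @export
write_trajectory <- function(traj, prefix, velocities = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  n <- traj$config$n
  df <- data.frame(t = traj$times)
  add <- function(df, mat, stem) {
    cols <- as.data.frame(mat)
    names(cols) <- sprintf("%s_%d", stem, seq_len(n))
    cbind(df, cols)
  }
  df <- add(add(df, traj$phi1, "phi_1"), traj$phi2, "phi_2")
  if (velocities)
    df <- add(add(df, traj$dphi1, "dphi_1"), traj$dphi2, "dphi_2")
  csv <- paste0(prefix, ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(traj$config, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Plot a viscosity sweep
#'
#' Overlays the per-lambda mean-angular-deviation traces with a constant
#' vertical shift between curves, the conventional way to compare damping
#' across viscosities on one axis. The shifts are presentation offsets and
#' carry no physical meaning.
#'
#' @param sweep A [viscosity_sweep()] result.
#' @param shift Vertical shift between consecutive curves (rad); default
#'   3x the largest steady offset magnitude.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, shift = NULL) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (is.null(shift))
    shift <- 3 * max(abs(vapply(sweep$series, steady_offset, numeric(1))))
  df <- do.call(rbind, lapply(seq_along(sweep$lambdas), function(k) {
    s <- sweep$series[[k]]
    data.frame(time = s$times,
               value = s$values + (k - 1) * shift,
               lambda = sprintf("lambda = %g", sweep$lambdas[k]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$lambda)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = "mean angular deviation (rad, shifted)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an angular-deviation trace
#'
#' @param series An [observable_series()].
#' @return A ggplot object.
#' @export
plot_series <- function(series) {
  stopifnot(inherits(series, "observable_series"))
  df <- as.data.frame(series)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "angular deviation (rad)",
                  title = series$label) +
    ggplot2::theme_minimal()
}
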