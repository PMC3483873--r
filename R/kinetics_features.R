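#' Extract kinetic summary features from a time series
#'
#' Computes the feature set used to summarize and compare simulated curves:
#' peak time (earliest time attaining the global maximum, so plateaus are
#' resolved deterministically), peak amplitude, area under the curve
#' (trapezoidal), the sustainment index (fraction of the horizon during
#' which the value stays at or above half the peak; 0 by convention for an
#' all-zero series) and the final-to-peak ratio.
#'
#' @param series Data frame with `time` (s) and `value` (nM) columns, as
#'   returned by [evaluate_observable()], or a numeric vector with a matching
#'   `times` argument.
#' @param t_end Horizon, s; defaults to the last time point. Only the part of
#'   the series up to `t_end` is used.
#' @param times Time grid when `series` is a bare numeric vector.
#' @return A list of class `egfr_features` with fields `peak_time`,
#'   `peak_amplitude`, `auc`, `sustainment_index`, `final_over_peak`.
#' @export
extract_features <- function(series, t_end = NULL, times = NULL) {
  if (is.numeric(series) && !is.null(times))
    series <- data.frame(time = times, value = series)
  stopifnot(is.data.frame(series), all(c("time", "value") %in% names(series)),
            nrow(series) > 0)
  if (is.null(t_end)) t_end <- max(series$time)
  s <- series[series$time <= t_end, , drop = FALSE]
  v <- s$value; tt <- s$time
  peak <- max(v)
  peak_time <- tt[which.max(v)]  # which.max returns the earliest maximum
  auc <- if (length(v) > 1) sum(diff(tt) * (utils::head(v, -1) +
                                            utils::tail(v, -1)) / 2) else 0
  sustain <- if (peak <= 0) 0 else {
    above <- v >= peak / 2
    if (length(v) > 1) {
      w <- diff(tt)
      # a grid interval counts when both endpoints are above half-peak
      sum(w[above[-length(above)] & above[-1]]) / (tt[length(tt)] - tt[1])
    } else as.numeric(above)
  }
  structure(list(peak_time = peak_time, peak_amplitude = peak, auc = auc,
                 sustainment_index = sustain,
                 final_over_peak = if (peak > 0) v[length(v)] / peak else 0),
            class = "egfr_features")
}

#' @export
print.egfr_features <- function(x, ...) {
  cat(sprintf(
    "peak %.4g nM at %.4g s | AUC %.4g nM*s | sustainment %.3f | final/peak %.3f\n",
    x$peak_amplitude, x$peak_time, x$auc, x$sustainment_index,
    x$final_over_peak))
  invisible(x)
}

#' Fit an exponential decay rate to a series
#'
#' Log-linear least squares of `log(value)` on time over `[0, window]`; the
#' slope's negation is the decay rate in s^-1.
#'
#' @param series Data frame with `time` and `value`.
#' @param window Fit window length, s.
#' @return Decay rate, s^-1.
#' @keywords internal
fit_decay_rate <- function(series, window) {
  s <- series[series$time <= window & series$value > 0, , drop = FALSE]
  if (nrow(s) < 3) stop("not enough positive points in fit window")
  fit <- stats::lm(log(value) ~ time, data = s)
  rate <- -unname(stats::coef(fit)["time"])
  if (!is.finite(rate) || rate <= 0)
    stop("series does not decay over the fit window (rate = ",
         signif(rate, 3), " /s)")
  rate
}

#' Surface-receptor internalization rate ratio
#'
#' Fits a single-exponential decay rate to the surface-receptor observable
#' of each trajectory over `[0, window]` and returns the wild-type to mutant
#' rate ratio. With the published construction (EGF-dependent internalization
#' constants halved in the mutant) this ratio is about 2.
#'
#' @param traj_wt,traj_mut Trajectories of the wild-type and mutant models.
#' @param window Fit window, s (default 100, the reported comparison window).
#' @param obs Observable to fit; defaults to the surface receptor pool.
#' @return Dimensionless rate ratio wt/mutant.
#' @export
internalization_ratio <- function(traj_wt, traj_mut, window = 100,
                                  obs = NULL) {
  if (window > max(traj_wt$times) || window > max(traj_mut$times))
    stop("window exceeds a trajectory horizon")
  get_series <- function(traj) {
    o <- if (is.null(obs)) default_observables(traj$network)[["surface_EGFR"]]
         else obs
    if (is.null(o)) stop("trajectory lacks the surface-receptor observable")
    evaluate_observable(traj, o)
  }
  fit_decay_rate(get_series(traj_wt), window) /
    fit_decay_rate(get_series(traj_mut), window)
}

interp_series <- function(series, times) {
  data.frame(time = times,
             value = stats::approx(series$time, series$value, xout = times,
                                   rule = 2)$y)
}

#' Compare two simulated scenarios observable by observable
#'
#' For each observable the kinetic features of both trajectories are
#' extracted on a shared grid (the coarser trajectory is interpolated onto
#' the finer grid's common range), together with derived ratios — peak shift
#' (A minus B, s), amplitude fold change (A/B) and sustainment difference —
#' and a dominance flag: `"A"` when A >= B for all t, `"B"` for the reverse,
#' `"tie"` when equal within tolerance, else `"crossing"`.
#'
#' @param trajA,trajB Trajectories to compare (A is conventionally the
#'   perturbed state, B the reference).
#' @param observables List of [observable()] objects or character vector of
#'   names drawn from [default_observables()].
#' @param rel_tol Relative tolerance for the dominance/tie classification.
#' @return Data frame of class `egfr_comparison`, one row per observable.
#' @export
compare_scenarios <- function(trajA, trajB,
                              observables = c("ppMEK", "ppERK", "pAkt",
                                              "STAT3n_dimer"),
                              rel_tol = 1e-6) {
  if (is.character(observables)) {
    pool <- default_observables()
    missing <- setdiff(observables, names(pool))
    if (length(missing))
      stop("unknown observable(s): ", paste(missing, collapse = ", "))
    observables <- pool[observables]
  }
  t_shared <- seq(0, min(max(trajA$times), max(trajB$times)),
                  by = min(diff(trajA$times)[1], diff(trajB$times)[1]))
  rows <- lapply(observables, function(o) {
    a <- interp_series(evaluate_observable(trajA, o), t_shared)
    b <- interp_series(evaluate_observable(trajB, o), t_shared)
    fa <- extract_features(a); fb <- extract_features(b)
    scale <- max(fa$peak_amplitude, fb$peak_amplitude, 1e-12)
    d <- a$value - b$value
    dominance <- if (all(abs(d) <= rel_tol * scale)) "tie"
      else if (all(d >= -rel_tol * scale)) "A"
      else if (all(d <= rel_tol * scale)) "B"
      else "crossing"
    data.frame(
      observable = o$name,
      peak_time_A = fa$peak_time, peak_time_B = fb$peak_time,
      peak_amp_A = fa$peak_amplitude, peak_amp_B = fb$peak_amplitude,
      peak_shift = fa$peak_time - fb$peak_time,
      amplitude_fold = if (fb$peak_amplitude > 0)
        fa$peak_amplitude / fb$peak_amplitude else NA_real_,
      sustainment_A = fa$sustainment_index,
      sustainment_B = fb$sustainment_index,
      sustainment_diff = fa$sustainment_index - fb$sustainment_index,
      final_over_peak_A = fa$final_over_peak,
      final_over_peak_B = fb$final_over_peak,
      dominance = dominance,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("egfr_comparison", class(out))
  out
}
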