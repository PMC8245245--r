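#' Steady-state analysis window
#'
#' Drops the ramp transient: keeps samples with `t >= t_start`. Both the
#' force and EMG analyses of a trial use only this window.
#'
#' @param value sampled trace.
#' @param time sample times, s, parallel to `value`.
#' @param t_start window start, s.
#' @return The windowed values.
#' @export
steady_window <- function(value, time, t_start = 2) {
  stopifnot(length(value) == length(time))
  if (max(time) < t_start)
    stop("trace ends before the steady window starts", call. = FALSE)
  value[time >= t_start]
}

#' Coefficient of variation of force
#'
#' Force-steadiness measure: 100 * SD/mean over the (steady-window)
#' samples of a single realization, with the population SD convention.
#'
#' @param x windowed force samples.
#' @return COV in %.
#' @export
force_cov <- function(x) {
  m <- mean(x)
  if (m <= 0) stop("force COV undefined: window mean is not positive",
                   call. = FALSE)
  100 * sqrt(mean((x - m)^2)) / m
}

#' Averaged rectified value of an EMG window
#'
#' @param x windowed EMG samples.
#' @return Mean absolute value.
#' @export
emg_arv <- function(x) {
  if (!length(x)) stop("empty EMG window", call. = FALSE)
  mean(abs(x))
}

#' EMG-force relation across excitation levels
#'
#' Builds the normalized EMG-force curve of one condition: per-level
#' mean force and mean EMG ARV are each divided by their maximum over
#' the levels, then an ordinary least-squares line (EMG on force) is
#' fit. The mid-range residual summary (`mid_residual`: mean residual of
#' the fit at the 30-70% levels) diagnoses the departure from linearity:
#' when force saturates while rate coding still drives the EMG up, the
#' saturated mid-range points sit above the fitted line. `mid_excess`
#' (mean of normalized EMG minus normalized force over the same levels)
#' is reported as a secondary pointwise comparison.
#'
#' @param level excitation levels, % (one entry per level).
#' @param force per-level mean steady force.
#' @param emg per-level mean EMG ARV.
#' @param mid_range levels treated as mid-range, `c(lo, hi)`.
#' @return A list of class `mu_emg_force_curve`: `table` (level,
#'   `force_norm`, `emg_norm`), `slope`, `intercept`, `r_squared`,
#'   `mid_residual`, `mid_excess`.
#' @export
emg_force_curve <- function(level, force, emg, mid_range = c(30, 70)) {
  if (anyDuplicated(level))
    stop("exactly one (force, emg) pair per level is required", call. = FALSE)
  if (length(level) != length(force) || length(level) != length(emg))
    stop("level, force and emg must be parallel", call. = FALSE)
  if (any(is.na(force)) || any(is.na(emg)))
    stop("missing levels in the EMG-force relation", call. = FALSE)
  if (max(force) <= 0 || max(emg) <= 0)
    stop("nonpositive maxima; cannot normalize", call. = FALSE)
  ord <- order(level)
  level <- level[ord]; force <- force[ord]; emg <- emg[ord]
  fn <- force / max(force)
  en <- emg / max(emg)
  fit <- stats::lm(en ~ fn)
  # summary.lm warns on an exactly proportional relation; the R^2 of 1 is
  # the correct report there
  fit_summary <- suppressWarnings(summary(fit))
  mid <- level >= mid_range[1] & level <= mid_range[2]
  out <- list(table = data.frame(level = level, force_norm = fn,
                                 emg_norm = en),
              slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = fit_summary$r.squared,
              mid_residual = mean(stats::resid(fit)[mid]),
              mid_excess = mean(en[mid] - fn[mid]))
  class(out) <- "mu_emg_force_curve"
  out
}

#' @export
print.mu_emg_force_curve <- function(x, ...) {
  cat(sprintf(
    "EMG-force relation over %d levels: slope %.3f, R^2 %.4f, mid-range residual %+.3f\n",
    nrow(x$table), x$slope, x$r_squared, x$mid_residual))
  invisible(x)
}

#' Percent change between two values
#'
#' `100 * (comparison - reference)/reference`; negative values are
#' reductions.
#'
#' @param reference baseline value (> 0).
#' @param comparison value compared against the baseline.
#' @return Percent change.
#' @examples
#' percent_change(5685, 382)  # about -93.3
#' @export
percent_change <- function(reference, comparison) {
  if (any(reference <= 0)) stop("reference must be > 0", call. = FALSE)
  100 * (comparison - reference) / reference
}
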