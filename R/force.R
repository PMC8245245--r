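#' Peak twitch force of a motor unit
#'
#' Exponential twitch-force assignment over an `RP`-fold range:
#' `P_i = exp(log(RP)/n * i)` in arbitrary units, mirroring the
#' recruitment-threshold rule so the last-recruited unit is the
#' strongest.
#'
#' @param i unit index (1-based), vectorized.
#' @param RP peak twitch force range (fold).
#' @param n number of units.
#' @return Peak twitch force(s), arbitrary units.
#' @examples
#' peak_twitch(120, RP = 100, n = 120)  # 100
#' @export
peak_twitch <- function(i, RP, n) {
  if (RP <= 0) stop("RP must be > 0", call. = FALSE)
  if (any(i < 1 | i > n)) stop("unit index out of range [1, n]", call. = FALSE)
  exp(log(RP) / n * i)
}

#' Twitch contraction time
#'
#' Inverse power-law coupling of contraction time to twitch force:
#' `T = T_L * (1/P)^(log(RT)/log(RP))`, so the weakest unit (P = 1) is the
#' slowest (`T_L`) and the strongest (P = RP) is `RT`-fold faster.
#'
#' @param P peak twitch force(s), au.
#' @param T_L longest contraction time, ms.
#' @param RT contraction time range (fold).
#' @param RP twitch force range (fold).
#' @return Contraction time(s), ms.
#' @export
contraction_time <- function(P, T_L, RT, RP) {
  if (any(P <= 0)) stop("P must be > 0", call. = FALSE)
  if (T_L <= 0 || RT <= 1 || RP <= 1)
    stop("require T_L > 0, RT > 1, RP > 1", call. = FALSE)
  T_L * (1 / P)^(log(RT) / log(RP))
}

#' Single-twitch impulse response
#'
#' Second-order critically damped twitch: `f(t) = g P (t/T) exp(1 - t/T)`,
#' peaking at exactly `g * P` when `t = T`.
#'
#' @param t time since the discharge (same unit as `T`), vectorized,
#'   nonnegative.
#' @param g force gain of the discharge (dimensionless).
#' @param P peak twitch force, au.
#' @param T contraction time.
#' @return Force values, au.
#' @export
twitch_response <- function(t, g, P, T) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  g * P * (t / T) * exp(1 - t / T)
}

#' Nonlinear twitch fusion gain
#'
#' Force gain of a discharge as a function of the normalized stimulus
#' rate x = T/ISI. The gain is 1 in the unfused regime (x <= 0.4) and
#' `S(x)/S(0.4)` above it, with `S(x) = (1 - exp(-2 x^3))/x` — continuous
#' at the boundary and maximal near x = 1, i.e. when the interspike
#' interval matches the contraction time. At high rates the per-twitch
#' gain falls so steady force saturates (tetanic fusion).
#'
#' @param T contraction time, ms.
#' @param ISI preceding interspike interval, ms (vectorized; recycled
#'   against `T`).
#' @return Dimensionless gain(s).
#' @examples
#' fusion_gain(90, 90 / 0.2)  # 1, unfused regime
#' fusion_gain(90, 90)        # ~2.88, near the fusion optimum
#' @export
fusion_gain <- function(T, ISI) {
  if (any(T <= 0) || any(ISI <= 0))
    stop("T and ISI must be > 0", call. = FALSE)
  x <- T / ISI
  S <- function(x) (1 - exp(-2 * x^3)) / x
  ifelse(x <= 0.4, 1, S(x) / S(0.4))
}

#' Force trace of one motor unit
#'
#' Superposes one twitch impulse response per discharge on a shared time
#' grid. Each discharge after the first is scaled by the fusion gain of
#' the interspike interval preceding it; the first discharge of the train
#' has gain 1 (a lone twitch equals the unloaded twitch). Each twitch's
#' support is truncated `support` contraction times after its discharge,
#' where the response has decayed below ~1e-11 of its peak.
#'
#' @param spike_times ordered discharge times, s.
#' @param P peak twitch force, au.
#' @param T contraction time, ms.
#' @param t_grid uniform time grid, s.
#' @param support twitch support length in multiples of `T`.
#' @return Numeric force trace, au, aligned with `t_grid`.
#' @export
unit_force <- function(spike_times, P, T, t_grid, support = 30) {
  n <- length(t_grid)
  f <- numeric(n)
  m <- length(spike_times)
  if (m == 0L) return(f)
  if (m > 1L && any(diff(spike_times) <= 0))
    stop("spike times must be strictly increasing", call. = FALSE)
  Ts <- T / 1000  # contraction time in seconds
  dt <- if (n > 1L) t_grid[2L] - t_grid[1L] else Ts
  t0 <- t_grid[1L]
  gains <- if (m > 1L) c(1, fusion_gain(T, 1000 * diff(spike_times))) else 1
  win <- ceiling(support * Ts / dt)
  for (j in seq_len(m)) {
    tj <- spike_times[j]
    i0 <- max(1L, floor((tj - t0) / dt) + 2L)
    if (i0 > n) next
    i1 <- min(n, i0 + win)
    tau <- t_grid[i0:i1] - tj
    f[i0:i1] <- f[i0:i1] + gains[j] * P * (tau / Ts) * exp(1 - tau / Ts)
  }
  f
}

#' Sum per-unit force traces
#'
#' Linear summation of motor unit forces into the whole-muscle force.
#'
#' @param traces list of equal-length numeric traces (or a matrix with
#'   one column per unit) on a shared time grid.
#' @return Numeric total-force trace.
#' @export
total_force <- function(traces) {
  if (is.matrix(traces)) return(rowSums(traces))
  if (!length(traces)) return(numeric(0))
  len <- lengths(traces)
  if (length(unique(len)) != 1L)
    stop("per-unit traces are not on a shared grid", call. = FALSE)
  Reduce(`+`, traces)
}

#' Whole-muscle force from spike trains
#'
#' Convenience wrapper: computes [unit_force()] for every unit of a pool
#' and linearly sums them.
#'
#' @param pool a `mu_pool` data frame.
#' @param trains list of spike-time vectors, one per pool row.
#' @param t_grid uniform time grid, s.
#' @param per_unit if `TRUE`, also return the per-unit trace matrix.
#' @return Numeric total-force trace, or (with `per_unit`) a list with
#'   elements `total` and `units`.
#' @export
pool_force <- function(pool, trains, t_grid, per_unit = FALSE) {
  stopifnot(length(trains) == nrow(pool))
  if (per_unit) {
    m <- vapply(seq_len(nrow(pool)), function(k) {
      unit_force(trains[[k]], pool$P[k], pool$T[k], t_grid)
    }, numeric(length(t_grid)))
    m <- matrix(m, nrow = length(t_grid))
    return(list(total = rowSums(m), units = m))
  }
  f <- numeric(length(t_grid))
  for (k in seq_len(nrow(pool))) {
    f <- f + unit_force(trains[[k]], pool$P[k], pool$T[k], t_grid)
  }
  f
}
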