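#' Motor neuron pool configuration
#'
#' Assembles and validates the scalar parameters defining a motor neuron
#' pool and its firing strategy. Defaults reproduce the classic 120-unit
#' pool: recruitment thresholds spanning a 40% excitation range, minimum
#' firing rate 8 Hz, a common rate-excitation gain of 1 Hz per %
#' excitation, peak firing rates assigned linearly between 25 and 35 Hz
#' ("onion skin": early-recruited small units get the higher rates;
#' "reverse onion skin": mirrored), Gaussian interspike intervals with a
#' 20% coefficient of variation, twitch forces spanning a 100-fold range,
#' contraction times spanning a 3-fold range below 90 ms, and 70,000
#' muscle fibers shared by the pool.
#'
#' @param n_units number of motor units in the pool.
#' @param RR recruitment range: threshold of the last-recruited unit, in
#'   % of maximum excitation.
#' @param MFR minimum firing rate at recruitment, Hz.
#' @param gain firing-rate gain, Hz per % excitation above threshold;
#'   common to all units.
#' @param pfr_scheme `"onion_skin"` or `"reverse_onion_skin"`.
#' @param pfr_lo,pfr_hi peak-firing-rate endpoints, Hz. Under the onion
#'   skin scheme the lowest-threshold unit gets `pfr_hi` and the
#'   highest-threshold unit `pfr_lo`; reversed under the mirrored scheme.
#' @param isi_cv coefficient of variation of the Gaussian interspike
#'   interval (dimensionless).
#' @param RP peak twitch force range (fold) across the pool.
#' @param RT contraction time range (fold) across the pool.
#' @param T_L longest contraction time (slowest, smallest unit), ms.
#' @param total_fibers total muscle fibers innervated by the whole pool.
#' @param ramp_s,hold_s excitation protocol: linear ramp duration and
#'   steady hold duration, seconds.
#' @param dt_force force-trace sampling interval, seconds.
#' @return An object of class `mu_pool_config` (a validated list).
#' @examples
#' cfg <- mu_pool_config()
#' cfg$RR
#' @export
mu_pool_config <- function(n_units = 120L, RR = 40, MFR = 8, gain = 1,
                           pfr_scheme = c("onion_skin", "reverse_onion_skin"),
                           pfr_lo = 25, pfr_hi = 35, isi_cv = 0.2,
                           RP = 100, RT = 3, T_L = 90,
                           total_fibers = 70000L,
                           ramp_s = 2, hold_s = 5, dt_force = 0.001) {
  pfr_scheme <- match.arg(pfr_scheme)
  cfg <- list(n_units = as.integer(n_units), RR = RR, MFR = MFR, gain = gain,
              pfr_scheme = pfr_scheme, pfr_lo = pfr_lo, pfr_hi = pfr_hi,
              isi_cv = isi_cv, RP = RP, RT = RT, T_L = T_L,
              total_fibers = as.integer(total_fibers),
              ramp_s = ramp_s, hold_s = hold_s, dt_force = dt_force)
  class(cfg) <- "mu_pool_config"
  validate_pool_config(cfg)
  cfg
}

validate_pool_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid pool configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_units) || cfg$n_units < 1) fail("n_units", "must be >= 1")
  if (!is.numeric(cfg$RR) || cfg$RR <= 0 || cfg$RR > 100)
    fail("RR", "must lie in (0, 100]")
  if (cfg$MFR <= 0) fail("MFR", "must be > 0")
  if (cfg$gain < 0) fail("gain", "must be >= 0")
  if (cfg$isi_cv < 0) fail("isi_cv", "must be >= 0")
  if (cfg$RP <= 1) fail("RP", "must be > 1")
  if (cfg$RT <= 1) fail("RT", "must be > 1")
  if (cfg$T_L <= 0) fail("T_L", "must be > 0")
  if (cfg$pfr_lo <= cfg$MFR)
    fail("pfr_lo", "must exceed MFR (a unit could never leave its minimum rate)")
  if (cfg$pfr_hi < cfg$pfr_lo) fail("pfr_hi", "must be >= pfr_lo")
  if (cfg$total_fibers < cfg$n_units)
    fail("total_fibers", "must be >= n_units")
  if (cfg$ramp_s <= 0 || cfg$hold_s <= 0)
    fail("ramp_s/hold_s", "must be > 0")
  if (cfg$dt_force <= 0) fail("dt_force", "must be > 0")
  invisible(cfg)
}

#' @export
print.mu_pool_config <- function(x, ...) {
  cat(sprintf("Motor unit pool configuration: %d units, RR %g%%, %s\n",
              x$n_units, x$RR, x$pfr_scheme))
  cat(sprintf("  rates: MFR %g Hz, gain %g Hz/%%, PFR %g-%g Hz, ISI CV %g\n",
              x$MFR, x$gain, x$pfr_lo, x$pfr_hi, x$isi_cv))
  cat(sprintf("  twitch: RP %g-fold, RT %g-fold, T_L %g ms; fibers %d\n",
              x$RP, x$RT, x$T_L, x$total_fibers))
  invisible(x)
}

#' Recruitment threshold of a motor unit
#'
#' Exponential recruitment-threshold assignment: the i-th of n units has
#' threshold `exp(log(RR)/n * i)` (% of maximum excitation), so most of
#' the pool is recruited at low drive and the last unit exactly at `RR`.
#'
#' @param i unit index (1-based), vectorized.
#' @param RR recruitment range, % excitation of the last unit.
#' @param n number of units in the pool.
#' @return Recruitment threshold(s), % of maximum excitation.
#' @examples
#' recruitment_threshold(120, RR = 40, n = 120)  # 40
#' @export
recruitment_threshold <- function(i, RR, n) {
  if (RR <= 0) stop("RR must be > 0", call. = FALSE)
  if (any(i < 1 | i > n)) stop("unit index out of range [1, n]", call. = FALSE)
  exp(log(RR) / n * i)
}

#' Peak firing rate assignment
#'
#' Linear assignment of peak firing rate against recruitment threshold.
#' Under `"onion_skin"` the rate falls from `pfr_hi` at the lowest
#' threshold in `rte_range` to `pfr_lo` at the highest; under
#' `"reverse_onion_skin"` the assignment is mirrored.
#'
#' @param rte recruitment threshold(s), % excitation.
#' @param scheme `"onion_skin"` or `"reverse_onion_skin"`.
#' @param pfr_lo,pfr_hi peak-firing-rate endpoints, Hz.
#' @param rte_range thresholds mapped to the two endpoints, typically
#'   `c(rte_1, RR)` for a concrete pool.
#' @param MFR minimum firing rate, Hz; `pfr_lo` must exceed it.
#' @return Peak firing rate(s), Hz.
#' @export
peak_firing_rate <- function(rte, scheme = c("onion_skin", "reverse_onion_skin"),
                             pfr_lo = 25, pfr_hi = 35,
                             rte_range = c(0, 40), MFR = 8) {
  scheme <- match.arg(scheme)
  if (pfr_lo <= MFR)
    stop("pfr_lo must exceed MFR: a unit could never exceed its minimum rate",
         call. = FALSE)
  if (pfr_hi < pfr_lo) stop("pfr_hi must be >= pfr_lo", call. = FALSE)
  if (pfr_hi == pfr_lo) return(rep(pfr_lo, length(rte)))
  frac <- (rte - rte_range[1]) / (rte_range[2] - rte_range[1])
  if (scheme == "onion_skin") pfr_hi - (pfr_hi - pfr_lo) * frac
  else pfr_lo + (pfr_hi - pfr_lo) * frac
}

#' Instantaneous firing rate of a motor unit
#'
#' Rate coding: zero below the recruitment threshold; above it the rate
#' rises linearly with excitatory drive from `MFR` at threshold, clamped
#' at the unit's peak firing rate.
#'
#' @param E excitatory drive, % of maximum (vectorized).
#' @param rte recruitment threshold, % excitation.
#' @param pfr peak firing rate, Hz.
#' @param MFR minimum firing rate, Hz.
#' @param gain rate gain, Hz per % excitation.
#' @return Firing rate(s), Hz.
#' @examples
#' firing_rate(20, rte = 10, pfr = 35)  # 18 Hz
#' @export
firing_rate <- function(E, rte, pfr, MFR = 8, gain = 1) {
  if (any(E < 0)) stop("excitation must be >= 0", call. = FALSE)
  ifelse(E < rte, 0, pmin(gain * (E - rte) + MFR, pfr))
}

#' Sample a stochastic spike train
#'
#' Renewal sampling of discharge times: each interspike interval is drawn
#' from a Gaussian whose mean is the reciprocal of the firing rate at the
#' previous spike and whose SD is `isi_cv` times that mean; negative draws
#' are resampled (vanishingly rare at CV 0.2). The first discharge is
#' placed at the instant the unit becomes recruited (`t_first`); if
#' `t_first` is `NULL` it is located by scanning `rate_fn` on a 1 ms grid.
#'
#' @param rate_fn function of time (s) returning the firing rate in Hz.
#' @param isi_cv coefficient of variation of the interspike interval.
#' @param t_end trial end time, s.
#' @param t_first time of the first discharge, s, or `NULL` to scan.
#' @return Ordered numeric vector of discharge times in `[0, t_end]`
#'   (empty if the unit is never recruited).
#' @export
sample_spike_train <- function(rate_fn, isi_cv, t_end, t_first = NULL) {
  if (isi_cv < 0) stop("isi_cv must be >= 0", call. = FALSE)
  if (is.null(t_first)) {
    tt <- seq(0, t_end, by = 0.001)
    hit <- which(rate_fn(tt) > 0)
    if (!length(hit)) return(numeric(0))
    t_first <- tt[hit[1]]
  }
  if (is.na(t_first) || t_first > t_end) return(numeric(0))
  # generous preallocation: peak plausible rate * duration
  cap <- max(16L, ceiling((t_end - t_first) * 200) + 4L)
  out <- numeric(cap)
  k <- 0L
  t <- t_first
  while (t <= t_end) {
    k <- k + 1L
    if (k > length(out)) out <- c(out, numeric(cap))
    out[k] <- t
    r <- rate_fn(t)
    if (r <= 0) break
    mu <- 1 / r
    repeat {
      isi <- stats::rnorm(1L, mean = mu, sd = isi_cv * mu)
      if (isi > 0) break
    }
    t <- t + isi
  }
  out[seq_len(k)]
}

#' Build a motor neuron pool
#'
#' Derives the per-unit properties of the pool from its configuration:
#' recruitment thresholds (exponential over `RR`), peak firing rates
#' (linear in threshold per the firing strategy), peak twitch forces
#' (exponential over `RP`), contraction times (power law over `RT`), and
#' innervation numbers (exponential over `RP`, summing exactly to
#' `total_fibers`).
#'
#' @param cfg a [mu_pool_config()] object.
#' @return A data frame of class `mu_pool` with one row per unit and
#'   columns `i`, `rte` (%), `pfr` (Hz), `P` (au), `T` (ms), `n_fibers`;
#'   the configuration is attached as attribute `config`.
#' @examples
#' pool <- build_pool(mu_pool_config())
#' pool[120, ]           # rte 40, P 100
#' sum(pool$n_fibers)    # 70000
#' @export
build_pool <- function(cfg) {
  stopifnot(inherits(cfg, "mu_pool_config"))
  validate_pool_config(cfg)
  i <- seq_len(cfg$n_units)
  rte <- recruitment_threshold(i, cfg$RR, cfg$n_units)
  if (cfg$n_units > 1) {
    pfr <- peak_firing_rate(rte, cfg$pfr_scheme, cfg$pfr_lo, cfg$pfr_hi,
                            rte_range = c(rte[1], cfg$RR), MFR = cfg$MFR)
  } else {
    pfr <- if (cfg$pfr_scheme == "onion_skin") cfg$pfr_lo else cfg$pfr_hi
  }
  P <- peak_twitch(i, cfg$RP, cfg$n_units)
  Tc <- contraction_time(P, cfg$T_L, cfg$RT, cfg$RP)
  nf <- allocate_innervation(cfg$n_units, cfg$total_fibers, cfg$RP)
  pool <- data.frame(i = i, rte = rte, pfr = pfr, P = P, T = Tc,
                     n_fibers = nf)
  if (any(pfr <= cfg$MFR))
    stop("pool construction: some units have PFR <= MFR", call. = FALSE)
  if (cfg$n_units > 1) {
    if (any(diff(rte) <= 0) || any(diff(P) <= 0) || any(diff(Tc) >= 0) ||
        any(diff(nf) < 0))
      stop("pool construction: per-unit monotonicity violated", call. = FALSE)
  }
  attr(pool, "config") <- cfg
  class(pool) <- c("mu_pool", "data.frame")
  pool
}

#' @export
print.mu_pool <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Motor unit pool: %d units (%s), %d fibers\n",
              nrow(x), if (!is.null(cfg)) cfg$pfr_scheme else "?",
              sum(x$n_fibers)))
  cat(sprintf("  rte %.2f-%.2f%%, PFR %.1f-%.1f Hz, P %.2f-%.1f au, T %.1f-%.1f ms\n",
              min(x$rte), max(x$rte), min(x$pfr), max(x$pfr),
              min(x$P), max(x$P), min(x$T), max(x$T)))
  invisible(x)
}
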