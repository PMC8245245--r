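#' Motor unit loss scenario
#'
#' Describes a pattern of motor unit loss: removal restricted to the
#' largest (highest-threshold) units, to the smallest units, or
#' unrestricted (a uniformly random subset), at a given fraction of the
#' pool.
#'
#' @param pattern one of `"none"`, `"largest"`, `"smallest"`,
#'   `"unrestricted"`.
#' @param fraction fraction of units removed, in `[0, 1)`.
#' @param seed optional seed for the unrestricted draw; if `NULL` the
#'   current RNG stream is used (so each trial draws a fresh subset from
#'   its own seeded stream).
#' @return A list of class `mu_loss_scenario`.
#' @export
loss_scenario <- function(pattern = c("none", "largest", "smallest",
                                      "unrestricted"),
                          fraction = 0, seed = NULL) {
  pattern <- match.arg(pattern)
  if (fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)", call. = FALSE)
  if (pattern == "none" && fraction != 0)
    stop("pattern 'none' requires fraction 0", call. = FALSE)
  structure(list(pattern = pattern, fraction = fraction, seed = seed),
            class = "mu_loss_scenario")
}

#' Apply a loss scenario to a pool
#'
#' Removes `round(fraction * n)` units: the highest-indexed ones
#' (`"largest"`), the lowest-indexed ones (`"smallest"`), or a uniformly
#' random subset (`"unrestricted"`). Surviving units keep their original
#' parameters — no reinnervation or other compensation is modeled.
#'
#' @param pool a `mu_pool` data frame.
#' @param scenario a [loss_scenario()] object.
#' @return The reduced pool (same class and attributes; original unit
#'   indices preserved in column `i`).
#' @export
apply_loss <- function(pool, scenario) {
  stopifnot(inherits(scenario, "mu_loss_scenario"))
  n <- nrow(pool)
  k <- round(scenario$fraction * n)
  keep <- switch(scenario$pattern,
    none = seq_len(n),
    largest = seq_len(n - k),
    smallest = if (k == 0) seq_len(n) else seq.int(k + 1L, n),
    unrestricted = {
      if (!is.null(scenario$seed)) set.seed(scenario$seed)
      sort(sample.int(n, n - k))
    })
  out <- pool[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- attr(pool, "config")
  class(out) <- class(pool)
  out
}

#' Excitatory drive protocol
#'
#' Trapezoidal excitation: linear rise from zero over the ramp, then a
#' constant hold at the target level.
#'
#' @param level steady excitation level, % of maximum.
#' @param t time(s), s, within `[0, ramp_s + hold_s]`.
#' @param ramp_s ramp duration, s.
#' @param hold_s hold duration, s.
#' @return Excitation value(s), % of maximum.
#' @examples
#' excitation(100, c(1, 2, 7))  # 50 100 100
#' @export
excitation <- function(level, t, ramp_s = 2, hold_s = 5) {
  if (level <= 0 || level > 100)
    stop("level must lie in (0, 100]", call. = FALSE)
  if (any(t < 0 | t > ramp_s + hold_s))
    stop("t outside the trial window", call. = FALSE)
  ifelse(t < ramp_s, level * t / ramp_s, level)
}

#' Derive a per-trial RNG seed
#'
#' Deterministic substream seed from the master seed and the condition
#' identifiers, so every cell of a condition grid is reproducible in
#' isolation. Plain 31-bit polynomial string hash.
#'
#' @param master master seed (integer).
#' @param strategy,pattern,fraction,level,rep condition identifiers.
#' @return An integer seed in `[0, 2^31)`.
#' @export
trial_seed <- function(master, strategy, pattern, fraction, level, rep) {
  key <- paste(master, strategy, pattern, format(fraction), level, rep,
               sep = "|")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483563
  as.integer(h)
}

#' Simulate one trial
#'
#' Runs the full per-trial pipeline: build the pool, apply the loss
#' scenario, sample a stochastic spike train per surviving unit under
#' the trapezoidal excitation, synthesize the force trace (and
#' optionally the surface EMG), and compute the steady-state metrics
#' over the hold window (the ramp is excluded from analysis). Fully
#' reproducible from `(cfg, scenario, level, seed)`; the EMG synthesis
#' consumes no randomness, so force results are identical with or
#' without it.
#'
#' @param cfg a [mu_pool_config()] object.
#' @param scenario a [loss_scenario()] object.
#' @param level steady excitation level, % of maximum.
#' @param seed RNG seed for this trial.
#' @param with_emg synthesize surface EMG as well (requires `emg` or
#'   builds one on the fly).
#' @param emg optional prebuilt [build_emg_system()] for the intact pool
#'   (reused across trials; templates are indexed by surviving units).
#' @param keep_traces retain the sampled traces in the result.
#' @return A list of class `mu_trial`: condition identifiers, `n_units`
#'   surviving, steady-window `force_mean` (au), `force_cov` (%),
#'   `emg_arv` (or `NA`), and optionally `time`/`force`/`emg` traces.
#' @export
run_trial <- function(cfg, scenario = loss_scenario(), level = 100,
                      seed = 1L, with_emg = FALSE, emg = NULL,
                      keep_traces = FALSE) {
  stopifnot(inherits(cfg, "mu_pool_config"))
  pool <- build_pool(cfg)
  if (with_emg && is.null(emg)) {
    emg <- build_emg_system(pool, seed = trial_seed(seed, "emg", "-", 0, 0, 0))
  }
  t_end <- cfg$ramp_s + cfg$hold_s
  set.seed(seed)
  pool_r <- apply_loss(pool, scenario)
  trains <- lapply(seq_len(nrow(pool_r)), function(k) {
    rte <- pool_r$rte[k]
    if (rte > level) return(numeric(0))
    t_first <- cfg$ramp_s * rte / level
    rate_fn <- function(t) firing_rate(excitation(level, t, cfg$ramp_s,
                                                  cfg$hold_s),
                                       rte, pool_r$pfr[k], cfg$MFR, cfg$gain)
    sample_spike_train(rate_fn, cfg$isi_cv, t_end, t_first)
  })
  nt <- round(t_end / cfg$dt_force)
  t_grid <- (seq_len(nt) - 1L) * cfg$dt_force
  force <- pool_force(pool_r, trains, t_grid)
  sw <- t_grid >= cfg$ramp_s
  res <- list(pattern = scenario$pattern, fraction = scenario$fraction,
              strategy = cfg$pfr_scheme, level = level, seed = seed,
              n_units = nrow(pool_r),
              force_mean = mean(force[sw]),
              force_cov = force_cov(force[sw]),
              emg_arv = NA_real_)
  if (with_emg) {
    x <- compose_emg(trains, emg$templates[pool_r$i], emg$fs, t_end)
    te <- (seq_along(x) - 1L) / emg$fs
    res$emg_arv <- emg_arv(x[te >= cfg$ramp_s])
    if (keep_traces) res$emg <- x
  }
  if (keep_traces) {
    res$time <- t_grid
    res$force <- force
  }
  class(res) <- "mu_trial"
  res
}

#' @export
print.mu_trial <- function(x, ...) {
  cat(sprintf(
    "Trial: %s loss %.0f%%, %s, level %g%% (seed %d)\n",
    x$pattern, 100 * x$fraction, x$strategy, x$level, x$seed))
  cat(sprintf("  %d units; steady force %.1f au, COV %.2f%%",
              x$n_units, x$force_mean, x$force_cov))
  if (!is.na(x$emg_arv)) cat(sprintf(", EMG ARV %.4g", x$emg_arv))
  cat("\n")
  invisible(x)
}

#' Run a factorial condition grid
#'
#' Simulates every cell of strategies x loss scenarios x excitation
#' levels x repetitions, each from its own [trial_seed()]-derived
#' substream. Unrestricted-loss cells redraw their random subset per
#' repetition. A cell that errors is recorded as `NA` with a warning
#' rather than aborting the grid.
#'
#' @param cfg a [mu_pool_config()] object (its `pfr_scheme` is
#'   overridden per strategy).
#' @param strategies character vector of firing strategies.
#' @param patterns character vector of loss patterns; `"none"` is
#'   simulated at fraction 0 regardless of `fractions`.
#' @param fractions numeric vector of loss fractions for the non-trivial
#'   patterns.
#' @param levels excitation levels, % of maximum.
#' @param reps repetitions per cell.
#' @param master_seed master seed for the whole grid.
#' @param with_emg synthesize EMG (one anatomy per strategy-independent
#'   pool, built once).
#' @param geometry geometry for the EMG system, if `with_emg`.
#' @param fs EMG sampling rate, Hz.
#' @return Data frame of class `mu_experiment`, one row per trial, with
#'   the condition identifiers, seeds, and steady-state metrics.
#' @export
run_grid <- function(cfg, strategies = c("onion_skin", "reverse_onion_skin"),
                     patterns = c("none", "largest", "smallest",
                                  "unrestricted"),
                     fractions = c(0.2, 0.4, 0.6),
                     levels = seq(10, 100, by = 10), reps = 10,
                     master_seed = 1L, with_emg = FALSE,
                     geometry = muscle_geometry(), fs = 4000) {
  scen <- list()
  for (p in patterns) {
    if (p == "none") scen[[length(scen) + 1L]] <- list(pattern = p, fraction = 0)
    else for (f in fractions) scen[[length(scen) + 1L]] <- list(pattern = p,
                                                               fraction = f)
  }
  emg <- NULL
  if (with_emg) {
    pool0 <- build_pool(cfg)
    emg <- build_emg_system(pool0, geometry, fs,
                            seed = trial_seed(master_seed, "emg", "-", 0, 0, 0))
  }
  rows <- list()
  for (s in strategies) {
    cfg_s <- cfg
    cfg_s$pfr_scheme <- s
    for (sc in scen) {
      scenario <- loss_scenario(sc$pattern, sc$fraction)
      for (lv in levels) {
        for (r in seq_len(reps)) {
          sd <- trial_seed(master_seed, s, sc$pattern, sc$fraction, lv, r)
          tr <- tryCatch(
            run_trial(cfg_s, scenario, lv, sd, with_emg = with_emg, emg = emg),
            error = function(e) {
              warning(sprintf("trial failed (%s/%s/%g/%g/rep %d): %s",
                              s, sc$pattern, sc$fraction, lv, r,
                              conditionMessage(e)))
              NULL
            })
          rows[[length(rows) + 1L]] <- data.frame(
            strategy = s, pattern = sc$pattern, fraction = sc$fraction,
            level = lv, rep = r, seed = sd,
            n_units = if (is.null(tr)) NA_integer_ else tr$n_units,
            force_mean = if (is.null(tr)) NA_real_ else tr$force_mean,
            force_cov = if (is.null(tr)) NA_real_ else tr$force_cov,
            emg_arv = if (is.null(tr)) NA_real_ else tr$emg_arv)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- cfg
  attr(out, "master_seed") <- master_seed
  class(out) <- c("mu_experiment", "data.frame")
  out
}

#' Average repetitions within each condition
#'
#' Collapses an experiment table to one row per (strategy, pattern,
#' fraction, level), averaging the steady-state metrics over
#' repetitions.
#'
#' @param grid a [run_grid()] result (or compatible data frame).
#' @return Data frame of per-condition means with columns `force_mean`,
#'   `force_cov`, `emg_arv`, and `n_reps`.
#' @export
condition_means <- function(grid) {
  key <- interaction(grid$strategy, grid$pattern, grid$fraction, grid$level,
                     drop = TRUE)
  agg <- function(v) tapply(v, key, mean)
  first <- function(v) tapply(v, key, `[`, 1L)
  out <- data.frame(strategy = as.character(first(grid$strategy)),
                    pattern = as.character(first(grid$pattern)),
                    fraction = as.numeric(first(grid$fraction)),
                    level = as.numeric(first(grid$level)),
                    n_reps = as.integer(tapply(grid$rep, key, length)),
                    force_mean = as.numeric(agg(grid$force_mean)),
                    force_cov = as.numeric(agg(grid$force_cov)),
                    emg_arv = as.numeric(agg(grid$emg_arv)))
  out <- out[order(out$strategy, out$pattern, out$fraction, out$level), ]
  rownames(out) <- NULL
  out
}
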