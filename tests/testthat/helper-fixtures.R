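# Shared fixtures and a memo cache so expensive simulations run once per
# test session and are reused across test files.

default_cfg <- function(...) mu_pool_config(...)

small_cfg <- function(...) {
  mu_pool_config(n_units = 12L, total_fibers = 700L, ...)
}

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# Mean steady force / COV over `reps` repetitions of one condition at one
# excitation level, seeded per repetition from the shared master seed.
condition_stats <- function(cfg, pattern, fraction, level = 100, reps = 10,
                            master = 20260927) {
  fm <- cv <- numeric(reps)
  for (r in seq_len(reps)) {
    tr <- run_trial(cfg, loss_scenario(pattern, fraction), level,
                    seed = trial_seed(master, cfg$pfr_scheme, pattern,
                                      fraction, level, r))
    fm[r] <- tr$force_mean
    cv[r] <- tr$force_cov
  }
  list(force = mean(fm), cov = mean(cv))
}

# The full-scale capacity/variability simulation behind the headline
# loss-pattern comparisons (10 reps at 100% excitation).
capacity_sim <- function() {
  cached("capacity", {
    out <- list()
    for (s in c("onion_skin", "reverse_onion_skin")) {
      cfg <- mu_pool_config(pfr_scheme = s)
      out[[s]] <- list(
        intact = condition_stats(cfg, "none", 0),
        largest = condition_stats(cfg, "largest", 0.6),
        smallest = condition_stats(cfg, "smallest", 0.6),
        unrestricted = condition_stats(cfg, "unrestricted", 0.6))
    }
    out
  })
}

# EMG-scale simulation: 120 units over 7,000 fibers (same per-unit
# proportions), EMG-force curves over the 10-level protocol, 3 reps.
emg_sim <- function() {
  cached("emg", {
    cfg <- mu_pool_config(total_fibers = 7000L)
    pool <- build_pool(cfg)
    emg <- build_emg_system(pool, seed = 424242L)
    conds <- list(none = 0, smallest = 0.6, unrestricted = 0.6,
                  largest = 0.6)
    reps <- 3L
    out <- list()
    for (p in names(conds)) {
      f <- a <- cv <- numeric(10)
      for (k in 1:10) {
        lv <- 10 * k
        fm <- am <- cm <- 0
        for (r in seq_len(reps)) {
          tr <- run_trial(cfg, loss_scenario(p, conds[[p]]), lv,
                          seed = trial_seed(77, "onion_skin", p, conds[[p]],
                                            lv, r),
                          with_emg = TRUE, emg = emg)
          fm <- fm + tr$force_mean
          am <- am + tr$emg_arv
          cm <- cm + tr$force_cov
        }
        f[k] <- fm / reps; a[k] <- am / reps; cv[k] <- cm / reps
      }
      out[[p]] <- list(level = seq(10, 100, 10), force = f, arv = a,
                       cov = cv,
                       curve = emg_force_curve(seq(10, 100, 10), f, a))
    }
    out
  })
}
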