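test_that("twitch amplitude and timing follow the exponential assignments", {
  expect_equal(peak_twitch(120, RP = 100, n = 120), 100)
  expect_equal(peak_twitch(60, RP = 100, n = 120), 10, tolerance = 1e-12)
  expect_equal(peak_twitch(1:5, RP = 1, n = 120), rep(1, 5))
  expect_equal(contraction_time(1, T_L = 90, RT = 3, RP = 100), 90)
  expect_equal(contraction_time(100, 90, 3, 100), 30)
  expect_equal(contraction_time(10, 90, 3, 100), 51.9615242270663,
               tolerance = 1e-12)
  P <- peak_twitch(1:120, 100, 120)
  expect_true(all(diff(contraction_time(P, 90, 3, 100)) < 0))
  expect_error(contraction_time(-1, 90, 3, 100), "P")
})

test_that("the twitch impulse response peaks at g*P at t = T", {
  expect_equal(twitch_response(90, g = 1, P = 100, T = 90), 100)
  expect_equal(twitch_response(0, 1, 100, 90), 0)
  expect_equal(twitch_response(180, 1, 100, 90), 73.5758882342885,
               tolerance = 1e-12)
  tt <- seq(0, 900, by = 0.01)
  expect_equal(tt[which.max(twitch_response(tt, 2.5, 40, 63))], 63,
               tolerance = 1e-3)
  expect_lt(twitch_response(30 * 90, 1, 100, 90), 1e-8)
})

test_that("fusion gain is 1 below the 0.4 boundary, continuous, peaked near 1", {
  expect_equal(fusion_gain(90, 90 / 0.2), 1)   # T/ISI = 0.2
  expect_equal(fusion_gain(90, 90 / 0.4), 1)   # boundary
  expect_equal(fusion_gain(90, 90 / (0.4 + 1e-9)), 1, tolerance = 1e-6)
  expect_equal(fusion_gain(90, 90), 2.87869841234853, tolerance = 1e-12)
  x <- seq(0.41, 3, by = 0.001)
  g <- fusion_gain(x * 50, 50)
  xmax <- x[which.max(g)]
  expect_gt(xmax, 0.95)
  expect_lt(xmax, 1.10)
  expect_error(fusion_gain(-1, 10), "T and ISI")
  expect_error(fusion_gain(90, 0), "T and ISI")
})

test_that("steady unit force saturates beyond the fusion rate", {
  # mean steady force is nondecreasing in rate, then plateaus: the mean
  # force at rate f is proportional to f * gain(T*f), which approaches a
  # constant once T/ISI passes ~2
  T <- 60
  t_grid <- (0:20000) * 1e-3
  mean_force <- function(rate_hz) {
    spikes <- seq(0, 20, by = 1 / rate_hz)
    f <- unit_force(spikes, P = 10, T = T, t_grid = t_grid)
    mean(f[t_grid >= 5 & t_grid <= 18])
  }
  rates <- c(5, 10, 15, 2000 / T, 2500 / T, 3000 / T)
  m <- vapply(rates, mean_force, numeric(1))
  expect_true(all(diff(m[1:4]) > 0))
  expect_equal(m[5] / m[4], 1, tolerance = 0.01)
  expect_equal(m[6] / m[4], 1, tolerance = 0.01)
})

test_that("unit force matches a direct term-by-term twitch summation", {
  # independent oracle: dense evaluation of the twitch formula per
  # discharge, gains recomputed from first principles, no truncation
  spikes <- c(0.10, 0.18, 0.25, 0.29, 0.38)
  P <- 7.3; T <- 55
  t_grid <- (0:1500) * 1e-3
  S <- function(x) (1 - exp(-2 * x^3)) / x
  oracle <- numeric(length(t_grid))
  for (j in seq_along(spikes)) {
    if (j == 1) g <- 1 else {
      x <- (T / 1000) / (spikes[j] - spikes[j - 1])
      g <- if (x <= 0.4) 1 else S(x) / S(0.4)
    }
    tau <- (t_grid - spikes[j]) * 1000  # ms
    act <- tau > 0
    oracle[act] <- oracle[act] +
      g * P * (tau[act] / T) * exp(1 - tau[act] / T)
  }
  impl <- unit_force(spikes, P, T, t_grid)
  expect_lt(max(abs(impl - oracle)) / max(abs(oracle)), 1e-9)
})

test_that("lone and well-separated twitches keep unit gain", {
  t_grid <- (0:3000) * 1e-3
  one <- unit_force(0.5, P = 12, T = 80, t_grid = t_grid)
  expect_equal(max(one), 12, tolerance = 1e-4)
  expect_equal(t_grid[which.max(one)], 0.5 + 0.080, tolerance = 2e-3)
  expect_true(all(one[t_grid <= 0.5] == 0))
  # two spikes far beyond T/0.4 apart: both twitches unscaled
  two <- unit_force(c(0.3, 1.8), P = 12, T = 80, t_grid = t_grid)
  expect_equal(max(two[t_grid < 1]), max(two[t_grid > 1.8]),
               tolerance = 1e-3)
})

test_that("a train at the fusion optimum more than doubles the twitch peak", {
  T <- 60
  t_grid <- (0:5000) * 1e-3
  spikes <- seq(0.2, 4.5, by = T / 1000)  # ISI = T
  f <- unit_force(spikes, P = 10, T = T, t_grid = t_grid)
  expect_gt(max(f[t_grid > 2 & t_grid < 4]), 2 * 10)
})

test_that("total force is the linear sum of unit traces", {
  t_grid <- (0:1000) * 1e-3
  a <- unit_force(c(0.1, 0.2), 5, 60, t_grid)
  b <- unit_force(c(0.15, 0.4), 20, 40, t_grid)
  expect_equal(total_force(list(a, b)), a + b)
  expect_equal(total_force(list(a)), a)
  expect_identical(total_force(list()), numeric(0))
  expect_equal(total_force(list(a, a)), 2 * a)
  expect_error(total_force(list(a, b[-1])), "shared grid")
  pool <- make_fixture_pool()
  trains <- lapply(seq_len(nrow(pool)), function(k) c(0.1, 0.2 + 0.01 * k))
  pf <- pool_force(pool, trains, t_grid, per_unit = TRUE)
  expect_equal(pf$total, rowSums(pf$units))
  expect_equal(pool_force(pool, trains, t_grid), pf$total)
})

test_that("unordered spikes are rejected", {
  expect_error(unit_force(c(0.2, 0.1), 5, 60, (0:100) * 1e-3),
               "increasing")
})
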