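test_that("innervation numbers follow the exponential rule and sum exactly", {
  nf <- allocate_innervation(120, 70000, 100)
  expect_equal(nf[1], 28L)
  expect_equal(sum(nf), 70000L)
  expect_true(all(diff(nf) >= 0))
  # degenerate uniform split
  expect_equal(allocate_innervation(2, 30, 1), c(15L, 15L))
  # largest-remainder rounding preserves the total at any scale
  for (tot in c(700, 7000, 12345)) {
    expect_equal(sum(allocate_innervation(120, tot, 100)), tot)
  }
  expect_error(allocate_innervation(120, 100, 100), "infeasible")
})

test_that("territories are sized by density and stay inside the muscle", {
  geom <- muscle_geometry()
  counts <- c(28, 500, 2728)
  set.seed(11)
  placed <- place_territories(counts, geom)
  expect_equal(placed$territories$radius[3], 6.58919330991807,
               tolerance = 1e-10)
  expect_equal(placed$territories$radius[1], 0.667558117812455,
               tolerance = 1e-10)
  # realized density within the territory disc
  dens <- counts / (pi * placed$territories$radius^2)
  expect_true(all(abs(dens[counts >= 100] - 20) <= 1))
  # every fiber inside its territory and inside the muscle cross-section
  for (k in seq_along(counts)) {
    fib <- placed$fibers[placed$fibers$unit == k, ]
    d <- sqrt((fib$x - placed$territories$cx[k])^2 +
              (fib$y - placed$territories$cy[k])^2)
    expect_true(all(d <= placed$territories$radius[k] + 1e-9))
    expect_true(all(sqrt(fib$x^2 + fib$y^2) <= geom$muscle_radius + 1e-9))
  }
  expect_equal(nrow(placed$fibers), sum(counts))
  # a territory that cannot fit is clipped with a warning
  expect_warning(place_territories(c(20 * pi * 100), geom), "clipped")
})

test_that("conduction velocity is linear in fiber diameter", {
  expect_equal(conduction_velocity(55), 3.7)
  expect_equal(conduction_velocity(25), 2.2)
  expect_equal(conduction_velocity(c(40, 40)), rep(conduction_velocity(40), 2))
  d <- seq(40, 70, by = 5)
  expect_true(all(diff(conduction_velocity(d)) > 0))
  expect_error(conduction_velocity(0), "diameter")
})

test_that("fiber action potentials behave like a zero-net-charge source", {
  fib <- list(x = 0, y = 2, velocity = 4, iz = 0, z_left = -50, z_right = 50)
  # multipole decay: during full propagation the tripole has zero net
  # charge, so doubling a large electrode distance loses more than half
  # the amplitude (faster than a monopole). Onset and extinction phases
  # carry a transient net charge and are excluded.
  k_mid <- round(20 / fib$velocity * 4000 / 1000) + 1L  # lead pole ~20 mm out
  v1 <- fiber_action_potential(fib, electrode = c(0, 60, 0))
  v2 <- fiber_action_potential(fib, electrode = c(0, 120, 0))
  expect_lt(abs(v2[k_mid]), abs(v1[k_mid]) / 2)
  # linearity: doubled pole charges double the waveform
  va <- fiber_action_potential(fib, c(0, 10.5, 25))
  vb <- fiber_action_potential(fib, c(0, 10.5, 25),
                               tripole = tripole_params(q_scale = 2))
  expect_equal(vb, 2 * va, tolerance = 1e-12)
  # axial mirror symmetry for a centered innervation zone: reflecting the
  # electrode through the IZ plane leaves the waveform unchanged
  vp <- fiber_action_potential(fib, c(0, 10.5, 10))
  vm <- fiber_action_potential(fib, c(0, 10.5, -10))
  expect_equal(vp, vm, tolerance = 1e-12)
  # zero potential at the discharge instant (poles coincide and cancel)
  expect_equal(va[1], 0, tolerance = 1e-12)
  expect_error(fiber_action_potential(fib, c(0, 2, 0)), "axis|inside")
})

test_that("MUAP templates sum fibers and shrink with distance", {
  geom <- muscle_geometry()
  fib1 <- data.frame(unit = 1, x = 0, y = 4, diameter = 55,
                     velocity = 3.7, iz = 0, z_left = -50, z_right = 50)
  tp <- muap_template(fib1, geom$electrode)
  expect_equal(tp$waveform,
               fiber_action_potential(as.list(fib1[1, ]), geom$electrode))
  # peak-to-peak falls monotonically as the unit moves deeper
  depths <- c(6, 3, 0, -3, -6)
  p2p <- vapply(depths, function(y0) {
    f <- transform(fib1, y = y0)
    diff(range(muap_template(f, geom$electrode)$waveform))
  }, numeric(1))
  expect_true(all(diff(p2p) < 0))
  # a large unit outweighs a small one at the same depth distribution
  set.seed(3)
  mk <- function(n) data.frame(unit = 1, x = runif(n, -1, 1),
                               y = runif(n, 2, 4), diameter = 55,
                               velocity = 3.7, iz = 0,
                               z_left = -50, z_right = 50)
  big <- muap_template(mk(200), geom$electrode)
  small <- muap_template(mk(10), geom$electrode)
  expect_gt(diff(range(big$waveform)), diff(range(small$waveform)))
})

test_that("EMG composition is a sparse, linear, shift-equivariant sum", {
  w <- list(waveform = c(0, 1, -2, 1, 0.5), fs = 4000)
  v <- list(waveform = c(1, -1), fs = 4000)
  # one discharge: the template delayed to the spike sample
  x <- compose_emg(list(0.01), list(w), fs = 4000, t_end = 0.05)
  expect_equal(which(x != 0) - 1L, 40L + which(w$waveform != 0) - 1L)
  expect_equal(x[41:45], w$waveform)
  # coincident discharges of two units superpose pointwise
  x2 <- compose_emg(list(0.01, 0.01), list(w, v), 4000, 0.05)
  xw <- compose_emg(list(0.01, numeric(0)), list(w, v), 4000, 0.05)
  xv <- compose_emg(list(numeric(0), 0.01), list(w, v), 4000, 0.05)
  expect_equal(x2, xw + xv)
  # no discharges: silence
  expect_equal(compose_emg(list(numeric(0)), list(w), 4000, 0.05),
               numeric(200))
  # amplitude linearity
  w3 <- list(waveform = 3 * w$waveform, fs = 4000)
  expect_equal(compose_emg(list(c(0.01, 0.02)), list(w3), 4000, 0.05),
               3 * compose_emg(list(c(0.01, 0.02)), list(w), 4000, 0.05))
  expect_warning(compose_emg(list(0.2), list(w), 4000, 0.05), "beyond")
})

test_that("expected ARV does not fall when discharges are added", {
  w <- list(waveform = c(0, 0.3, 1, -1.5, 0.8, -0.2), fs = 4000)
  arv_at_rate <- function(rate, seed) {
    set.seed(seed)
    tr <- sample_spike_train(function(t) rep(rate, length(t)), 0.2, 5,
                             t_first = 0.01)
    emg_arv(compose_emg(list(tr), list(w), 4000, 5))
  }
  lo <- vapply(1:20, function(s) arv_at_rate(10, s), numeric(1))
  hi <- vapply(1:20, function(s) arv_at_rate(20, 1000 + s), numeric(1))
  se <- sqrt(var(lo) / 20 + var(hi) / 20)
  expect_gt(mean(hi), mean(lo) - 3 * se)
})
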