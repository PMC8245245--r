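#' Muscle and detection geometry
#'
#' Geometry of the cylindrical muscle model and the monopolar surface
#' electrode. The muscle axis runs along z; the cross-section is the
#' disc x^2 + y^2 <= muscle_radius^2 (mm); skin lies at
#' y = muscle_radius + fat_thickness. Fibers run parallel to the axis,
#' a semilength to each side of an innervation zone scattered about
#' z = 0. The electrode sits on the skin over the muscle midline,
#' midway between the innervation zone and one tendon by default.
#'
#' @param muscle_radius muscle cross-section radius, mm.
#' @param fat_thickness combined fat + skin thickness, mm.
#' @param fiber_density fibers per mm^2 within a unit territory.
#' @param fiber_semilength fiber length each side of the innervation
#'   zone, mm.
#' @param iz_scatter innervation zones uniform in `[-iz_scatter,
#'   iz_scatter]` mm about z = 0.
#' @param electrode electrode position `c(x, y, z)` in mm, or `NULL` for
#'   the default placement.
#' @return An object of class `mu_geometry` (a validated list).
#' @export
muscle_geometry <- function(muscle_radius = 8, fat_thickness = 2.5,
                            fiber_density = 20, fiber_semilength = 50,
                            iz_scatter = 2.5, electrode = NULL) {
  if (is.null(electrode)) {
    electrode <- c(x = 0, y = muscle_radius + fat_thickness,
                   z = fiber_semilength / 2)
  }
  g <- list(muscle_radius = muscle_radius, fat_thickness = fat_thickness,
            fiber_density = fiber_density,
            fiber_semilength = fiber_semilength, iz_scatter = iz_scatter,
            electrode = electrode)
  with(g, {
    if (muscle_radius <= 0 || fat_thickness <= 0 || fiber_density <= 0 ||
        fiber_semilength <= 0 || iz_scatter < 0)
      stop("invalid geometry: all lengths/densities must be positive",
           call. = FALSE)
  })
  if (sqrt(electrode[1]^2 + electrode[2]^2) < muscle_radius)
    stop("invalid geometry: field 'electrode' lies inside the muscle",
         call. = FALSE)
  class(g) <- "mu_geometry"
  g
}

#' Distribute muscle fibers over motor units
#'
#' Innervation numbers follow the same exponential rule as the twitch
#' force: raw counts proportional to `exp(log(fold_range)/n * i)`, scaled
#' to the fiber total and rounded by the largest-remainder method so the
#' integer counts sum exactly to `total_fibers`.
#'
#' @param n_units number of motor units.
#' @param total_fibers total fiber count to distribute.
#' @param fold_range innervation-number range (fold) across the pool.
#' @return Integer vector of per-unit fiber counts (nondecreasing).
#' @examples
#' nf <- allocate_innervation(120, 70000, 100)
#' nf[1]     # 28
#' sum(nf)   # 70000
#' @export
allocate_innervation <- function(n_units, total_fibers, fold_range) {
  if (total_fibers < n_units)
    stop("infeasible: total_fibers < n_units", call. = FALSE)
  if (fold_range < 1) stop("fold_range must be >= 1", call. = FALSE)
  i <- seq_len(n_units)
  raw <- exp(log(fold_range) / n_units * i)
  x <- raw * (total_fibers / sum(raw))
  base <- floor(x)
  deficit <- as.integer(round(total_fibers - sum(base)))
  counts <- as.integer(base)
  if (deficit > 0L) {
    # bump the largest remainders; ties go to the larger unit
    ord <- order(x - base, i, decreasing = TRUE)
    counts[ord[seq_len(deficit)]] <- counts[ord[seq_len(deficit)]] + 1L
  }
  counts
}

#' Place motor unit territories and fibers in the muscle cross-section
#'
#' Each unit occupies a circular territory sized so its fiber density is
#' the configured value (`radius = sqrt(count/(density*pi))`); centers
#' are sampled uniformly over positions keeping the territory inside the
#' muscle cross-section, and fibers are scattered uniformly within the
#' territory disc. A territory that cannot fit is clipped to the muscle
#' radius with a warning (its density then exceeds the nominal value).
#'
#' Uses the current RNG stream; seed beforehand for reproducibility.
#'
#' @param counts per-unit fiber counts.
#' @param geometry a [muscle_geometry()] object.
#' @return List with `territories` (data frame: `unit`, `cx`, `cy`,
#'   `radius`) and `fibers` (data frame: `unit`, `x`, `y`).
#' @export
place_territories <- function(counts, geometry) {
  stopifnot(inherits(geometry, "mu_geometry"))
  Rm <- geometry$muscle_radius
  n <- length(counts)
  radius <- sqrt(counts / (geometry$fiber_density * pi))
  clip <- radius > Rm
  if (any(clip)) {
    warning(sprintf("%d territory radii exceed the muscle radius; clipped",
                    sum(clip)))
    radius[clip] <- Rm
  }
  cx <- cy <- numeric(n)
  fx <- fy <- numeric(sum(counts))
  fu <- integer(sum(counts))
  pos <- 0L
  for (k in seq_len(n)) {
    free <- Rm - radius[k]
    if (free > 0) {
      r <- free * sqrt(stats::runif(1))
      th <- 2 * pi * stats::runif(1)
      cx[k] <- r * cos(th); cy[k] <- r * sin(th)
    } else {
      cx[k] <- 0; cy[k] <- 0
    }
    m <- counts[k]
    if (m > 0L) {
      rr <- radius[k] * sqrt(stats::runif(m))
      tt <- 2 * pi * stats::runif(m)
      idx <- pos + seq_len(m)
      fx[idx] <- cx[k] + rr * cos(tt)
      fy[idx] <- cy[k] + rr * sin(tt)
      fu[idx] <- k
      pos <- pos + m
    }
  }
  list(territories = data.frame(unit = seq_len(n), cx = cx, cy = cy,
                                radius = radius),
       fibers = data.frame(unit = fu, x = fx, y = fy))
}

#' Muscle fiber conduction velocity
#'
#' Linear velocity-diameter coupling: `v = v0 + slope * (d - d0)` m/s.
#'
#' @param diameter fiber diameter, micrometers (vectorized).
#' @param v0 velocity at the reference diameter, m/s.
#' @param slope m/s per micrometer.
#' @param d0 reference diameter, micrometers.
#' @return Conduction velocity(ies), m/s.
#' @export
conduction_velocity <- function(diameter, v0 = 2.2, slope = 0.05, d0 = 25) {
  if (any(diameter <= 0)) stop("diameter must be > 0", call. = FALSE)
  v0 + slope * (diameter - d0)
}

#' Current-tripole source parameters
#'
#' Parameters of the propagating current-tripole description of the
#' intracellular action potential: pole offsets `b1`, `b2` mm behind the
#' leading pole, charges `(+q, -(q + q'), +q')` with zero net charge and
#' a 90:10 leading/terminal split by default, a linear charge ramp of
#' `ramp` mm at the fiber-tendon ending, and a single effective volume
#' conductor conductivity `sigma` (arbitrary units; EMG amplitudes in
#' this model are relative).
#'
#' @param b1,b2 trailing pole offsets, mm.
#' @param q_terminal terminal-to-leading charge ratio.
#' @param ramp extinction ramp length at the fiber end, mm.
#' @param sigma effective conductivity (sets the amplitude scale).
#' @param q_scale overall charge scale.
#' @return A list of class `mu_tripole`.
#' @export
tripole_params <- function(b1 = 2, b2 = 4, q_terminal = 1 / 9, ramp = 2,
                           sigma = 1, q_scale = 1) {
  stopifnot(b2 > b1, b1 > 0, q_terminal > 0, ramp > 0, sigma > 0)
  p <- list(b1 = b1, b2 = b2, q_terminal = q_terminal, ramp = ramp,
            sigma = sigma, q_scale = q_scale)
  class(p) <- "mu_tripole"
  p
}

#' Single-fiber action potential at a surface electrode
#'
#' Two current tripoles originate at the fiber's innervation zone, travel
#' in opposite axial directions at the fiber's conduction velocity, and
#' extinguish at the fiber-tendon endings (each pole's charge ramping
#' linearly to zero over the final `ramp` mm of travel). Trailing poles
#' emerge from the innervation zone sequentially, so the six poles
#' coincide (and cancel) at the discharge instant. The monopolar
#' potential is the sum of `charge / (4 pi sigma r)` over the poles in a
#' homogeneous isotropic volume conductor; the fat layer enters as pure
#' distance.
#'
#' @param fiber list or one-row data frame with `x`, `y` (mm),
#'   `velocity` (m/s), `iz`, `z_left`, `z_right` (mm axial positions of
#'   the innervation zone and the two fiber ends).
#' @param electrode electrode position `c(x, y, z)`, mm.
#' @param fs sampling rate, Hz (>= 2000).
#' @param tripole a [tripole_params()] object.
#' @return Numeric waveform sampled at `fs`, starting at the discharge
#'   and ending when both tripoles are extinct.
#' @export
fiber_action_potential <- function(fiber, electrode, fs = 4000,
                                   tripole = tripole_params()) {
  if (fs < 2000) stop("fs must be >= 2 kHz", call. = FALSE)
  if (fiber$velocity <= 0) stop("fiber velocity must be > 0", call. = FALSE)
  if (!(fiber$z_left < fiber$iz && fiber$iz < fiber$z_right))
    stop("innervation zone must lie strictly between the fiber ends",
         call. = FALSE)
  rad2 <- (fiber$x - electrode[1])^2 + (fiber$y - electrode[2])^2
  if (rad2 == 0) stop("electrode lies on the fiber axis", call. = FALSE)
  v <- fiber$velocity              # m/s == mm/ms
  dr <- fiber$z_right - fiber$iz   # travel distance, right tripole
  dl <- fiber$iz - fiber$z_left
  t_end <- (max(dr, dl) + tripole$b2) / v        # ms
  L <- ceiling(t_end * fs / 1000) + 1L
  t_ms <- (seq_len(L) - 1L) * 1000 / fs
  offs <- c(0, tripole$b1, tripole$b2)
  ch <- tripole$q_scale * c(1, -(1 + tripole$q_terminal), tripole$q_terminal)
  amp <- 1 / (4 * pi * tripole$sigma)
  ez <- electrode[3]
  V <- numeric(L)
  for (k in 1:3) {
    s <- pmax(0, v * t_ms - offs[k])  # distance traveled past the IZ
    # rightward tripole
    wr <- pmin(1, pmax(0, (dr - s) / tripole$ramp))
    zr <- fiber$iz + pmin(s, dr)
    V <- V + ch[k] * amp * wr / sqrt(rad2 + (zr - ez)^2)
    # leftward tripole
    wl <- pmin(1, pmax(0, (dl - s) / tripole$ramp))
    zl <- fiber$iz - pmin(s, dl)
    V <- V + ch[k] * amp * wl / sqrt(rad2 + (zl - ez)^2)
  }
  V
}

#' Motor unit action potential template
#'
#' The MUAP is the sum of the action potentials of the unit's fibers,
#' zero-padded to a common length.
#'
#' @param fibers data frame of the unit's fibers (columns as in
#'   [fiber_action_potential()]).
#' @param electrode electrode position `c(x, y, z)`, mm.
#' @param fs sampling rate, Hz.
#' @param tripole a [tripole_params()] object.
#' @return List of class `mu_muap` with `waveform` and `fs`.
#' @export
muap_template <- function(fibers, electrode, fs = 4000,
                          tripole = tripole_params()) {
  stopifnot(nrow(fibers) >= 1)
  waves <- lapply(seq_len(nrow(fibers)), function(r) {
    fiber_action_potential(as.list(fibers[r, ]), electrode, fs, tripole)
  })
  L <- max(lengths(waves))
  w <- numeric(L)
  for (wv in waves) w[seq_along(wv)] <- w[seq_along(wv)] + wv
  structure(list(waveform = w, fs = fs), class = "mu_muap")
}

#' Build the full surface-EMG system for a pool
#'
#' Places territories and fibers, draws fiber diameters (Gaussian, equal
#' mean for all units, truncated at 3 SD) and innervation-zone offsets,
#' derives conduction velocities, and computes one MUAP template per
#' motor unit. Loss scenarios can later index into the returned template
#' list, so this is built once per pool.
#'
#' @param pool a `mu_pool` data frame.
#' @param geometry a [muscle_geometry()] object.
#' @param fs EMG sampling rate, Hz.
#' @param seed RNG seed for the anatomical draws.
#' @param diameter_mean,diameter_sd fiber diameter distribution,
#'   micrometers.
#' @param tripole a [tripole_params()] object.
#' @return List of class `mu_emg_system` with `templates` (per-unit
#'   [muap_template()]s), `fibers`, `territories`, `geometry`, `fs`,
#'   `seed`.
#' @export
build_emg_system <- function(pool, geometry = muscle_geometry(), fs = 4000,
                             seed = 1L, diameter_mean = 55, diameter_sd = 5,
                             tripole = tripole_params()) {
  set.seed(seed)
  placed <- place_territories(pool$n_fibers, geometry)
  fib <- placed$fibers
  nf <- nrow(fib)
  d <- stats::rnorm(nf, diameter_mean, diameter_sd)
  lo <- diameter_mean - 3 * diameter_sd
  hi <- diameter_mean + 3 * diameter_sd
  while (any(bad <- d < lo | d > hi)) {
    d[bad] <- stats::rnorm(sum(bad), diameter_mean, diameter_sd)
  }
  fib$diameter <- d
  fib$velocity <- conduction_velocity(d)
  fib$iz <- stats::runif(nf, -geometry$iz_scatter, geometry$iz_scatter)
  fib$z_left <- fib$iz - geometry$fiber_semilength
  fib$z_right <- fib$iz + geometry$fiber_semilength
  templates <- lapply(seq_len(nrow(pool)), function(u) {
    muap_template(fib[fib$unit == u, , drop = FALSE], geometry$electrode,
                  fs, tripole)
  })
  structure(list(templates = templates, fibers = fib,
                 territories = placed$territories, geometry = geometry,
                 fs = fs, seed = seed),
            class = "mu_emg_system")
}

#' Compose the surface EMG of a trial
#'
#' Sparse superposition of MUAP templates: every discharge of unit j
#' adds that unit's template at the discharge time, x(t) = sum_j sum_k
#' a_j(t - T_j(k)). Template tails extending past `t_end` are truncated;
#' discharges after `t_end` are dropped with a warning.
#'
#' @param trains list of spike-time vectors (s), parallel to `templates`.
#' @param templates list of [muap_template()]s.
#' @param fs sampling rate, Hz (must match the templates).
#' @param t_end trial duration, s.
#' @return Numeric EMG trace of `round(t_end * fs)` samples on the grid
#'   `t_k = (k - 1)/fs`.
#' @export
compose_emg <- function(trains, templates, fs, t_end) {
  stopifnot(length(trains) == length(templates))
  n <- round(t_end * fs)
  maxL <- if (length(templates)) max(vapply(templates, function(tp)
    length(tp$waveform), integer(1))) else 0L
  x <- numeric(n + maxL)
  for (j in seq_along(trains)) {
    w <- templates[[j]]$waveform
    Lw <- length(w)
    for (tk in trains[[j]]) {
      if (tk > t_end) {
        warning("discharge beyond t_end dropped")
        next
      }
      i0 <- floor(tk * fs) + 1L
      x[i0:(i0 + Lw - 1L)] <- x[i0:(i0 + Lw - 1L)] + w
    }
  }
  x[seq_len(n)]
}
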