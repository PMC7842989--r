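#' Nasal spray configuration
#'
#' Droplet size statistics follow a Rosin-Rammler distribution fitted to a
#' commercial metered nasal spray: mass fraction retained above diameter
#' `d` is `exp(-(d / mean_um)^spread)`.
#'
#' @param mean_um Rosin-Rammler characteristic (mean) diameter (default 78).
#' @param spread Spread parameter `n` (default 2.7).
#' @param d_min_um,d_max_um Truncation range of released diameters
#'   (defaults 1 and 150).
#' @param n_bins Number of diameter bins (default 150).
#' @param streams_per_bin Droplet streams released per bin (default 200).
#' @param density_kg_m3 Carrier droplet density (default 1000).
#' @param speed_m_s Initial spray velocity (default 10).
#' @param cone_angle_deg Spray cone angle (default 50).
#' @param insertion_angle_deg Nozzle insertion angle from horizontal
#'   (default 30).
#' @return An object of class `mc_spray_config`.
#' @export
spray_config <- function(mean_um = 78, spread = 2.7, d_min_um = 1,
                         d_max_um = 150, n_bins = 150, streams_per_bin = 200,
                         density_kg_m3 = 1000, speed_m_s = 10,
                         cone_angle_deg = 50, insertion_angle_deg = 30) {
  if (!(d_min_um < mean_um && mean_um < d_max_um)) {
    stop("require d_min < mean diameter < d_max", call. = FALSE)
  }
  if (spread <= 0) stop("spread parameter must be positive", call. = FALSE)
  if (n_bins < 1 || streams_per_bin < 0) {
    stop("need at least 1 bin and a non-negative stream count", call. = FALSE)
  }
  if (density_kg_m3 <= 0) stop("droplet density must be positive", call. = FALSE)
  structure(
    list(mean_um = mean_um, spread = spread, d_min_um = d_min_um,
         d_max_um = d_max_um, n_bins = as.integer(n_bins),
         streams_per_bin = as.integer(streams_per_bin),
         density_kg_m3 = density_kg_m3, speed_m_s = speed_m_s,
         cone_angle_deg = cone_angle_deg,
         insertion_angle_deg = insertion_angle_deg),
    class = "mc_spray_config"
  )
}

#' Rosin-Rammler retained mass fraction
#'
#' Mass fraction of the spray carried by droplets with diameter above `d`.
#'
#' @param d_um Diameter in micrometres (vectorised).
#' @param mean_um Characteristic diameter.
#' @param spread Spread parameter.
#' @return `exp(-(d/mean)^spread)`.
#' @export
#' @examples
#' rosin_rammler_retained(78, 78, 2.7)   # exp(-1)
rosin_rammler_retained <- function(d_um, mean_um = 78, spread = 2.7) {
  if (any(!is.finite(d_um)) || any(d_um < 0) || mean_um <= 0 || spread <= 0) {
    stop("diameters and Rosin-Rammler parameters must be positive",
         call. = FALSE)
  }
  exp(-(d_um / mean_um)^spread)
}

#' Build a binned droplet population
#'
#' Bins span the truncated diameter range; each bin's mass fraction is the
#' Rosin-Rammler mass retained between its edges, renormalised over the
#' range. Number weights follow from mass over per-droplet mass
#' `rho * pi d^3 / 6`.
#'
#' @param config An [spray_config()].
#' @return An object of class `mc_population`: a data.frame with one row
#'   per bin (`bin`, `d_um`, `d_lo_um`, `d_hi_um`, `mass_fraction`,
#'   `number_weight`, `droplet_mass_kg`, `streams`).
#' @export
build_droplet_population <- function(config = spray_config()) {
  edges <- seq(config$d_min_um, config$d_max_um, length.out = config$n_bins + 1L)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  ret <- function(d) rosin_rammler_retained(d, config$mean_um, config$spread)
  mass <- ret(lo) - ret(hi)
  mass <- mass / (ret(config$d_min_um) - ret(config$d_max_um))
  mid <- (lo + hi) / 2
  droplet_mass <- config$density_kg_m3 * pi * (mid * 1e-6)^3 / 6
  number <- mass / droplet_mass
  number <- number / sum(number)
  out <- data.frame(
    bin = seq_along(mid), d_um = mid, d_lo_um = lo, d_hi_um = hi,
    mass_fraction = mass, number_weight = number,
    droplet_mass_kg = droplet_mass, streams = config$streams_per_bin
  )
  attr(out, "config") <- config
  class(out) <- c("mc_population", "data.frame")
  out
}

#' Write a droplet population to CSV
#'
#' @param population An `mc_population`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(population, path) {
  df <- data.frame(
    bin_diameter_um = population$d_um,
    mass_fraction = population$mass_fraction,
    number_weight = population$number_weight,
    droplet_mass_kg = population$droplet_mass_kg
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Air properties and carrier flow for particle kinetics
#'
#' @param viscosity_Pa_s Air dynamic viscosity (default 1.789e-5).
#' @param density_kg_m3 Air density (default 1.225).
#' @param velocity A function `function(x, t)` returning the prescribed air
#'   velocity (m/s, length-3) at position `x` (m), or a length-3 constant.
#' @return An object of class `mc_air`.
#' @export
air_properties <- function(viscosity_Pa_s = 1.789e-5, density_kg_m3 = 1.225,
                           velocity = c(0, 0, 0)) {
  if (viscosity_Pa_s <= 0 || density_kg_m3 <= 0) {
    stop("air properties must be positive", call. = FALSE)
  }
  vel_fun <- if (is.function(velocity)) velocity else {
    v <- rep_len(as.numeric(velocity), 3L)
    function(x, t) v
  }
  structure(
    list(viscosity_Pa_s = viscosity_Pa_s, density_kg_m3 = density_kg_m3,
         velocity = vel_fun),
    class = "mc_air"
  )
}

#' Lagrangian particle state
#'
#' @param position_m,velocity_m_s Length-3 numeric vectors.
#' @param d_um Droplet diameter in micrometres.
#' @param density_kg_m3 Droplet density.
#' @return An object of class `mc_particle_state`.
#' @export
particle_state <- function(position_m = c(0, 0, 0), velocity_m_s = c(0, 0, 0),
                           d_um = 78, density_kg_m3 = 1000) {
  if (d_um <= 0 || density_kg_m3 <= 0) {
    stop("diameter and density must be positive", call. = FALSE)
  }
  structure(
    list(position_m = rep_len(as.numeric(position_m), 3L),
         velocity_m_s = rep_len(as.numeric(velocity_m_s), 3L),
         d_um = d_um, density_kg_m3 = density_kg_m3),
    class = "mc_particle_state"
  )
}

# Morsi-Alexander piecewise drag constants (a1, a2, a3) by Re band
morsi_alexander_table <- function() {
  data.frame(
    re_lo = c(0, 0.1, 1, 10, 100, 1000, 5000, 10000),
    re_hi = c(0.1, 1, 10, 100, 1000, 5000, 10000, Inf),
    a1 = c(0, 3.690, 1.222, 0.6167, 0.3644, 0.357, 0.46, 0.5191),
    a2 = c(24, 22.73, 29.1667, 46.50, 98.33, 148.62, -490.546, -1662.5),
    a3 = c(0, 0.0903, -3.8889, -116.67, -2778, -47500, 578700, 5416700)
  )
}

#' Sphere drag coefficient (Morsi-Alexander)
#'
#' `C_D = a1 + a2/Re + a3/Re^2` with empirical constants tabulated per
#' Reynolds-number band.
#'
#' @param re_p Particle Reynolds number (vectorised, positive).
#' @return Drag coefficient.
#' @export
#' @examples
#' drag_coefficient(0.05)   # Stokes band: 24 / Re = 480
drag_coefficient <- function(re_p) {
  if (any(!is.finite(re_p)) || any(re_p <= 0)) {
    stop("particle Reynolds number must be positive", call. = FALSE)
  }
  tab <- morsi_alexander_table()
  band <- findInterval(re_p, tab$re_lo, rightmost.closed = FALSE)
  tab$a1[band] + tab$a2[band] / re_p + tab$a3[band] / re_p^2
}

#' Particle Reynolds number
#'
#' `Re_p = rho d_p |u_air - u| / mu`. The density is the carrier gas
#' density by default; `density = "particle"` uses the droplet density
#' instead (see the package vignette for why both forms are provided).
#'
#' @param state An [particle_state()].
#' @param air An [air_properties()].
#' @param t Time (passed to the air velocity function).
#' @param density `"gas"` (default) or `"particle"`.
#' @return Particle Reynolds number.
#' @export
particle_reynolds <- function(state, air, t = 0, density = c("gas", "particle")) {
  density <- match.arg(density)
  rho <- if (density == "gas") air$density_kg_m3 else state$density_kg_m3
  slip <- sqrt(sum((air$velocity(state$position_m, t) - state$velocity_m_s)^2))
  rho * state$d_um * 1e-6 * slip / air$viscosity_Pa_s
}

#' Stokes relaxation time of a droplet
#'
#' `tau_p = rho_p d_p^2 / (18 mu)`, the exponential time constant of
#' velocity equilibration in the Stokes drag regime.
#'
#' @param d_um Droplet diameter in micrometres.
#' @param density_kg_m3 Droplet density.
#' @param viscosity_Pa_s Carrier gas viscosity.
#' @return Relaxation time in seconds.
#' @export
#' @examples
#' relaxation_time(10)    # ~3.1e-4 s
relaxation_time <- function(d_um, density_kg_m3 = 1000,
                            viscosity_Pa_s = 1.789e-5) {
  if (any(d_um <= 0) || density_kg_m3 <= 0 || viscosity_Pa_s <= 0) {
    stop("inputs must be positive", call. = FALSE)
  }
  density_kg_m3 * (d_um * 1e-6)^2 / (18 * viscosity_Pa_s)
}

# drag + gravity acceleration (m/s^2) for the particle ODE
particle_acceleration <- function(pos, vel, state, air, t, gravity,
                                  reynolds_density) {
  u_air <- air$velocity(pos, t)
  slip <- u_air - vel
  slip_mag <- sqrt(sum(slip^2))
  tau <- relaxation_time(state$d_um, state$density_kg_m3, air$viscosity_Pa_s)
  acc <- if (slip_mag > 0) {
    re <- {
      rho <- if (reynolds_density == "gas") air$density_kg_m3 else state$density_kg_m3
      rho * state$d_um * 1e-6 * slip_mag / air$viscosity_Pa_s
    }
    corr <- drag_coefficient(re) * re / 24
    corr / tau * slip
  } else {
    c(0, 0, 0)
  }
  if (gravity) acc <- acc + c(0, 0, -9.81)
  acc
}

#' Advance a Lagrangian particle through a prescribed air flow
#'
#' Integrates `du/dt = f_D + f_G` with the nonlinear Stokes-drag correction
#' `f_D = (C_D Re_p / 24) (u_air - u) / tau_p` using a fixed-step classical
#' fourth-order Runge-Kutta scheme. Steps larger than a fraction of the
#' relaxation time are sub-divided automatically so the drag stiffness is
#' resolved.
#'
#' @param state An [particle_state()].
#' @param air An [air_properties()].
#' @param dt Time step in seconds.
#' @param gravity Include gravity (`FALSE` by default).
#' @param t0 Start time.
#' @param substeps Number of RK4 substeps; `NULL` picks
#'   `ceiling(dt / (tau_p / 20))` capped at 1e6.
#' @param reynolds_density `"gas"` or `"particle"` (see
#'   [particle_reynolds()]).
#' @return The advanced `mc_particle_state`.
#' @export
advance_particle <- function(state, air, dt, gravity = FALSE, t0 = 0,
                             substeps = NULL,
                             reynolds_density = c("gas", "particle")) {
  reynolds_density <- match.arg(reynolds_density)
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  tau <- relaxation_time(state$d_um, state$density_kg_m3, air$viscosity_Pa_s)
  if (is.null(substeps)) {
    substeps <- min(max(1, ceiling(dt / (tau / 20))), 1e6)
  }
  hdt <- dt / substeps
  pos <- state$position_m; vel <- state$velocity_m_s
  t <- t0
  f <- function(p, v, tt) {
    list(dp = v,
         dv = particle_acceleration(p, v, state, air, tt, gravity,
                                    reynolds_density))
  }
  for (i in seq_len(substeps)) {
    k1 <- f(pos, vel, t)
    k2 <- f(pos + hdt / 2 * k1$dp, vel + hdt / 2 * k1$dv, t + hdt / 2)
    k3 <- f(pos + hdt / 2 * k2$dp, vel + hdt / 2 * k2$dv, t + hdt / 2)
    k4 <- f(pos + hdt * k3$dp, vel + hdt * k3$dv, t + hdt)
    pos <- pos + hdt / 6 * (k1$dp + 2 * k2$dp + 2 * k3$dp + k4$dp)
    vel <- vel + hdt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
    if (any(!is.finite(vel))) {
      stop("particle velocity overflow: reduce dt", call. = FALSE)
    }
    t <- t + hdt
  }
  particle_state(pos, vel, state$d_um, state$density_kg_m3)
}
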