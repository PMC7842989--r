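#' Physical constants for solute diffusion in the mucus gel
#'
#' Bundles the constants used by the diffusivity chain: the Stokes-Einstein
#' aqueous diffusivity and its Obstruction-Scaling reduction inside the mucin
#' fibre network.
#'
#' @param fibre_radius_nm Mucin fibre radius \eqn{r_f} in nm (default 3.5).
#' @param mesh_spacing_nm Effective mesh fibre spacing \eqn{r_g} of the mucin
#'   network in nm (default 50).
#' @param temperature_K Absolute temperature in K. Default 310.15 K (body
#'   temperature).
#' @param water_viscosity_Pa_s Dynamic viscosity of water \eqn{\mu_0} in Pa s
#'   at `temperature_K`. Default 6.913e-4 (water at 37 C).
#' @return An object of class `mc_diffusion_constants`.
#' @export
#' @examples
#' diffusion_constants()
diffusion_constants <- function(fibre_radius_nm = 3.5,
                                mesh_spacing_nm = 50,
                                temperature_K = 310.15,
                                water_viscosity_Pa_s = 6.913e-4) {
  vals <- c(fibre_radius_nm, mesh_spacing_nm, temperature_K, water_viscosity_Pa_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all diffusion constants must be positive and finite", call. = FALSE)
  }
  structure(
    list(
      fibre_radius_nm = fibre_radius_nm,
      mesh_spacing_nm = mesh_spacing_nm,
      boltzmann_J_per_K = 1.380649e-23,
      temperature_K = temperature_K,
      water_viscosity_Pa_s = water_viscosity_Pa_s
    ),
    class = "mc_diffusion_constants"
  )
}

#' @export
print.mc_diffusion_constants <- function(x, ...) {
  cat("Mucus diffusion constants\n")
  cat(sprintf("  mucin fibre radius r_f : %.2f nm\n", x$fibre_radius_nm))
  cat(sprintf("  mesh fibre spacing r_g : %.2f nm\n", x$mesh_spacing_nm))
  cat(sprintf("  temperature T          : %.2f K\n", x$temperature_K))
  cat(sprintf("  water viscosity mu_0   : %.4g Pa s\n", x$water_viscosity_Pa_s))
  invisible(x)
}

#' Mucus gel layer description
#'
#' The mucus blanket is modelled as an upper viscous gel layer of constant
#' thickness sitting on a watery periciliary layer. Solute diffuses through
#' the gel in 1-D with a reflective (zero-flux) boundary at the air-facing
#' top and a fully absorbing boundary at the bottom, where the periciliary
#' layer and epithelium take up solute instantaneously.
#'
#' @param thickness_um Gel layer thickness \eqn{h_g} in micrometres
#'   (default 10).
#' @param periciliary_um Periciliary layer thickness in micrometres, carried
#'   as metadata only (default 5).
#' @return An object of class `mc_gel_layer`.
#' @export
gel_layer <- function(thickness_um = 10, periciliary_um = 5) {
  if (!is.finite(thickness_um) || thickness_um <= 0) {
    stop("gel thickness must be positive", call. = FALSE)
  }
  structure(
    list(
      thickness_um = thickness_um,
      thickness_m = thickness_um * 1e-6,
      periciliary_um = periciliary_um
    ),
    class = "mc_gel_layer"
  )
}

#' Drug solute description
#'
#' @param radius_nm Effective hydrodynamic (macromolecular) radius of the
#'   dissolved drug solute, in nm.
#' @param mass_fraction Drug solute mass fraction \eqn{\alpha} of the carrier
#'   droplet, assumed constant across droplets (default 1).
#' @param concentration_kg_m3 Solute concentration used when converting
#'   absorption fractions to an absolute dose (default 1).
#' @return An object of class `mc_solute`.
#' @export
solute_spec <- function(radius_nm, mass_fraction = 1, concentration_kg_m3 = 1) {
  if (!is.finite(radius_nm) || radius_nm <= 0) {
    stop("solute radius must be positive", call. = FALSE)
  }
  if (!is.finite(mass_fraction) || mass_fraction <= 0 || mass_fraction > 1) {
    stop("mass fraction must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      radius_nm = radius_nm,
      mass_fraction = mass_fraction,
      concentration_kg_m3 = concentration_kg_m3
    ),
    class = "mc_solute"
  )
}

#' Aqueous diffusivity from the Stokes-Einstein relation
#'
#' \eqn{D_0 = k_B T / (6 \pi \mu_0 r_s)} for a solute of hydrodynamic radius
#' \eqn{r_s} in water.
#'
#' @param radius_nm Solute radius in nm (vectorised).
#' @param constants A [diffusion_constants()] object.
#' @return Diffusivity in m^2/s.
#' @export
#' @examples
#' diffusivity_water(90)    # ~3.65e-12 m^2/s at body temperature
diffusivity_water <- function(radius_nm, constants = diffusion_constants()) {
  if (any(!is.finite(radius_nm)) || any(radius_nm <= 0)) {
    stop("solute radius must be positive", call. = FALSE)
  }
  r_m <- radius_nm * 1e-9
  constants$boltzmann_J_per_K * constants$temperature_K /
    (6 * pi * constants$water_viscosity_Pa_s * r_m)
}

#' Gel diffusivity from the Obstruction-Scaling model
#'
#' Reduces the aqueous diffusivity by the mucin fibre network obstruction
#' factor \eqn{\exp[-(\pi/4)((r_s + r_f)/(r_g + r_f))^2]}.
#'
#' @param radius_nm Solute radius in nm (vectorised).
#' @param D0 Aqueous diffusivity in m^2/s. Computed from `radius_nm` via
#'   [diffusivity_water()] when omitted.
#' @param constants A [diffusion_constants()] object.
#' @return Gel diffusivity \eqn{D_g} in m^2/s.
#' @export
#' @examples
#' diffusivity_mucus(50) / diffusivity_water(50)   # obstruction factor
diffusivity_mucus <- function(radius_nm, D0 = NULL,
                              constants = diffusion_constants()) {
  if (any(!is.finite(radius_nm)) || any(radius_nm <= 0)) {
    stop("solute radius must be positive", call. = FALSE)
  }
  if (is.null(D0)) D0 <- diffusivity_water(radius_nm, constants)
  ratio <- (radius_nm + constants$fibre_radius_nm) /
    (constants$mesh_spacing_nm + constants$fibre_radius_nm)
  D0 * exp(-(pi / 4) * ratio^2)
}

# series decay rate kappa = pi^2 D / (4 h^2)  [1/s]
series_rate <- function(D_g, gel) {
  pi^2 * D_g / (4 * gel$thickness_m^2)
}

#' Absorbed fraction of a deposited solute dose
#'
#' Fraction of a unit solute dose absorbed by the epithelium a time `t`
#' after deposition, for 1-D diffusion through the gel layer with a
#' reflective top boundary and a fully absorbing bottom boundary and the
#' whole dose initially at the top surface:
#' \deqn{A(t) = 1 - \frac{4}{\pi} \sum_{n \ge 0}
#'   e^{-(2n+1)^2 \pi^2 D_g t / (4 h_g^2)} \frac{(-1)^n}{2n+1}.}
#' The alternating series is truncated when the magnitude of the next term
#' falls below `tol`; `A(0)` is returned as exactly 0 and values are clamped
#' to `[0, 1]`.
#'
#' @param t Time after deposition in seconds (vectorised).
#' @param D_g Gel diffusivity in m^2/s.
#' @param gel A [gel_layer()] object.
#' @param tol Truncation tolerance on the alternating-series remainder.
#' @param max_terms Cap on retained series terms; exceeding it is an error.
#' @return Absorbed fraction in `[0, 1]`, same length as `t`.
#' @export
#' @examples
#' D <- diffusivity_mucus(90)
#' absorption_fraction(500, D)   # ~0.98
absorption_fraction <- function(t, D_g, gel = gel_layer(), tol = 1e-12,
                                max_terms = 10000) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("time must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(D_g) || D_g <= 0) stop("D_g must be positive", call. = FALSE)
  kappa <- series_rate(D_g, gel)
  A <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    tp <- t[pos]
    s <- numeric(length(tp))
    n <- 0
    repeat {
      k <- 2 * n + 1
      term <- exp(-k^2 * kappa * tp) / k
      s <- s + if (n %% 2 == 0) term else -term
      # alternating series with strictly decreasing terms: remainder bound
      k_next <- 2 * (n + 1) + 1
      bound <- max(exp(-k_next^2 * kappa * tp) / k_next)
      if (bound < tol) break
      n <- n + 1
      if (n >= max_terms) {
        stop(sprintf(
          "absorption series did not meet tol %.3g within %d terms (smallest t = %.3g s)",
          tol, max_terms, min(tp)
        ), call. = FALSE)
      }
    }
    A[pos] <- 1 - (4 / pi) * s
  }
  pmin(pmax(A, 0), 1)
}

#' Normalised solute concentration profile in the gel layer
#'
#' Series solution of the 1-D diffusion equation in the gel layer with a
#' reflective boundary at `x = 0` (top) and an absorbing boundary at
#' `x = h_g` (bottom), with the dose initially concentrated at the top
#' surface. The profile integrates to `1 - absorption_fraction(t, ...)`.
#'
#' @param x Depth into the gel layer in metres, `0 <= x <= h_g` (vectorised).
#' @param t Time after deposition in seconds (scalar, `t >= 0`). At `t = 0`
#'   the initial condition is a Dirac mass at `x = 0`, represented as `Inf`
#'   at `x = 0` and 0 elsewhere.
#' @param D_g Gel diffusivity in m^2/s.
#' @param gel A [gel_layer()] object.
#' @param tol Series truncation tolerance.
#' @param max_terms Cap on retained series terms.
#' @return Concentration in 1/m, same length as `x`.
#' @export
concentration_profile <- function(x, t, D_g, gel = gel_layer(), tol = 1e-12,
                                  max_terms = 10000) {
  h <- gel$thickness_m
  if (any(!is.finite(x)) || any(x < 0) || any(x > h * (1 + 1e-12))) {
    stop("x must lie inside the gel layer [0, h_g]", call. = FALSE)
  }
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("t must be a single non-negative time", call. = FALSE)
  }
  if (t == 0) {
    return(ifelse(x == 0, Inf, 0))
  }
  kappa <- series_rate(D_g, gel)
  s <- numeric(length(x))
  n <- 0
  repeat {
    k <- 2 * n + 1
    amp <- exp(-k^2 * kappa * t)
    s <- s + amp * cos(k * pi * x / (2 * h))
    amp_next <- exp(-(k + 2)^2 * kappa * t)
    # tail bound: geometric in the exponent gaps
    tail_bound <- amp_next / max(1 - exp(-8 * (n + 2) * kappa * t), 1e-300)
    if ((2 / h) * tail_bound < tol) break
    n <- n + 1
    if (n >= max_terms) {
      stop(sprintf(
        "concentration series did not meet tol %.3g within %d terms (t = %.3g s)",
        tol, max_terms, t
      ), call. = FALSE)
    }
  }
  (2 / h) * s
}
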