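#' Per-particle drug absorption bookkeeping
#'
#' Every deposited droplet runs a single absorption clock from its
#' deposition time: diffusion through the gel layer does not pause while
#' the carrier rides the mucus. For each passage interval
#' `(region, t_in, t_out)` the solute increment
#' `alpha * m * [A(t_out) - A(t_in)]` is credited to that region if it
#' absorbs; increments accrued while the carrier sits on the
#' non-absorbing vestibule are discarded (lost). On clearance through the
#' outlet the unabsorbed remainder `alpha * m * [1 - A(t_clear)]` is
#' booked as cleared-unabsorbed; a particle still in transit at the
#' horizon books its remainder as in-mucus residual. The four buckets sum
#' to `alpha * m` identically.
#'
#' @param clearance An `mc_clearance` (or a compatible list with
#'   `passages` and `status`).
#' @param solute An [solute_spec()].
#' @param gel An [gel_layer()].
#' @param constants An [diffusion_constants()].
#' @param regions Region flags, defaults to [region_specs()].
#' @return An object of class `mc_absorption`: list with `particle`
#'   (per-particle buckets), `by_region` (absorbed mass per absorbing
#'   region), `per_particle_region`, `D_g`, and the inputs' metadata.
#' @export
absorb_particles <- function(clearance, solute, gel = gel_layer(),
                             constants = diffusion_constants(),
                             regions = region_specs()) {
  pas <- clearance$passages
  st <- clearance$status
  if (is.null(pas) || nrow(pas) == 0) {
    pas <- data.frame(particle_id = integer(0), region = character(0),
                      t_in_s = numeric(0), t_out_s = numeric(0))
  }
  check_contiguous_passages(pas)
  D_g <- diffusivity_mucus(solute$radius_nm, constants = constants)
  alpha_m <- solute$mass_fraction * st$mass_kg

  A_in <- absorption_fraction(pas$t_in_s, D_g, gel)
  A_out <- absorption_fraction(pas$t_out_s, D_g, gel)
  inc <- (A_out - A_in) *
    alpha_m[match(pas$particle_id, st$particle_id)]
  absorbing <- regions$absorbing[match(pas$region, regions$region)]
  if (anyNA(absorbing)) stop("passage through unknown region", call. = FALSE)

  ppr <- data.frame(particle_id = pas$particle_id, region = pas$region,
                    absorbed_kg = ifelse(absorbing, inc, 0),
                    lost_kg = ifelse(absorbing, 0, inc))
  absorbed <- rowsum(ppr$absorbed_kg, ppr$particle_id)
  lost <- rowsum(ppr$lost_kg, ppr$particle_id)
  ord <- match(as.character(st$particle_id), rownames(absorbed))
  absorbed_p <- ifelse(is.na(ord), 0, absorbed[ord])
  lost_p <- ifelse(is.na(ord), 0, lost[ord])

  # terminal remainder
  t_end <- tapply(pas$t_out_s, pas$particle_id, max)
  t_end <- t_end[as.character(st$particle_id)]
  A_end <- ifelse(is.na(t_end), 0,
                  absorption_fraction(ifelse(is.na(t_end), 0, t_end), D_g, gel))
  remainder <- alpha_m * (1 - A_end)
  cleared_kg <- ifelse(st$status == "cleared", remainder, 0)
  residual_kg <- ifelse(st$status == "cleared", 0, remainder)

  particle <- data.frame(
    particle_id = st$particle_id,
    d_um = st$d_um,
    mass_kg = st$mass_kg,
    alpha_mass_kg = alpha_m,
    deposit_region = st$deposit_region,
    absorbed_kg = absorbed_p,
    lost_kg = lost_p,
    cleared_kg = cleared_kg,
    residual_kg = residual_kg,
    fraction_absorbed = ifelse(alpha_m > 0, absorbed_p / alpha_m, 0)
  )
  bal <- abs(particle$absorbed_kg + particle$lost_kg + particle$cleared_kg +
               particle$residual_kg - alpha_m)
  rel <- bal / pmax(alpha_m, 1e-300)
  if (any(rel > 1e-10)) {
    stop("solute mass conservation violated (max rel err ",
         signif(max(rel), 3), ")", call. = FALSE)
  }
  reg_abs <- rowsum(ppr$absorbed_kg, ppr$region)
  by_region <- data.frame(region = rownames(reg_abs),
                          absorbed_kg = as.numeric(reg_abs))
  structure(
    list(particle = particle,
         by_region = by_region[by_region$region %in%
                                 regions$region[regions$absorbing], ],
         per_particle_region = ppr,
         D_g = D_g, solute = solute, gel = gel, constants = constants),
    class = "mc_absorption"
  )
}

check_contiguous_passages <- function(pas) {
  if (nrow(pas) < 2) return(invisible(TRUE))
  ord <- order(pas$particle_id, pas$t_in_s)
  p <- pas[ord, ]
  same <- p$particle_id[-1] == p$particle_id[-nrow(p)]
  gap <- abs(p$t_in_s[-1] - p$t_out_s[-nrow(p)])
  if (any(same & gap > 1e-6)) {
    stop("passage intervals are not contiguous", call. = FALSE)
  }
  first <- !duplicated(p$particle_id)
  if (any(p$t_in_s[first] != 0)) {
    stop("first passage interval must start at deposition (t = 0)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Absorption of a single particle from its passage record
#'
#' Convenience wrapper around [absorb_particles()] for one particle.
#'
#' @param passage Data.frame with `region`, `t_in_s`, `t_out_s` rows in
#'   order.
#' @param mass_kg Carrier droplet mass.
#' @param status `"cleared"` or `"in_transit"`.
#' @param solute,gel,constants,regions As in [absorb_particles()].
#' @return One-row per-particle bucket table (see [absorb_particles()]).
#' @export
particle_absorption <- function(passage, mass_kg, status = "cleared",
                                solute = solute_spec(10),
                                gel = gel_layer(),
                                constants = diffusion_constants(),
                                regions = region_specs()) {
  cl <- list(
    passages = data.frame(particle_id = 1L, region = passage$region,
                          t_in_s = passage$t_in_s, t_out_s = passage$t_out_s),
    status = data.frame(particle_id = 1L, status = status,
                        clear_time_s = max(passage$t_out_s),
                        deposit_region = passage$region[1],
                        mass_kg = mass_kg, d_um = NA_real_)
  )
  absorb_particles(cl, solute, gel, constants, regions)$particle
}

#' @export
print.mc_absorption <- function(x, ...) {
  s <- regional_absorption_summary(x)
  cat(sprintf("Drug absorption, solute radius %.1f nm (D_g = %.3g m^2/s)\n",
              x$solute$radius_nm, x$D_g))
  cat(sprintf("  total absorbed : %.2f%%\n", s$total_percent))
  cat(sprintf("  lost in vestibule %.2f%%, cleared unabsorbed %.2f%%, residual %.2f%%\n",
              s$lost_percent, s$cleared_percent, s$residual_percent))
  cat("  by absorbing region (%):\n")
  print(s$by_region, ...)
  invisible(x)
}

#' Regional absorption summary
#'
#' Normalises the absorbed-mass bookkeeping by the total solute mass:
#' regional percentages `A_r`, the contribution of each initial
#' deposition region to the total, and the loss buckets. The two views
#' (by absorbing region, by origin region) total identically.
#'
#' @param absorption An `mc_absorption`.
#' @return List with `total_percent`, `by_region`, `by_origin`,
#'   `lost_percent`, `cleared_percent`, `residual_percent`.
#' @export
regional_absorption_summary <- function(absorption) {
  p <- absorption$particle
  total_mass <- sum(p$alpha_mass_kg)
  if (total_mass <= 0) stop("zero total solute mass", call. = FALSE)
  by_region <- absorption$by_region
  by_region$percent <- by_region$absorbed_kg / total_mass * 100
  orig <- rowsum(p$absorbed_kg, p$deposit_region)
  by_origin <- data.frame(deposit_region = rownames(orig),
                          absorbed_kg = as.numeric(orig))
  by_origin$percent <- by_origin$absorbed_kg / total_mass * 100
  list(
    total_percent = sum(p$absorbed_kg) / total_mass * 100,
    by_region = by_region,
    by_origin = by_origin,
    lost_percent = sum(p$lost_kg) / total_mass * 100,
    cleared_percent = sum(p$cleared_kg) / total_mass * 100,
    residual_percent = sum(p$residual_kg) / total_mass * 100
  )
}

#' Convert absorption fractions to an absolute absorbed dose
#'
#' `dosage = (4/3) pi c sum_i A_i r_i^3` over deposited droplets, where
#' `A_i` is droplet `i`'s final absorbed fraction of its own solute load,
#' `r_i` its carrier radius and `c` the solute concentration.
#'
#' @param absorption An `mc_absorption` (per-droplet fractions and radii
#'   are taken from it).
#' @param solute Optional [solute_spec()] overriding the concentration.
#' @param radii_m Optional droplet radii in metres (defaults to the
#'   deposited carrier radii).
#' @return Absorbed drug mass in kg.
#' @export
dosage <- function(absorption, solute = absorption$solute, radii_m = NULL) {
  p <- absorption$particle
  if (is.null(radii_m)) radii_m <- p$d_um * 1e-6 / 2
  (4 / 3) * pi * solute$concentration_kg_m3 *
    sum(p$fraction_absorbed * radii_m^3)
}

#' Total and regional absorption as a function of solute radius
#'
#' The passage records are radius-independent (carriers are passive
#' tracers), so the clearance solution is computed once and the
#' diffusion--absorption accounting is swept over solute radii.
#'
#' @param clearance An `mc_clearance`.
#' @param radii_nm Vector of solute radii in nm.
#' @param solute Template [solute_spec()] supplying the mass fraction and
#'   concentration.
#' @param gel,constants,regions As in [absorb_particles()].
#' @return An object of class `mc_sweep`: a data.frame with one row per
#'   radius and columns `r_s_nm`, `D_g_m2_s`, `total_pct`,
#'   `lost_pct`, `cleared_pct`, `residual_pct`, `region_<name>_pct` and
#'   `origin_<name>_pct`.
#' @export
absorption_radius_sweep <- function(clearance, radii_nm,
                                    solute = solute_spec(10),
                                    gel = gel_layer(),
                                    constants = diffusion_constants(),
                                    regions = region_specs()) {
  if (!length(radii_nm)) stop("empty radius list", call. = FALSE)
  rows <- lapply(radii_nm, function(r) {
    sol <- solute_spec(r, solute$mass_fraction, solute$concentration_kg_m3)
    ab <- absorb_particles(clearance, sol, gel, constants, regions)
    s <- regional_absorption_summary(ab)
    row <- data.frame(r_s_nm = r, D_g_m2_s = ab$D_g,
                      total_pct = s$total_percent,
                      lost_pct = s$lost_percent,
                      cleared_pct = s$cleared_percent,
                      residual_pct = s$residual_percent)
    for (i in seq_len(nrow(s$by_region))) {
      row[[paste0("region_", s$by_region$region[i], "_pct")]] <-
        s$by_region$percent[i]
    }
    for (i in seq_len(nrow(s$by_origin))) {
      row[[paste0("origin_", s$by_origin$deposit_region[i], "_pct")]] <-
        s$by_origin$percent[i]
    }
    row
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- 0
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mc_sweep", "data.frame")
  out
}

#' Write absorption results to CSV
#'
#' @param absorption An `mc_absorption`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_absorption_csv <- function(absorption, path) {
  utils::write.csv(absorption$particle, path, row.names = FALSE)
  invisible(path)
}
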