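#' Physical properties of the mucus blanket
#'
#' Carried as metadata by the reduced surface solve (the potential
#' reduction needs no viscosity at its Reynolds number of order 1e-4) and
#' used to convert the per-cell source density into an areal injection
#' speed.
#'
#' @param density_kg_m3 Mucus density (default 1000).
#' @param viscosity_Pa_s Mucus viscosity (default 12).
#' @param gel_thickness_um Upper gel layer thickness (default 10).
#' @param periciliary_um Periciliary layer thickness (default 5).
#' @param target_mean_speed_mm_min Calibration target for the area-weighted
#'   mean mucus speed over the main cavity wall, excluding vestibules and
#'   sinuses (default 6).
#' @return An object of class `mc_mucus_properties`.
#' @export
mucus_properties <- function(density_kg_m3 = 1000,
                             viscosity_Pa_s = 12,
                             gel_thickness_um = 10,
                             periciliary_um = 5,
                             target_mean_speed_mm_min = 6) {
  vals <- c(density_kg_m3, viscosity_Pa_s, gel_thickness_um,
            periciliary_um, target_mean_speed_mm_min)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("mucus properties must be positive", call. = FALSE)
  }
  structure(
    list(density_kg_m3 = density_kg_m3, viscosity_Pa_s = viscosity_Pa_s,
         gel_thickness_um = gel_thickness_um, periciliary_um = periciliary_um,
         target_mean_speed_mm_min = target_mean_speed_mm_min),
    class = "mc_mucus_properties"
  )
}

#' Default mucus source layout
#'
#' Distributes the mucus production between the general mucosa (source
#' weight proportional to cell area on mucus-producing meshed regions) and
#' the maxillary ostium patches, through which the unmeshed sinuses inject
#' their output into the main domain. The vestibule and the nasopharynx
#' conduit carry no source.
#'
#' @param domain An `mc_domain`.
#' @param ostium_share Fraction of the total source placed on the ostium
#'   patches (default 0.3; the sinuses are a major mucus source).
#' @return Numeric vector of non-negative per-cell weights (sum 1).
#' @export
default_source_layout <- function(domain, ostium_share = 0.3) {
  cells <- domain$cells
  specs <- region_specs()
  producing <- specs$region[specs$mucus_producing]
  w <- ifelse(cells$region %in% producing, cells$area_cm2, 0)
  if (sum(w) > 0) w <- w / sum(w)
  if (any(cells$is_ostium) && ostium_share > 0) {
    w <- w * (1 - ostium_share)
    w[cells$is_ostium] <- w[cells$is_ostium] +
      ostium_share * cells$area_cm2[cells$is_ostium] /
        sum(cells$area_cm2[cells$is_ostium])
  }
  w
}

#' Swirl perturbation configuration
#'
#' A divergence-free stream-function perturbation superposed on the
#' potential mucus field. It recreates the recirculating motion seen near
#' the vestibule and anterior to the maxillary ostia: particles anterior to
#' the ostia first detour towards the nasal valve before turning back, and
#' particles deposited in the vestibule are slowly stirred across the
#' vestibule boundary into the main stream.
#'
#' @param amplitude_mm_min Peak swirl speed in mm/min (0 disables).
#' @param spots Optional list of spots, each a list with `x_mm`, `y_mm`,
#'   `radius_mm` and `sign`. `NULL` places one default eddy per chamber at
#'   the vestibule/main-passage boundary.
#' @return An object of class `mc_swirl_config`.
#' @export
swirl_config <- function(amplitude_mm_min = 8, spots = NULL) {
  if (!is.finite(amplitude_mm_min) || amplitude_mm_min < 0) {
    stop("swirl amplitude must be non-negative", call. = FALSE)
  }
  structure(list(amplitude_mm_min = amplitude_mm_min, spots = spots),
            class = "mc_swirl_config")
}

default_swirl_spots <- function(domain) {
  cfg <- domain$config
  x0 <- if (!is.null(cfg)) cfg$vestibule_length_mm + 1 else domain$res_mm * 4
  m <- domain$rows_per_chamber
  res <- domain$res_mm
  # compact eddy straddling the vestibule boundary in the main-passage
  # band (0.58 of the chamber width out from the septal mid-line): its
  # near tail slowly stirs posterior-vestibule deposits into the main
  # stream while the septum band stays near the mean flow
  spots <- list()
  if (domain$two_chambers) {
    spots[[1]] <- list(x_mm = x0, y_mm = (m - 0.58 * m) * res, radius_mm = 4,
                       sign = 1)
    spots[[2]] <- list(x_mm = x0, y_mm = (m + 0.58 * m) * res, radius_mm = 4,
                       sign = -1)
  } else {
    spots[[1]] <- list(x_mm = x0, y_mm = (0.58 * m) * res, radius_mm = 4,
                       sign = 1)
  }
  spots
}

# stream function of the swirl at arbitrary points
swirl_psi <- function(x, y, spots, amplitude) {
  psi <- numeric(length(x))
  if (amplitude <= 0 || !length(spots)) return(psi)
  for (sp in spots) {
    r2 <- (x - sp$x_mm)^2 + (y - sp$y_mm)^2
    # peak speed equals `amplitude` at r = radius
    psi <- psi + sp$sign * amplitude * sp$radius_mm * exp(0.5) *
      exp(-r2 / (2 * sp$radius_mm^2))
  }
  psi
}

#' Solve the steady mucus surface velocity field
#'
#' Finite-volume 5-point solve of the metric-weighted potential problem
#' `div(w grad(phi)) = -w s` on the unwrapped structured grid, with
#' `phi = 0` on the outlet edge and zero normal flux on every other
#' boundary (including the sealed chamber divide anterior to the choanae).
#' The velocity is `v = -grad(phi)` in mm/min, so mucus runs from the
#' distributed sources to the posterior outlet; an optional divergence-free
#' swirl perturbation is superposed afterwards.
#'
#' @param domain An `mc_domain` with at least one outlet cell.
#' @param props An [mucus_properties()] object.
#' @param source_layout Non-negative per-cell source weights (zero on the
#'   vestibule); defaults to [default_source_layout()].
#' @param scale Multiplicative source strength in 1/min applied to the
#'   normalised layout (see [calibrate_source_strength()]).
#' @param swirl An [swirl_config()]; `NULL` disables the perturbation.
#' @return An object of class `mc_mucus_field` carrying cell-centred
#'   velocities (mm/min), face velocities, the potential, the per-cell
#'   source density and the domain.
#' @export
solve_mucus_field <- function(domain, props = mucus_properties(),
                              source_layout = default_source_layout(domain),
                              scale = 1, swirl = swirl_config()) {
  cells <- domain$cells
  n <- nrow(cells)
  if (!any(cells$is_outlet)) {
    stop("domain has no outlet cell: the potential problem is singular",
         call. = FALSE)
  }
  if (length(source_layout) != n || any(source_layout < 0)) {
    stop("source layout must be a non-negative per-cell weight vector",
         call. = FALSE)
  }
  if (any(source_layout[cells$region == "vestibule"] > 0)) {
    stop("no mucus source may be placed on the vestibule", call. = FALSE)
  }
  h <- domain$res_mm
  s <- scale * source_layout                     # 1/min per cell
  w <- cells$width_factor
  idx <- domain$index

  # interior faces as vectorised (a, b) cell pairs; harmonic-mean conductance
  fa <- integer(0); fb <- integer(0)
  if (domain$nx > 1) {
    a <- as.vector(idx[, -domain$nx, drop = FALSE])
    b <- as.vector(idx[, -1, drop = FALSE])
    ok <- !is.na(a) & !is.na(b)
    fa <- c(fa, a[ok]); fb <- c(fb, b[ok])
  }
  if (domain$ny > 1) {
    a <- as.vector(idx[-domain$ny, , drop = FALSE])
    b <- as.vector(idx[-1, , drop = FALSE])
    iy_low <- rep(seq_len(domain$ny - 1L), domain$nx)
    ix_all <- rep(seq_len(domain$nx), each = domain$ny - 1L)
    sealed <- chamber_divide(domain, iy_low, ix_all)
    ok <- !is.na(a) & !is.na(b) & !sealed
    fa <- c(fa, a[ok]); fb <- c(fb, b[ok])
  }
  wf <- 2 / (1 / w[fa] + 1 / w[fb])
  diag_acc <- numeric(n)
  acc <- rowsum(c(wf, wf), c(fa, fb))
  diag_acc[as.integer(rownames(acc))] <- acc[, 1]
  # outlet Dirichlet faces (ghost phi = 0 at the east face)
  out_cells <- cells$cell[cells$is_outlet]
  diag_acc[out_cells] <- diag_acc[out_cells] + 2 * w[out_cells]
  ii <- c(fa, fb, seq_len(n))
  jj <- c(fb, fa, seq_len(n))
  vv <- c(-wf, -wf, diag_acc)

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  b <- w * s * h^2
  phi <- as.numeric(Matrix::solve(A, b))
  resid <- max(abs(A %*% phi - b)) / max(max(abs(b)), 1e-300)
  if (!is.finite(resid) || resid > 1e-8) {
    stop(sprintf("mucus potential solve did not converge (residual %.3g)",
                 resid), call. = FALSE)
  }

  # face-normal velocities (mm/min); zero on closed boundaries
  phim <- matrix(NA_real_, domain$ny, domain$nx)
  phim[cbind(cells$iy, cells$ix)] <- phi
  face_u <- matrix(0, domain$ny, domain$nx)   # east face of (iy, ix)
  face_v <- matrix(0, domain$ny, domain$nx)   # north face of (iy, ix)
  if (domain$nx > 1) {
    du <- -(phim[, -1, drop = FALSE] - phim[, -domain$nx, drop = FALSE]) / h
    du[is.na(du)] <- 0
    face_u[, -domain$nx] <- du
  }
  face_u[cbind(cells$iy[cells$is_outlet], cells$ix[cells$is_outlet])] <-
    2 * phim[cbind(cells$iy[cells$is_outlet], cells$ix[cells$is_outlet])] / h
  if (domain$ny > 1) {
    dv <- -(phim[-1, , drop = FALSE] - phim[-domain$ny, , drop = FALSE]) / h
    dv[is.na(dv)] <- 0
    for (iy in seq_len(domain$ny - 1L)) {
      dv[iy, chamber_divide(domain, iy, seq_len(domain$nx))] <- 0
    }
    face_v[-domain$ny, ] <- dv
  }

  # swirl on faces from corner stream-function differences (discretely
  # divergence-free); sealed and boundary faces stay closed
  sw_spots <- list()
  amp <- 0
  if (!is.null(swirl) && swirl$amplitude_mm_min > 0) {
    amp <- swirl$amplitude_mm_min
    sw_spots <- if (is.null(swirl$spots)) default_swirl_spots(domain) else swirl$spots
    xe <- seq_len(domain$nx) * h      # east face x of column ix
    yn <- seq_len(domain$ny) * h      # north face y of row iy
    for (ix in seq_len(domain$nx - 1L)) {
      a <- idx[, ix]; b <- idx[, ix + 1L]
      open <- !is.na(a) & !is.na(b)
      if (!any(open)) next
      ys <- which(open)
      psi_top <- swirl_psi(rep(xe[ix], length(ys)), yn[ys], sw_spots, amp)
      psi_bot <- swirl_psi(rep(xe[ix], length(ys)), yn[ys] - h, sw_spots, amp)
      face_u[ys, ix] <- face_u[ys, ix] + (psi_top - psi_bot) / h
    }
    for (iy in seq_len(domain$ny - 1L)) {
      a <- idx[iy, ]; b <- idx[iy + 1L, ]
      sealed <- chamber_divide(domain, iy, seq_len(domain$nx))
      open <- !is.na(a) & !is.na(b) & !sealed
      if (!any(open)) next
      xs <- which(open)
      psi_e <- swirl_psi(xe[xs], rep(yn[iy], length(xs)), sw_spots, amp)
      psi_w <- swirl_psi(xe[xs] - h, rep(yn[iy], length(xs)), sw_spots, amp)
      face_v[iy, xs] <- face_v[iy, xs] - (psi_e - psi_w) / h
    }
  }

  # cell-centred velocities from opposite-face averages
  uw <- cbind(0, face_u[, -domain$nx, drop = FALSE])
  vs <- rbind(0, face_v[-domain$ny, , drop = FALSE])
  vx <- (uw + face_u) / 2
  vy <- (vs + face_v) / 2
  inactive <- is.na(phim)
  vx[inactive] <- NA_real_
  vy[inactive] <- NA_real_

  # areal injection speed (m/s): source density times gel thickness
  inj_m_s <- s / 60 * props$gel_thickness_um * 1e-6

  structure(
    list(
      domain = domain, props = props,
      vx = vx, vy = vy, phi = phim,
      face_u = face_u, face_v = face_v,
      source_per_min = s, injection_m_s = inj_m_s,
      source_scale = scale, source_layout = source_layout,
      swirl_amplitude = amp, swirl_spots = sw_spots
    ),
    class = "mc_mucus_field"
  )
}

#' @export
print.mc_mucus_field <- function(x, ...) {
  cat(sprintf("Mucus surface velocity field on a %d x %d grid\n",
              x$domain$ny, x$domain$nx))
  cat(sprintf("  mean speed over calibration wall : %.3f mm/min\n",
              mean_mucus_speed(x)))
  cat(sprintf("  source scale %.4g 1/min, swirl amplitude %.2f mm/min\n",
              x$source_scale, x$swirl_amplitude))
  cat(sprintf("  mass balance residual            : %.3g\n",
              check_mass_balance(x)))
  invisible(x)
}

#' Area-weighted mean mucus speed over the calibration wall
#'
#' The calibration wall is the main cavity mucosa: main passage, septum and
#' olfactory cells (vestibules and sinuses excluded).
#'
#' @param field An `mc_mucus_field`.
#' @return Mean speed in mm/min.
#' @export
mean_mucus_speed <- function(field) {
  cells <- field$domain$cells
  sel <- cells$region %in% c("main_passage", "septum", "olfactory")
  if (!any(sel)) sel <- rep(TRUE, nrow(cells))
  sp <- sqrt(field$vx[cbind(cells$iy, cells$ix)]^2 +
               field$vy[cbind(cells$iy, cells$ix)]^2)
  sum(sp[sel] * cells$area_cm2[sel]) / sum(cells$area_cm2[sel])
}

#' Calibrate the mucus source strength
#'
#' Returns the multiplicative source scaling that makes the area-weighted
#' mean mucus speed over the calibration wall equal the target (default
#' 6 mm/min) to within 0.1%. Without a swirl perturbation the potential
#' problem is linear in the source and a single rescale suffices; with a
#' fixed-amplitude swirl the scaling is found by root bracketing.
#'
#' @param domain An `mc_domain`.
#' @param props An [mucus_properties()] object.
#' @param source_layout Per-cell source weights.
#' @param swirl An [swirl_config()] used in the final field.
#' @return The scaling factor (1/min per unit layout weight).
#' @export
calibrate_source_strength <- function(domain, props = mucus_properties(),
                                      source_layout = default_source_layout(domain),
                                      swirl = swirl_config()) {
  target <- props$target_mean_speed_mm_min
  base <- solve_mucus_field(domain, props, source_layout, scale = 1,
                            swirl = NULL)
  m0 <- mean_mucus_speed(base)
  if (!is.finite(m0) || m0 <= 0) {
    stop("baseline mean mucus speed is zero; cannot calibrate", call. = FALSE)
  }
  scale <- target / m0
  if (!is.null(swirl) && swirl$amplitude_mm_min > 0) {
    f <- function(sc) {
      mean_mucus_speed(solve_mucus_field(domain, props, source_layout,
                                         scale = sc, swirl = swirl)) - target
    }
    lo <- scale / 10; hi <- scale * 10
    scale <- stats::uniroot(f, c(lo, hi), tol = scale * 1e-5)$root
  }
  scale
}

#' Discrete mass-balance residual of a mucus field
#'
#' Relative imbalance between the injected source flux and the flux leaving
#' through the outlet faces, \eqn{|F_{src} - F_{out}| / F_{src}}.
#'
#' @param field An `mc_mucus_field`.
#' @return Relative residual (absolute outlet flux if the source is zero).
#' @export
check_mass_balance <- function(field) {
  dom <- field$domain
  cells <- dom$cells
  h <- dom$res_mm
  src <- sum(cells$width_factor * field$source_per_min * h^2)
  out <- cells$is_outlet
  outflux <- sum(cells$width_factor[out] *
                   field$face_u[cbind(cells$iy[out], cells$ix[out])] * h)
  if (src == 0) return(abs(outflux))
  abs(src - outflux) / src
}

#' Construct a field from prescribed cell-centred velocities
#'
#' Useful for toy configurations and for post-processing externally
#' computed surface velocity fields.
#'
#' @param domain An `mc_domain`.
#' @param vx,vy Velocities in mm/min: scalars, per-cell vectors (cell
#'   order), or `ny x nx` matrices.
#' @param source_per_min Optional per-cell source density (1/min).
#' @return An `mc_mucus_field`.
#' @export
as_mucus_field <- function(domain, vx, vy, source_per_min = 0) {
  tomat <- function(v) {
    m <- matrix(NA_real_, domain$ny, domain$nx)
    if (length(v) == 1) {
      m[cbind(domain$cells$iy, domain$cells$ix)] <- v
    } else if (is.matrix(v)) {
      m <- v
    } else {
      m[cbind(domain$cells$iy, domain$cells$ix)] <- v
    }
    m
  }
  vxm <- tomat(vx); vym <- tomat(vy)
  s <- rep_len(source_per_min, nrow(domain$cells))
  face_u <- matrix(0, domain$ny, domain$nx)
  out <- domain$cells$is_outlet
  face_u[cbind(domain$cells$iy[out], domain$cells$ix[out])] <-
    vxm[cbind(domain$cells$iy[out], domain$cells$ix[out])]
  structure(
    list(domain = domain, props = mucus_properties(),
         vx = vxm, vy = vym, phi = NULL,
         face_u = face_u, face_v = matrix(0, domain$ny, domain$nx),
         source_per_min = s, injection_m_s = s / 60 * 1e-5,
         source_scale = NA_real_, source_layout = s,
         swirl_amplitude = 0, swirl_spots = list()),
    class = "mc_mucus_field"
  )
}

#' Write a mucus field to CSV
#'
#' Columns: `x_mm`, `y_mm`, `vx_mm_per_min`, `vy_mm_per_min`, `source`.
#'
#' @param field An `mc_mucus_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  cells <- field$domain$cells
  df <- data.frame(
    x_mm = cells$x_mm, y_mm = cells$y_mm,
    vx_mm_per_min = field$vx[cbind(cells$iy, cells$ix)],
    vy_mm_per_min = field$vy[cbind(cells$iy, cells$ix)],
    source = field$source_per_min
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load an externally produced surface velocity field
#'
#' Reads the [write_field_csv()] schema (`x_mm`, `y_mm`, `vx_mm_per_min`,
#' `vy_mm_per_min`, `source`) onto an existing domain, e.g. to post-process
#' a full CFD export.
#'
#' @param path CSV path.
#' @param domain The `mc_domain` the field lives on.
#' @return An `mc_mucus_field`.
#' @export
load_field_csv <- function(path, domain) {
  df <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "vx_mm_per_min", "vy_mm_per_min", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("field CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  id <- locate_cells(domain, df$x_mm, df$y_mm)
  if (anyNA(id)) {
    stop("field rows outside the domain: ",
         paste(which(is.na(id)), collapse = ", "), call. = FALSE)
  }
  ord <- match(domain$cells$cell, id)
  if (anyNA(ord)) stop("field CSV does not cover every domain cell", call. = FALSE)
  fld <- as_mucus_field(domain, df$vx_mm_per_min[ord], df$vy_mm_per_min[ord],
                        df$source[ord])
  fld
}
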