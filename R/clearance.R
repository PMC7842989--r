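#' Bilinear velocity interpolation on the unwrapped plane
#'
#' @param field An `mc_mucus_field`.
#' @param x_mm,y_mm Query positions (vectorised).
#' @return List with `vx`, `vy` in mm/min; inactive corners are dropped
#'   from the bilinear stencil (zero velocity where no corner is active).
#' @keywords internal
velocity_at <- function(field, x_mm, y_mm) {
  dom <- field$domain
  res <- dom$res_mm
  cx <- x_mm / res + 0.5         # fractional column in cell-centre coords
  cy <- y_mm / res + 0.5
  i0 <- pmin(pmax(floor(cx), 1), dom$nx)
  j0 <- pmin(pmax(floor(cy), 1), dom$ny)
  i1 <- pmin(i0 + 1, dom$nx)
  j1 <- pmin(j0 + 1, dom$ny)
  fx <- pmin(pmax(cx - i0, 0), 1)
  fy <- pmin(pmax(cy - j0, 0), 1)
  vx <- numeric(length(x_mm)); vy <- numeric(length(x_mm)); wt <- numeric(length(x_mm))
  corner <- function(jj, ii, w) {
    val_x <- field$vx[cbind(jj, ii)]
    val_y <- field$vy[cbind(jj, ii)]
    ok <- !is.na(val_x)
    vx[ok] <<- vx[ok] + w[ok] * val_x[ok]
    vy[ok] <<- vy[ok] + w[ok] * val_y[ok]
    wt[ok] <<- wt[ok] + w[ok]
  }
  corner(j0, i0, (1 - fx) * (1 - fy))
  corner(j0, i1, fx * (1 - fy))
  corner(j1, i0, (1 - fx) * fy)
  corner(j1, i1, fx * fy)
  pos <- wt > 0
  vx[pos] <- vx[pos] / wt[pos]
  vy[pos] <- vy[pos] / wt[pos]
  list(vx = vx, vy = vy)
}

#' Advect deposited particles along the mucus field
#'
#' Particles are passive surface tracers (mucus transport at ~6 mm/min is
#' quasi-static, so droplet inertia is irrelevant post-deposition).
#' Midpoint (RK2) integration of `dx/dt = v(x)` with bilinear velocity
#' interpolation; region transitions are detected by cell lookup each step
#' and logged with linearly interpolated crossing times; a particle is
#' removed once it crosses the posterior outlet edge. Steps longer than
#' one cell at the peak field speed are sub-divided automatically (with a
#' warning).
#'
#' @param particles An `mc_deposition`.
#' @param field An `mc_mucus_field` solved on the particles' domain.
#' @param dt Time step in seconds (default 1).
#' @param horizon_s Simulation horizon in seconds (default 1800,
#'   i.e. 30 min).
#' @param snapshot_times_s Times (s) at which particle positions are
#'   recorded; defaults to every 5 minutes.
#' @return An object of class `mc_clearance` with elements `passages`
#'   (`particle_id`, `region`, `t_in_s`, `t_out_s`), `status`
#'   (`particle_id`, `status`, `clear_time_s`, `deposit_region`,
#'   `mass_kg`, `d_um`), `snapshots` and the call parameters.
#' @export
advect_particles <- function(particles, field, dt = 1, horizon_s = 1800,
                             snapshot_times_s = seq(0, horizon_s, by = 300)) {
  dom <- field$domain
  if (dt <= 0 || horizon_s < dt) {
    stop("need dt > 0 and horizon >= dt", call. = FALSE)
  }
  n <- nrow(particles)
  x <- particles$x_mm; y <- particles$y_mm
  cell0 <- locate_cells(dom, x, y)
  if (anyNA(cell0)) {
    stop("particle(s) initially outside the domain: ",
         paste(utils::head(which(is.na(cell0)), 10), collapse = ", "),
         call. = FALSE)
  }
  vmax <- max(sqrt(field$vx^2 + field$vy^2), na.rm = TRUE)   # mm/min
  n_sub <- max(1L, ceiling((vmax / 60 * dt) / dom$res_mm))
  if (n_sub > 1L) {
    warning("dt exceeds the one-cell advection bound; sub-stepping by ",
            n_sub)
  }
  h_min <- dt / n_sub / 60       # substep in minutes
  L <- dom$nx * dom$res_mm       # outlet edge

  region <- dom$cells$region[cell0]
  t_in <- numeric(n)
  active <- rep(TRUE, n)
  status <- rep("in_transit", n)
  clear_time <- rep(NA_real_, n)
  pass <- vector("list", 256); np <- 0L
  push <- function(df) {
    np <<- np + 1L
    if (np > length(pass)) length(pass) <<- 2L * np
    pass[[np]] <<- df
  }
  snaps <- vector("list", length(snapshot_times_s)); ns <- 0L
  record_snapshot <- function(t_now) {
    ns <<- ns + 1L
    snaps[[ns]] <<- data.frame(
      t_s = t_now, particle_id = particles$id,
      x_mm = ifelse(active, x, NA_real_),
      y_mm = ifelse(active, y, NA_real_),
      status = ifelse(active, "in_transit", "cleared")
    )
  }
  snap_left <- sort(unique(snapshot_times_s))
  if (length(snap_left) && snap_left[1] <= 0) {
    record_snapshot(0); snap_left <- snap_left[-1]
  }

  t <- 0
  steps <- ceiling(horizon_s / dt)
  for (st in seq_len(steps)) {
    for (sub in seq_len(n_sub)) {
      idx <- which(active)
      if (!length(idx)) break
      xs <- x[idx]; ys <- y[idx]
      v1 <- velocity_at(field, xs, ys)
      v2 <- velocity_at(field, xs + v1$vx * h_min / 2, ys + v1$vy * h_min / 2)
      xn <- xs + v2$vx * h_min
      yn <- ys + v2$vy * h_min
      dt_s <- h_min * 60

      # outlet clearance
      out <- xn > L
      if (any(out)) {
        frac <- (L - xs[out]) / (xn[out] - xs[out])
        tc <- t + frac * dt_s
        ids <- idx[out]
        push(data.frame(particle_id = particles$id[ids],
                        region = region[ids], t_in_s = t_in[ids],
                        t_out_s = tc))
        status[ids] <- "cleared"
        clear_time[ids] <- tc
        active[ids] <- FALSE
        x[ids] <- xn[out]; y[ids] <- yn[out]
      }
      stay <- !out
      if (any(stay)) {
        ids <- idx[stay]
        xs2 <- xn[stay]; ys2 <- yn[stay]
        cid <- locate_cells(dom, xs2, ys2)
        # particles stepping into inactive territory slide along the wall
        bad <- is.na(cid)
        if (any(bad)) {
          cid_x <- locate_cells(dom, xs2[bad], ys[stay][bad])
          usex <- !is.na(cid_x)
          ys2[bad][usex] <- ys[stay][bad][usex]
          cid[bad][usex] <- cid_x[usex]
          bad2 <- is.na(cid)
          if (any(bad2)) {
            cid_y <- locate_cells(dom, xs[stay][bad2], ys2[bad2])
            usey <- !is.na(cid_y)
            xs2[bad2][usey] <- xs[stay][bad2][usey]
            cid[bad2][usey] <- cid_y[usey]
            still <- is.na(cid)
            xs2[still] <- xs[stay][still]
            ys2[still] <- ys[stay][still]
            cid[still] <- locate_cells(dom, xs2[still], ys2[still])
          }
        }
        newreg <- dom$cells$region[cid]
        moved <- newreg != region[ids]
        if (any(moved)) {
          mi <- which(moved)
          # crossing time from the first grid line crossed along the step
          ox <- xs[stay][mi]; oy <- ys[stay][mi]
          nx2 <- xs2[mi]; ny2 <- ys2[mi]
          res <- dom$res_mm
          fx <- rep(Inf, length(mi)); fy <- rep(Inf, length(mi))
          dxs <- nx2 - ox; dys <- ny2 - oy
          cross_x <- which(abs(dxs) > 0 & floor(ox / res) != floor(nx2 / res))
          if (length(cross_x)) {
            edge <- ifelse(dxs[cross_x] > 0, ceiling(ox[cross_x] / res),
                           floor(ox[cross_x] / res)) * res
            fx[cross_x] <- (edge - ox[cross_x]) / dxs[cross_x]
          }
          cross_y <- which(abs(dys) > 0 & floor(oy / res) != floor(ny2 / res))
          if (length(cross_y)) {
            edge <- ifelse(dys[cross_y] > 0, ceiling(oy[cross_y] / res),
                           floor(oy[cross_y] / res)) * res
            fy[cross_y] <- (edge - oy[cross_y]) / dys[cross_y]
          }
          frac <- pmin(pmax(pmin(fx, fy), 0), 1)
          frac[!is.finite(frac)] <- 0.5
          tc <- t + frac * dt_s
          ids_m <- ids[mi]
          push(data.frame(particle_id = particles$id[ids_m],
                          region = region[ids_m], t_in_s = t_in[ids_m],
                          t_out_s = tc))
          region[ids_m] <- newreg[mi]
          t_in[ids_m] <- tc
        }
        x[ids] <- xs2; y[ids] <- ys2
      }
      t <- t + dt_s
    }
    while (length(snap_left) && t >= snap_left[1] - 1e-9) {
      record_snapshot(snap_left[1]); snap_left <- snap_left[-1]
    }
    if (!any(active)) break
  }
  # close open intervals at the horizon
  idx <- which(active)
  if (length(idx)) {
    push(data.frame(particle_id = particles$id[idx], region = region[idx],
                    t_in_s = t_in[idx], t_out_s = horizon_s))
  }
  while (length(snap_left)) {   # horizon reached before late snapshots
    record_snapshot(snap_left[1]); snap_left <- snap_left[-1]
  }
  passages <- do.call(rbind, pass[seq_len(np)])
  passages <- passages[order(passages$particle_id, passages$t_in_s), ]
  rownames(passages) <- NULL
  structure(
    list(
      passages = passages,
      status = data.frame(
        particle_id = particles$id, status = status,
        clear_time_s = clear_time,
        deposit_region = particles$region,
        mass_kg = particles$mass_kg, d_um = particles$d_um
      ),
      snapshots = do.call(rbind, snaps[seq_len(ns)]),
      dt_s = dt, horizon_s = horizon_s, n_substeps = n_sub
    ),
    class = "mc_clearance"
  )
}

#' @export
print.mc_clearance <- function(x, ...) {
  n <- nrow(x$status)
  cleared <- sum(x$status$status == "cleared")
  cat(sprintf("Mucociliary clearance run: %d particles, horizon %.0f s\n",
              n, x$horizon_s))
  cat(sprintf("  cleared %d (%.1f%%), in transit %d\n", cleared,
              100 * cleared / n, n - cleared))
  med <- median_clearance_times(x)
  cat("  median clearance time by deposit region (s):\n")
  print(med, ...)
  invisible(x)
}

#' Particle positions and cleared fractions at a snapshot time
#'
#' @param clearance An `mc_clearance`.
#' @param t_s A time among the recorded snapshot times.
#' @return List with `particles` (positions/status at `t_s`) and
#'   `cleared_fraction` (cumulative mass fraction cleared by `t_s`, per
#'   initial deposition region).
#' @export
clearance_snapshot <- function(clearance, t_s) {
  snap <- clearance$snapshots
  sel <- !is.na(snap$t_s) & abs(snap$t_s - t_s) < 1e-9
  if (!any(sel)) {
    stop("t = ", t_s, " s is not among the recorded snapshot times",
         call. = FALSE)
  }
  part <- snap[sel, ]
  st <- clearance$status
  cleared_mass <- st$mass_kg * (st$status == "cleared" &
                                  !is.na(st$clear_time_s) &
                                  st$clear_time_s <= t_s + 1e-9)
  cf <- tapply(cleared_mass, st$deposit_region, sum) /
    tapply(st$mass_kg, st$deposit_region, sum)
  list(particles = part,
       cleared_fraction = data.frame(region = names(cf),
                                     cleared_fraction = as.numeric(cf)))
}

#' Median clearance time by initial deposition region
#'
#' Particles still in transit at the horizon count as `Inf`, so a region
#' where most particles never clear has an infinite median.
#'
#' @param clearance An `mc_clearance`.
#' @return Named numeric vector of median clearance times in seconds.
#' @export
median_clearance_times <- function(clearance) {
  st <- clearance$status
  tt <- ifelse(st$status == "cleared", st$clear_time_s, Inf)
  vapply(split(tt, st$deposit_region), stats::median, 0)
}

#' Write passage records to CSV
#'
#' @param clearance An `mc_clearance`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_passages_csv <- function(clearance, path) {
  df <- merge(clearance$passages,
              clearance$status[, c("particle_id", "status")],
              by = "particle_id", sort = FALSE)
  df <- df[order(df$particle_id, df$t_in_s), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
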