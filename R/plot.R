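#' @export
plot.mc_domain <- function(x, ...) {
  cells <- x$cells
  regs <- sort(unique(cells$region))
  cols <- grDevices::hcl.colors(length(regs), "Set 3")
  z <- matrix(NA_real_, x$ny, x$nx)
  z[cbind(cells$iy, cells$ix)] <- match(cells$region, regs)
  graphics::image(
    x = (seq_len(x$nx) - 0.5) * x$res_mm,
    y = (seq_len(x$ny) - 0.5) * x$res_mm,
    z = t(z), col = cols, xlab = "x (mm, anterior to posterior)",
    ylab = "y (mm, unwrapped circumference)",
    main = "Unwrapped nasal-wall regions", ...
  )
  ost <- cells[cells$is_ostium, ]
  if (nrow(ost)) graphics::points(ost$x_mm, ost$y_mm, pch = 4)
  graphics::legend("topleft", legend = regs, fill = cols, cex = 0.7,
                   bg = "white")
  invisible(x)
}

#' @export
plot.mc_mucus_field <- function(x, ...) {
  dom <- x$domain
  sp <- sqrt(x$vx^2 + x$vy^2)
  graphics::image(
    x = (seq_len(dom$nx) - 0.5) * dom$res_mm,
    y = (seq_len(dom$ny) - 0.5) * dom$res_mm,
    z = t(log10(pmax(sp, 1e-3))), col = grDevices::hcl.colors(64, "Viridis"),
    xlab = "x (mm)", ylab = "y (mm)",
    main = "Mucus speed (log10 mm/min)", ...
  )
  invisible(x)
}

#' @export
plot.mc_population <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(x$d_um, x$mass_fraction, type = "h",
                 xlab = "diameter (um)", ylab = "mass fraction",
                 main = "Mass distribution", ...)
  graphics::plot(x$d_um, x$number_weight, type = "h",
                 xlab = "diameter (um)", ylab = "number weight",
                 main = "Number distribution", ...)
  invisible(x)
}

#' @export
plot.mc_sweep <- function(x, which = c("regions", "origins"), ...) {
  which <- match.arg(which)
  prefix <- if (which == "regions") "region_" else "origin_"
  cols <- grep(paste0("^", prefix), names(x), value = TRUE)
  graphics::plot(x$r_s_nm, x$total_pct, type = "l", lwd = 2,
                 ylim = c(0, max(x$total_pct) * 1.15),
                 xlab = "solute radius (nm)", ylab = "absorption (%)",
                 main = if (which == "regions") {
                   "Total and regional absorption"
                 } else {
                   "Absorption by initial deposition region"
                 }, ...)
  pal <- grDevices::hcl.colors(max(length(cols), 2), "Dark 3")
  for (i in seq_along(cols)) {
    graphics::lines(x$r_s_nm, x[[cols[i]]], col = pal[i], lty = 2)
  }
  graphics::legend("topright",
                   legend = c("total", sub(paste0("^", prefix), "",
                                           sub("_pct$", "", cols))),
                   col = c("black", pal[seq_along(cols)]),
                   lty = c(1, rep(2, length(cols))), cex = 0.7)
  invisible(x)
}
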