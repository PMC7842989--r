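test_that("1-D strip with uniform source matches the closed-form solution", {
  dom <- strip_domain(n_cells = 20)
  layout <- rep(1, nrow(dom$cells))
  s <- 0.05                               # 1/min
  fld <- solve_mucus_field(dom, source_layout = layout, scale = s,
                           swirl = NULL)
  cells <- dom$cells
  vx <- fld$vx[cbind(cells$iy, cells$ix)]
  # dv/dx = s with a closed west end: v(x) = s x, v(L) = s L at the outlet
  expect_equal(vx, s * cells$x_mm, tolerance = 1e-10)
  out <- cells$is_outlet
  expect_equal(fld$face_u[cbind(cells$iy[out], cells$ix[out])],
               s * 20, tolerance = 1e-10)
  expect_lt(check_mass_balance(fld), 1e-12)
})

test_that("zero source yields a zero field; corruption breaks the balance", {
  dom <- strip_domain()
  fld <- solve_mucus_field(dom, source_layout = rep(0, nrow(dom$cells)),
                           swirl = NULL)
  expect_true(all(abs(fld$vx) < 1e-14, na.rm = TRUE))
  expect_true(all(abs(fld$vy) < 1e-14, na.rm = TRUE))

  fld2 <- solve_mucus_field(dom, source_layout = rep(1, nrow(dom$cells)),
                            scale = 0.05, swirl = NULL)
  expect_lt(check_mass_balance(fld2), 1e-8)
  out <- dom$cells$is_outlet
  fld2$face_u[cbind(dom$cells$iy[out], dom$cells$ix[out])] <- 0
  expect_gt(check_mass_balance(fld2), 0.5)
})

test_that("point source flux satisfies the discrete divergence theorem", {
  dom <- build_synthetic_domain(domain_config(
    areas_left = c(main_passage = 2), areas_right = c(main_passage = 0),
    area_nasopharynx = 0, resolution_mm = 1, length_mm = 20,
    vestibule_length_mm = 0, nasopharynx_length_mm = 0,
    chamber_width_mm = 10, septum_frac = 0, olfactory_frac = 0
  ))
  cells <- dom$cells
  src_cell <- which(cells$ix == 10 & cells$iy == 5)
  layout <- numeric(nrow(cells)); layout[src_cell] <- 1
  s <- 0.2
  fld <- solve_mucus_field(dom, source_layout = layout, scale = s,
                           swirl = NULL)
  injected <- s * dom$res_mm^2              # w = 1 everywhere
  # brute-force flux summation over box contours of increasing size
  box_flux <- function(k) {
    i1 <- 10 - k; i2 <- 10 + k; j1 <- 5 - k; j2 <- 5 + k
    i1 <- max(i1, 1); j1 <- max(j1, 1); j2 <- min(j2, dom$ny)
    east <- sum(fld$face_u[j1:j2, i2])
    west <- if (i1 > 1) sum(fld$face_u[j1:j2, i1 - 1]) else 0
    north <- if (j2 < dom$ny) sum(fld$face_v[j2, i1:i2]) else 0
    south <- if (j1 > 1) sum(fld$face_v[j1 - 1, i1:i2]) else 0
    (east - west + north - south) * dom$res_mm
  }
  for (k in 1:3) expect_equal(box_flux(k), injected, tolerance = 1e-10)
})

test_that("calibration hits the target mean speed and is scale invariant", {
  dom <- default_domain()
  fld <- calibrated_field()
  expect_equal(mean_mucus_speed(fld), 6, tolerance = 1e-3)
  expect_lt(check_mass_balance(fld), 1e-8)

  # doubling all source weights changes nothing after calibration
  layout <- default_source_layout(dom)
  sc1 <- calibrate_source_strength(dom, source_layout = layout,
                                   swirl = NULL)
  sc2 <- calibrate_source_strength(dom, source_layout = 2 * layout,
                                   swirl = NULL)
  f1 <- solve_mucus_field(dom, source_layout = layout, scale = sc1,
                          swirl = NULL)
  f2 <- solve_mucus_field(dom, source_layout = 2 * layout, scale = sc2,
                          swirl = NULL)
  expect_equal(f1$vx, f2$vx, tolerance = 1e-9)
  expect_equal(mean_mucus_speed(f1), 6, tolerance = 1e-3)
})

test_that("the potential solve is linear in the source", {
  dom <- strip_domain(n_cells = 15)
  layout <- seq_len(nrow(dom$cells)) / 10    # non-uniform
  base <- solve_mucus_field(dom, source_layout = layout, scale = 1,
                            swirl = NULL)
  for (alpha in c(0.5, 2)) {
    f <- solve_mucus_field(dom, source_layout = layout, scale = alpha,
                           swirl = NULL)
    expect_equal(f$vx, alpha * base$vx, tolerance = 1e-9)
  }
})

test_that("flow accelerates into the narrowing nasopharynx strip", {
  dom <- default_domain()
  fld <- calibrated_field()
  cells <- dom$cells
  sp <- sqrt(fld$vx^2 + fld$vy^2)[cbind(cells$iy, cells$ix)]
  naso <- cells$region == "nasopharynx"
  chamber_posterior <- cells$region %in% c("main_passage", "septum") &
    cells$x_mm > 0.6 * max(cells$x_mm[!naso])
  expect_gt(mean(sp[naso]), 1.5 * mean(sp[chamber_posterior]))
  # peak speed grows towards the outlet where the width factor is smallest
  out_col <- cells$ix == dom$nx
  expect_gt(mean(sp[out_col]), mean(sp[naso]))
})

test_that("ostium sources produce a locally radial flow pattern", {
  dom <- default_domain()
  # make the ostia dominant to isolate their signature
  fld <- solve_mucus_field(dom, source_layout = default_source_layout(
    dom, ostium_share = 0.9), scale = 0.1, swirl = NULL)
  cells <- dom$cells
  ost <- cells[cells$is_ostium & cells$chamber == "right", ]
  cx <- mean(ost$ix); cy <- mean(ost$iy)
  near <- function(dix, diy) {
    id <- dom$index[round(cy + diy), round(cx + dix)]
    c(vx = fld$vx[cells$iy[id], cells$ix[id]],
      vy = fld$vy[cells$iy[id], cells$ix[id]])
  }
  expect_lt(near(-2, 0)[["vx"]], 0)   # west of the patch: flow west
  expect_gt(near(2, 0)[["vx"]], 0)    # east: flow east
  expect_gt(near(0, 2)[["vy"]], 0)    # above: flow up
  expect_lt(near(0, -2)[["vy"]], 0)   # below: flow down
})

test_that("field CSV export round-trips through the external-field reader", {
  dom <- build_synthetic_domain(domain_config(resolution_mm = 4))
  scale <- calibrate_source_strength(dom, swirl = NULL)
  fld <- solve_mucus_field(dom, scale = scale, swirl = NULL)
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(fld, path)
  fld2 <- load_field_csv(path, dom)
  cells <- dom$cells
  expect_equal(fld2$vx[cbind(cells$iy, cells$ix)],
               fld$vx[cbind(cells$iy, cells$ix)], tolerance = 1e-9)
  expect_equal(fld2$vy[cbind(cells$iy, cells$ix)],
               fld$vy[cbind(cells$iy, cells$ix)], tolerance = 1e-9)
})

test_that("a domain without an outlet is rejected", {
  dom <- strip_domain()
  dom$cells$is_outlet[] <- FALSE
  expect_error(solve_mucus_field(dom), "no outlet")
  expect_error(
    solve_mucus_field(default_domain(),
                      source_layout = rep(1, nrow(default_domain()$cells))),
    "vestibule")
})
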