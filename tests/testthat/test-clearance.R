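uniform_scene <- function(vx_mm_min = 6, n_cells = 20, res = 1) {
  dom <- build_synthetic_domain(domain_config(
    areas_left = c(vestibule = 0.1, main_passage = 0.1),
    areas_right = c(main_passage = 0),
    area_nasopharynx = 0, resolution_mm = res, length_mm = n_cells * res,
    vestibule_length_mm = 10, nasopharynx_length_mm = 0,
    chamber_width_mm = res, septum_frac = 0, olfactory_frac = 0
  ))
  list(domain = dom, field = as_mucus_field(dom, vx_mm_min, 0))
}

particle_at <- function(dom, x, y, d = 50, mass = 1e-9) {
  cell <- locate_cells(dom, x, y)
  data.frame(id = 1L, d_um = d, mass_kg = mass, x_mm = x, y_mm = y,
             cell = cell, region = dom$cells$region[cell], time_s = 0)
}

test_that("uniform-field kinematics: clearance and region crossing times", {
  sc <- uniform_scene()            # 6 mm/min along x, outlet at x = 20
  p <- particle_at(sc$domain, 17, 0.5)
  cl <- advect_particles(p, sc$field, dt = 1, horizon_s = 300,
                         snapshot_times_s = c(0, 60))
  # 3 mm to the outlet at 6 mm/min = 30 s
  expect_equal(cl$status$status, "cleared")
  expect_equal(cl$status$clear_time_s, 30, tolerance = 1)

  # region boundary at x = 10: entry time of the second region
  p2 <- particle_at(sc$domain, 2, 0.5)
  cl2 <- advect_particles(p2, sc$field, dt = 1, horizon_s = 600,
                          snapshot_times_s = c(0))
  pas <- cl2$passages
  expect_equal(pas$region, c("vestibule", "main_passage"))
  expect_equal(pas$t_in_s[2], (10 - 2) / 6 * 60, tolerance = 1)
  expect_equal(pas$t_out_s[1], pas$t_in_s[2])     # half-open intervals
  expect_equal(pas$t_in_s[1], 0)
  expect_equal(pas$t_out_s[2], cl2$status$clear_time_s)
})

test_that("zero field leaves particles in transit with one interval", {
  sc <- uniform_scene(0)
  p <- particle_at(sc$domain, 5, 0.5)
  cl <- advect_particles(p, sc$field, dt = 1, horizon_s = 120,
                         snapshot_times_s = c(0, 60, 120))
  expect_equal(cl$status$status, "in_transit")
  expect_equal(nrow(cl$passages), 1L)
  expect_equal(cl$passages$t_in_s, 0)
  expect_equal(cl$passages$t_out_s, 120)
  snap <- clearance_snapshot(cl, 120)
  expect_equal(snap$particles$x_mm, 5)
  expect_equal(snap$cleared_fraction$cleared_fraction, 0)
  expect_error(clearance_snapshot(cl, 37), "snapshot")
})

test_that("passage bookkeeping reconstructs elapsed time exactly", {
  scn <- default_scenario()
  cl <- scn$clearance
  pas <- cl$passages
  # contiguity: within a particle, each t_out equals the next t_in
  ord <- order(pas$particle_id, pas$t_in_s)
  p <- pas[ord, ]
  same <- p$particle_id[-1] == p$particle_id[-nrow(p)]
  expect_lt(max(abs((p$t_in_s[-1] - p$t_out_s[-nrow(p)])[same])), 1e-9)
  expect_true(all(p$t_in_s[!duplicated(p$particle_id)] == 0))

  # interval sums: clear time for cleared, horizon for in-transit
  tot <- tapply(pas$t_out_s - pas$t_in_s, pas$particle_id, sum)
  tot <- tot[as.character(cl$status$particle_id)]
  want <- ifelse(cl$status$status == "cleared", cl$status$clear_time_s,
                 cl$horizon_s)
  expect_equal(as.numeric(tot), want, tolerance = 1e-6)
})

test_that("cumulative cleared fraction is monotone and a step in a toy case", {
  scn <- default_scenario()
  times <- sort(unique(scn$clearance$snapshots$t_s))
  cf <- sapply(times, function(t) {
    s <- clearance_snapshot(scn$clearance, t)$cleared_fraction
    sum(s$cleared_fraction)
  })
  expect_true(all(diff(cf) >= -1e-12))
  t0 <- clearance_snapshot(scn$clearance, 0)
  expect_equal(sum(t0$cleared_fraction$cleared_fraction), 0)

  # uniform field: the cleared fraction is a step at the transit time
  sc <- uniform_scene()
  p <- particle_at(sc$domain, 14, 0.5)       # transit (20-14)/6 min = 60 s
  cl <- advect_particles(p, sc$field, dt = 1, horizon_s = 300,
                         snapshot_times_s = c(0, 30, 90))
  expect_equal(clearance_snapshot(cl, 30)$cleared_fraction$cleared_fraction, 0)
  expect_equal(clearance_snapshot(cl, 90)$cleared_fraction$cleared_fraction, 1)
})

test_that("default scenario clears regions in the expected order", {
  scn <- default_scenario()
  med <- median_clearance_times(scn$clearance)
  expect_lt(med[["nasopharynx"]], med[["septum"]])
  expect_lt(med[["septum"]], med[["main_passage"]])
  expect_lt(med[["main_passage"]], med[["vestibule"]])
  # nasopharynx deposits are gone within a minute of model time
  expect_lt(med[["nasopharynx"]], 60)
  # 30-minute snapshot: nasopharynx-origin particles cleared at least as
  # completely as vestibule-origin ones
  cf <- clearance_snapshot(scn$clearance, 1800)$cleared_fraction
  cfv <- setNames(cf$cleared_fraction, cf$region)
  expect_gte(cfv[["nasopharynx"]], cfv[["vestibule"]])
})

test_that("bad advection inputs are rejected", {
  sc <- uniform_scene()
  p <- particle_at(sc$domain, 5, 0.5)
  p$x_mm <- -3
  expect_error(advect_particles(p, sc$field, dt = 1, horizon_s = 10),
               "outside the domain")
  p2 <- particle_at(sc$domain, 5, 0.5)
  expect_error(advect_particles(p2, sc$field, dt = 0, horizon_s = 10),
               "dt")
  # oversized steps sub-step with a warning
  expect_warning(
    advect_particles(p2, sc$field, dt = 60, horizon_s = 240,
                     snapshot_times_s = c(0)),
    "sub-stepping")
})
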