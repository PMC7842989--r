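# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_domain <- function() {
  cached("domain", function() build_synthetic_domain(domain_config()))
}

calibrated_field <- function() {
  cached("field", function() {
    dom <- default_domain()
    scale <- calibrate_source_strength(dom)
    solve_mucus_field(dom, scale = scale)
  })
}

# desk-scale end-to-end scenario with a radius sweep; ~20 s, reused by the
# clearance, absorption and acceptance tests
default_scenario <- function() {
  cached("scenario", function() {
    suppressWarnings(run_scenario(default_scenario_config(
      seed = 1,
      radii_nm = c(1, 5, 10, 20, 30, 40, 50, 60, 70, 80, 85, 90, 95,
                   100, 105, 110)
    )))
  })
}

# tiny single-region strip domain: one row of cells, outlet at the east end
strip_domain <- function(n_cells = 20, res_mm = 1) {
  cfg <- domain_config(
    areas_left = c(main_passage = n_cells * res_mm^2 / 100),
    areas_right = c(main_passage = 0),
    area_nasopharynx = 0,
    resolution_mm = res_mm,
    length_mm = n_cells * res_mm,
    vestibule_length_mm = 0,
    nasopharynx_length_mm = 0,
    chamber_width_mm = res_mm,
    septum_frac = 0, olfactory_frac = 0
  )
  build_synthetic_domain(cfg)
}

# explicit finite-difference solution of the gel-layer diffusion problem:
# reflective top (x = 0), absorbing bottom (x = h), unit mass initially in
# the top cell; cell-centred grid, ghost-cell boundaries
fd_gel_solution <- function(t_target, D, h = 1e-5, M = 200) {
  dx <- h / M
  dt <- 0.4 * dx^2 / D
  nsteps <- ceiling(t_target / dt)
  dt <- t_target / nsteps
  lam <- D * dt / dx^2
  c_now <- numeric(M)
  c_now[1] <- 1 / dx
  for (i in seq_len(nsteps)) {
    left <- c(c_now[1], c_now[-M])          # reflective ghost
    right <- c(c_now[-1], -c_now[M])        # absorbing ghost (face value 0)
    c_now <- c_now + lam * (left - 2 * c_now + right)
  }
  list(x = (seq_len(M) - 0.5) * dx, c = c_now,
       absorbed = 1 - sum(c_now) * dx)
}
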