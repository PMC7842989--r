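test_that("diffusivity chain matches the closed-form formulas", {
  cst <- diffusion_constants()
  # Stokes-Einstein, independent evaluation
  expect_equal(diffusivity_water(90),
               1.380649e-23 * 310.15 / (6 * pi * 6.913e-4 * 90e-9),
               tolerance = 1e-12)
  expect_equal(signif(diffusivity_water(90), 3), 3.65e-12)
  expect_equal(signif(diffusivity_water(1), 3), 3.29e-10)
  # 1/r scaling
  expect_equal(diffusivity_water(40), diffusivity_water(20) / 2)

  # obstruction factor at r_s = r_g is exp(-pi/4)
  expect_equal(diffusivity_mucus(50) / diffusivity_water(50), exp(-pi / 4),
               tolerance = 1e-12)
  # r_s -> 0 limit
  expect_equal(diffusivity_mucus(1e-6) / diffusivity_water(1e-6),
               exp(-(pi / 4) * (3.5 / 53.5)^2), tolerance = 1e-6)
  # strictly decreasing over the studied radius range
  Dg <- diffusivity_mucus(1:110)
  expect_true(all(diff(Dg) < 0))
  expect_error(diffusivity_water(-1), "positive")
})

test_that("absorption function has the analytic limits and printed values", {
  D <- diffusivity_mucus(90)
  expect_identical(absorption_fraction(0, D), 0)
  # long-time limit
  h <- gel_layer()$thickness_m
  t_inf <- 20 * 4 * h^2 / (pi^2 * D)
  expect_equal(absorption_fraction(t_inf, D), 1, tolerance = 1e-8)
  # monotone in t and in D (up to the series truncation tolerance)
  ts <- 10^seq(-2, 4, length.out = 60)
  expect_gt(min(diff(absorption_fraction(ts, D))), -1e-9)
  for (t in c(1, 50, 500)) {
    A_over_D <- sapply(c(110, 70, 30, 5),
                       function(r) absorption_fraction(t, diffusivity_mucus(r)))
    expect_gt(min(diff(A_over_D)), -1e-12)  # non-decreasing in D
  }
  # strictly increasing in D where nothing has saturated yet
  A1 <- sapply(c(110, 70, 30), function(r) {
    absorption_fraction(1, diffusivity_mucus(r))
  })
  expect_true(all(diff(A1) > 0))

  # slow 90 nm solute: ~97-98% at 500 s; fast 10 nm solute: ~100% at 10 s
  expect_equal(100 * absorption_fraction(500, diffusivity_mucus(90)), 97,
               tolerance = 2)
  expect_gte(100 * absorption_fraction(10, diffusivity_mucus(10)), 99.5)
  expect_error(absorption_fraction(-1, D), "non-negative")
})

test_that("concentration profile satisfies boundary and mass constraints", {
  D <- diffusivity_mucus(60)
  gel <- gel_layer()
  h <- gel$thickness_m
  for (tf in c(0.05, 0.3, 1)) {
    t <- tf * h^2 / D
    expect_equal(concentration_profile(h, t, D), 0, tolerance = 1e-9)
    # quadrature of the profile equals 1 - A(t)
    q <- stats::integrate(function(x) concentration_profile(x, t, D), 0, h,
                          rel.tol = 1e-10)$value
    expect_equal(q, 1 - absorption_fraction(t, D), tolerance = 1e-6)
  }
  expect_error(concentration_profile(2 * h, 1, D), "gel layer")
  # Dirac initial condition representation
  expect_identical(concentration_profile(c(0, h / 2), 0, D), c(Inf, 0))
})

test_that("series solution agrees with a finite-difference oracle", {
  gel <- gel_layer()
  h <- gel$thickness_m
  for (r in c(10, 60, 110)) {
    D <- diffusivity_mucus(r)
    for (tf in c(0.1, 0.5)) {
      t <- tf * h^2 / D
      fd <- fd_gel_solution(t, D, h, M = 200)
      cs <- concentration_profile(fd$x, t, D)
      expect_lt(max(abs(cs - fd$c)) * h, 1e-4)
      expect_lt(abs(fd$absorbed - absorption_fraction(t, D)), 1e-4)
    }
  }
})

test_that("per-particle bookkeeping matches limits and a brute-force oracle", {
  sol <- solute_spec(60, mass_fraction = 0.4)
  m <- 2e-9
  # particle spending all time in one absorbing region absorbs everything
  h <- gel_layer()$thickness_m
  t_inf <- 25 * 4 * h^2 / (pi^2 * diffusivity_mucus(60))
  res <- particle_absorption(
    data.frame(region = "septum", t_in_s = 0, t_out_s = t_inf),
    mass_kg = m, status = "in_transit", solute = sol)
  expect_lt(abs(res$absorbed_kg - 0.4 * m), 1e-8 * 0.4 * m)
  expect_lt(abs(res$lost_kg + res$cleared_kg + res$residual_kg),
            1e-8 * 0.4 * m)

  # vestibule-only residence: everything accrued there is lost
  res_v <- particle_absorption(
    data.frame(region = "vestibule", t_in_s = 0, t_out_s = 600),
    mass_kg = m, status = "in_transit", solute = sol)
  A600 <- absorption_fraction(600, diffusivity_mucus(60))
  expect_equal(res_v$absorbed_kg, 0)
  expect_equal(res_v$lost_kg, 0.4 * m * A600, tolerance = 1e-12)
  expect_equal(res_v$residual_kg, 0.4 * m * (1 - A600), tolerance = 1e-12)

  # two intervals vs fine-grained accumulation of dA
  pas <- data.frame(region = c("vestibule", "main_passage"),
                    t_in_s = c(0, 37.5), t_out_s = c(37.5, 120))
  res2 <- particle_absorption(pas, mass_kg = m, status = "cleared",
                              solute = sol)
  D <- diffusivity_mucus(60)
  tt <- seq(0, 120, by = 1e-3)
  dA <- diff(absorption_fraction(tt, D))
  mid <- (tt[-1] + tt[-length(tt)]) / 2
  brute_lost <- 0.4 * m * sum(dA[mid < 37.5])
  brute_abs <- 0.4 * m * sum(dA[mid >= 37.5])
  expect_equal(res2$lost_kg, brute_lost, tolerance = 1e-9)
  expect_equal(res2$absorbed_kg, brute_abs, tolerance = 1e-9)
  expect_equal(res2$cleared_kg,
               0.4 * m * (1 - absorption_fraction(120, D)),
               tolerance = 1e-12)

  # non-contiguous intervals are rejected
  bad <- data.frame(region = c("septum", "main_passage"),
                    t_in_s = c(0, 50), t_out_s = c(40, 80))
  expect_error(particle_absorption(bad, mass_kg = m), "contiguous")
})

test_that("regional summary views are consistent", {
  sol <- solute_spec(10)
  h <- gel_layer()$thickness_m
  t_inf <- 25 * 4 * h^2 / (pi^2 * diffusivity_mucus(10))
  cl <- list(
    passages = data.frame(particle_id = c(1L, 2L),
                          region = c("septum", "vestibule"),
                          t_in_s = c(0, 0), t_out_s = c(t_inf, 1)),
    status = data.frame(particle_id = c(1L, 2L),
                        status = c("in_transit", "cleared"),
                        clear_time_s = c(NA, 1),
                        deposit_region = c("septum", "vestibule"),
                        mass_kg = c(1e-9, 1e-9), d_um = c(50, 50))
  )
  ab <- absorb_particles(cl, sol)
  s <- regional_absorption_summary(ab)
  expect_equal(s$total_percent, 50, tolerance = 0.1)
  expect_equal(s$by_region$percent[s$by_region$region == "septum"], 50,
               tolerance = 0.1)
  expect_equal(s$by_origin$percent[s$by_origin$deposit_region == "septum"],
               50, tolerance = 0.1)
  expect_equal(sum(s$by_region$percent), sum(s$by_origin$percent),
               tolerance = 1e-9)
})

test_that("dosage converts fractions to absolute absorbed mass", {
  mk_abs <- function(fracs, d_um) {
    structure(list(
      particle = data.frame(fraction_absorbed = fracs, d_um = d_um),
      solute = solute_spec(10, concentration_kg_m3 = 1)
    ), class = "mc_absorption")
  }
  # zero concentration
  ab <- mk_abs(1, 2)
  ab$solute$concentration_kg_m3 <- 0
  expect_equal(dosage(ab), 0)
  # single droplet fully absorbed: the droplet's solute volume
  ab1 <- mk_abs(1, 2)     # radius 1 um
  expect_equal(dosage(ab1), 4 / 3 * pi * (1e-6)^3)
  # hand-expanded two-droplet case
  ab2 <- mk_abs(c(0.5, 0.25), c(2, 4))
  expect_equal(dosage(ab2),
               4 / 3 * pi * (0.5 * (1e-6)^3 + 0.25 * (2e-6)^3))
})

test_that("solute mass is conserved per particle and in aggregate", {
  scn <- default_scenario()
  for (r in c(1, 50, 110)) {
    ab <- absorb_particles(scn$clearance, solute_spec(r))
    p <- ab$particle
    bal <- p$absorbed_kg + p$lost_kg + p$cleared_kg + p$residual_kg
    expect_lt(max(abs(bal - p$alpha_mass_kg) / p$alpha_mass_kg), 1e-10)
    expect_lt(abs(sum(bal) - sum(p$alpha_mass_kg)) / sum(p$alpha_mass_kg),
              1e-10)
  }
})

test_that("radius sweep is consistent and has the expected monotonicities", {
  scn <- default_scenario()
  sw <- as.data.frame(scn$sweep)
  # single-radius sweep equals the direct computation
  ab50 <- regional_absorption_summary(
    absorb_particles(scn$clearance, solute_spec(50)))
  expect_equal(sw$total_pct[sw$r_s_nm == 50], ab50$total_percent,
               tolerance = 1e-9)
  one <- absorption_radius_sweep(scn$clearance, 50)
  expect_equal(one$total_pct, ab50$total_percent, tolerance = 1e-9)
  expect_error(absorption_radius_sweep(scn$clearance, numeric(0)), "empty")

  # a fully-cleared region's absorption falls as diffusion slows
  sep <- sw$region_septum_pct
  expect_lt(sep[sw$r_s_nm == 110], sep[sw$r_s_nm == 1])

  # fast-diffusion limit: total equals the non-vestibule deposited mass
  dep <- scn$deposition
  non_vest <- 100 * sum(dep$mass_kg[dep$region != "vestibule"]) /
    sum(dep$mass_kg)
  expect_lt(abs(sw$total_pct[sw$r_s_nm == 1] - non_vest), 2)
})
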