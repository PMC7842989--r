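test_that("generated deposition hits the configured regional mass split", {
  scn <- default_scenario()
  dep <- scn$deposition
  frac <- regional_mass_fractions(dep, scn$domain)
  pct <- setNames(frac$mass_percent, frac$region)
  main_bucket <- sum(pct[c("main_passage", "septum", "olfactory")],
                     na.rm = TRUE)
  expect_lt(abs(pct[["vestibule"]] - 79.8), 2)
  expect_lt(abs(main_bucket - 19.0), 2)
  expect_lt(abs(pct[["nasopharynx"]] - 1.2), 2)
  expect_equal(sum(frac$mass_percent), 100, tolerance = 1e-9)

  # 100% deposition efficiency: every stream's mass is on the wall
  expect_equal(sum(dep$mass_kg), 1, tolerance = 1e-12)
  expect_equal(nrow(dep), sum(scn$population$streams))

  # positions snapped to cells; regions match the containing cell
  expect_equal(dep$region, scn$domain$cells$region[dep$cell])
  expect_false(anyNA(dep$cell))
})

test_that("deposition is size-stratified and seed-reproducible", {
  scn <- default_scenario()
  dom <- scn$domain
  dep <- scn$deposition
  # anterior vestibule/septum band hosts coarser droplets than the
  # posterior half of the cavity
  anterior <- dep$region %in% c("vestibule", "septum")
  posterior <- dep$x_mm > 0.6 * max(dom$cells$x_mm)
  expect_gt(mean(dep$d_um[anterior]), mean(dep$d_um[posterior]))
  # nasopharynx receives only fine droplets
  expect_lt(max(dep$d_um[dep$region == "nasopharynx"]), 20)

  pop <- build_droplet_population(spray_config(streams_per_bin = 10))
  d1 <- generate_deposition(pop, dom, seed = 7)
  d2 <- generate_deposition(pop, dom, seed = 7)
  expect_identical(d1, d2)

  # different seeds: different positions, same split within sampling error
  d3 <- generate_deposition(pop, dom, seed = 8)
  expect_false(isTRUE(all.equal(d1$x_mm, d3$x_mm)))
  p1 <- regional_mass_fractions(d1)$mass_percent
  v1 <- p1[regional_mass_fractions(d1)$region == "vestibule"]
  p3 <- regional_mass_fractions(d3)$mass_percent
  v3 <- p3[regional_mass_fractions(d3)$region == "vestibule"]
  expect_lt(abs(v1 - v3), 5)
})

test_that("degenerate hot-spot configurations behave as specified", {
  dom <- default_domain()
  pop <- build_droplet_population(spray_config(streams_per_bin = 2))
  # single zero-spread hot-spot: all particles in one cell
  hs <- data.frame(name = "pin", bucket = "vestibule", x_mm = 6, y_mm = 80,
                   sd_mm = 0, w_large = 1, w_medium = 1, w_small = 1)
  cfg <- deposition_config(
    target_split = c(vestibule = 100, main = 0, nasopharynx = 0),
    hotspots = hs,
    base_bucket_weights = rbind(large = c(1, 0, 0), medium = c(1, 0, 0),
                                small = c(1, 0, 0)))
  dep <- generate_deposition(pop, dom, cfg, seed = 1)
  expect_equal(length(unique(dep$cell)), 1L)
  expect_equal(unique(dep$region), "vestibule")

  # hot-spot centred outside the domain errors
  hs_bad <- hs; hs_bad$x_mm <- 1e4
  expect_error(
    generate_deposition(pop, dom, deposition_config(hotspots = hs_bad),
                        seed = 1),
    "outside the domain")
  expect_error(generate_deposition(pop[0, ], dom, seed = 1), "empty")
})

test_that("regional mass fractions follow the mass weights", {
  one <- data.frame(region = "septum", mass_kg = 2)
  expect_equal(regional_mass_fractions(one)$mass_percent, 100)
  two <- data.frame(region = c("septum", "olfactory"), mass_kg = c(1, 1))
  expect_equal(sort(regional_mass_fractions(two)$mass_percent), c(50, 50))
  expect_error(regional_mass_fractions(two[0, ]), "empty")
})

test_that("deposition CSV round-trips and rejects out-of-domain rows", {
  dom <- default_domain()
  pop <- build_droplet_population(spray_config(streams_per_bin = 3))
  dep <- generate_deposition(pop, dom, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_deposition_csv(dep, path)
  dep2 <- load_deposition_csv(path, dom)
  cols <- c("id", "d_um", "mass_kg", "x_mm", "y_mm", "cell", "region")
  expect_equal(as.data.frame(dep2)[, cols], as.data.frame(dep)[, cols],
               ignore_attr = TRUE)

  df <- utils::read.csv(path)
  df$x_mm[2] <- -50
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(dep3 <- load_deposition_csv(path, dom), "rejected 1")
  expect_equal(attr(dep3, "rejected"), 2L)
  expect_equal(nrow(dep3), nrow(dep) - 1L)
})

test_that("a handcrafted 3-row deposition file resolves regions by lookup", {
  dom <- default_domain()
  cells <- dom$cells
  pick <- c(which(cells$region == "vestibule")[1],
            which(cells$region == "septum")[1],
            which(cells$region == "nasopharynx")[1])
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,d_um,mass_kg,x_mm,y_mm",
    sprintf("%d,%g,%g,%g,%g", 1:3, c(80, 30, 5), c(1e-9, 2e-9, 3e-9),
            cells$x_mm[pick], cells$y_mm[pick])
  ), path)
  dep <- load_deposition_csv(path, dom)
  expect_equal(nrow(dep), 3L)
  expect_equal(dep$region, c("vestibule", "septum", "nasopharynx"))
  expect_equal(dep$cell, pick)
})
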