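# Geometry, history transport, tallies and conservation.

test_that("the phantom stack has the prescribed layer structure", {
  st <- build_stack()
  expect_equal(st$layers$name[1], "epidermis")
  expect_equal(st$layers$z_min_mm[1], 0)
  expect_equal(st$layers$z_max_mm - st$layers$z_min_mm,
               c(0.1, 1.0, 10, 100, 100))
  # contiguity
  expect_equal(st$layers$z_min_mm[-1],
               st$layers$z_max_mm[-nrow(st$layers)])

  pad <- make_pad_material("alginate", "none", 0)
  st10 <- build_stack(pad, 10)
  expect_equal(st10$layers$name[1], "pad")
  expect_equal(st10$layers$z_min_mm[1], -10)
  expect_equal(st10$layers$z_max_mm[1], 0)
  expect_error(build_stack(pad, -1), "positive")
  expect_error(layer_stack("a", list(pad), 0), "positive")
})

test_that("a vacuum-like slab transmits everything", {
  ghost <- material("ghost", 1e-8, composition_from_formula(c(H = 2, O = 1)))
  st <- layer_stack("void", list(ghost), 50)
  tl <- run_beam(beam_spec("photon", 300, 2e3, seed = 1), st, batches = 2)
  expect_equal(tl$escapes$mean_MeV[2], 0.3, tolerance = 1e-6)
  expect_equal(sum(tl$layers$mean_MeV), 0, tolerance = 1e-6)
})

test_that("narrow-beam transmission matches Beer-Lambert", {
  w <- water_material()
  st <- layer_stack("slab", list(w), 20)
  ph <- transport_physics(attenuation_only = TRUE)
  n <- 2e5
  tl <- run_beam(beam_spec("photon", 100, n, seed = 7), st, ph,
                 batches = 10)
  mu <- mu_over_rho(material_photon_model(w), 100)$total * w$density
  p_exp <- exp(-mu * 2)
  t_mc <- tl$escapes$mean_MeV[2] / 0.1
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(t_mc - p_exp), 3 * se)
})

test_that("tallies conserve energy exactly and reproduce under a seed", {
  st <- build_stack(make_pad_material("chitosan", "ZnO", 0.05), 2)
  tl <- run_beam(beam_spec("photon", 300, 5e3, seed = 13), st, batches = 5)
  cc <- conservation_check(tl)
  expect_lt(abs(cc$residual) / cc$beam_MeV, 1e-9)
  expect_true(all(tl$layers$mean_MeV >= 0))

  tl2 <- run_beam(beam_spec("photon", 300, 5e3, seed = 13), st, batches = 5)
  expect_identical(tl$layers$mean_MeV, tl2$layers$mean_MeV)
  expect_identical(tl$escapes$mean_MeV, tl2$escapes$mean_MeV)

  tl3 <- run_beam(beam_spec("photon", 300, 5e3, seed = 14), st, batches = 5)
  expect_false(identical(tl$layers$mean_MeV, tl3$layers$mean_MeV))
})

test_that("standard errors shrink like 1/sqrt(N)", {
  st <- build_stack()
  se1 <- run_beam(beam_spec("photon", 100, 2e4, seed = 5), st,
                  batches = 10)$layers$se_MeV[4]
  se2 <- run_beam(beam_spec("photon", 100, 8e4, seed = 5), st,
                  batches = 10)$layers$se_MeV[4]
  expect_gt(se1 / se2, 2 * 0.7)
  expect_lt(se1 / se2, 2 * 1.3)
})

test_that("300 keV electrons range out within the first millimetre", {
  tl <- run_beam(beam_spec("electron", 300, 1e4, seed = 21), build_stack(),
                 batches = 5)
  near_surface <- sum(tl$layers$mean_MeV[1:2])  # epidermis + dermis, 1.1 mm
  expect_gt(near_surface / 0.3, 0.90)
  # essentially nothing beyond the subcutaneous layer
  expect_lt(tl$layers$mean_MeV[4], 1e-3)
})

test_that("thick pads absorb electrons: range-out property", {
  # pad thickness >= 1.5 x CSDA range: transmitted electron energy < 0.1%
  pad <- make_pad_material("cellulose", "none", 0)
  r_mm <- csda_range(pad, 500)$r_mm
  st <- layer_stack(c("pad", "target"),
                    list(pad, tissue_material("muscle")),
                    c(1.5 * r_mm, 50))
  tl <- run_beam(beam_spec("electron", 500, 2e4, seed = 22), st,
                 batches = 5)
  transmitted <- tl$layers$mean_MeV[2] + tl$escapes$mean_MeV[2]
  expect_lt(transmitted / 0.5, 1e-3 + 0.002)  # bremsstrahlung-limited
})

test_that("electron backscatter grows with atomic number", {
  w <- layer_stack("slab", list(water_material()), 50)
  hz <- layer_stack("slab", list(library_material("Bi2O3")), 50)
  b_w <- run_beam(beam_spec("electron", 300, 2e4, seed = 23), w,
                  batches = 5)$escapes$mean_MeV[1]
  b_hz <- run_beam(beam_spec("electron", 300, 2e4, seed = 24), hz,
                   batches = 5)$escapes$mean_MeV[1]
  expect_gt(b_hz, b_w)
})

test_that("tally cutoff insensitivity in a fully absorbing geometry", {
  st <- layer_stack("slab", list(water_material()), 80)
  t5 <- run_beam(beam_spec("electron", 300, 1e4, seed = 25), st,
                 transport_physics(electron_cutoff_keV = 5), batches = 5)
  t20 <- run_beam(beam_spec("electron", 300, 1e4, seed = 26), st,
                  transport_physics(electron_cutoff_keV = 20), batches = 5)
  d5 <- t5$layers$mean_MeV[1]
  d20 <- t20$layers$mean_MeV[1]
  se <- sqrt(t5$layers$se_MeV[1]^2 + t20$layers$se_MeV[1]^2)
  expect_lt(abs(d5 - d20), 3 * se + 1e-4)
})

test_that("tally export carries the documented schema", {
  tl <- run_beam(beam_spec("photon", 100, 2e3, seed = 31), build_stack(),
                 batches = 2)
  f <- tempfile(fileext = ".csv")
  write_tally_csv(tl, f, id = "demo")
  df <- read.csv(f)
  expect_named(df, c("config", "layer", "mean_MeV", "se_MeV", "n",
                     "particle", "energy_keV"))
  expect_true(all(c("epidermis", "escape_upstream") %in% df$layer))
  unlink(f)
})
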