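# Stopping powers, ranges and the condensed-history step model.

test_that("collision stopping power matches the reference regime", {
  w <- water_material()
  expect_equal(collision_stopping(w, 1000), 1.85, tolerance = 0.05)
  # monotone decreasing over 100-1000 keV
  s <- collision_stopping(w, seq(100, 1000, by = 50))
  expect_true(all(diff(s) < 0))
  # mass-normalized: density does not enter
  w2 <- material("dense water", 2.5, w$composition)
  expect_identical(collision_stopping(w2, 500), collision_stopping(w, 500))
  expect_error(collision_stopping(w, 0.5), "outside")
  expect_error(collision_stopping(w, 5000), "outside")
})

test_that("radiative stopping scales with Z_eff and vanishes at low E", {
  w <- water_material()
  expect_lt(radiative_stopping(w, 2) / collision_stopping(w, 2), 1e-4)
  doped <- make_pad_material("alginate", "Bi2O3", 0.10)
  pure <- make_pad_material("alginate", "none", 0)
  for (E in c(100, 500, 1000)) {
    expect_gt(radiative_stopping(doped, E), radiative_stopping(pure, E))
  }
  # water radiative/collision ratio at 1 MeV is below one percent
  r <- radiative_stopping(w, 1000) / collision_stopping(w, 1000)
  expect_gt(r, 0.006)
  expect_lt(r, 0.011)
})

test_that("CSDA ranges integrate the stopping power", {
  w <- water_material()
  r <- csda_range(w, c(100, 300, 500, 1000))
  expect_true(all(diff(r$r_gcm2) > 0))
  expect_equal(r$r_gcm2[r$E_keV == 1000], 0.4367, tolerance = 0.10)
  # 300 keV range in water, in mm: consistent with sub-mm skin penetration
  r300 <- r$r_mm[r$E_keV == 300]
  expect_gt(r300, 0.75)
  expect_lt(r300, 0.95)
  # independent quadrature oracle at 500 keV
  oracle <- integrate(function(E) {
    1 / ((collision_stopping(w, E) + radiative_stopping(w, E)) * 1000)
  }, 1, 500, rel.tol = 1e-8)$value
  expect_equal(csda_range(w, 500)$r_gcm2, oracle, tolerance = 2e-3)
})

test_that("stopping table is exportable and internally consistent", {
  tab <- stopping_table(water_material())
  expect_named(tab, c("E_keV", "S_col", "S_rad", "R_csda_gcm2"))
  expect_true(all(tab$S_col > 0))
  expect_true(all(diff(tab$R_csda_gcm2) > 0))
  # R(E) consistent with the integral of 1/S_tot between grid nodes
  i <- 100
  dr <- tab$R_csda_gcm2[i + 1] - tab$R_csda_gcm2[i]
  quad <- integrate(function(E) {
    1 / ((collision_stopping(water_material(), E) +
          radiative_stopping(water_material(), E)) * 1000)
  }, tab$E_keV[i], tab$E_keV[i + 1], rel.tol = 1e-9)$value
  expect_equal(dr, quad, tolerance = 1e-4)
})

test_that("condensed steps conserve energy and scale correctly", {
  pad <- make_pad_material("cellulose", "none", 0)
  set.seed(11)
  st <- condensed_step(500, pad, 1e-3)
  expect_equal(st$de_local_keV + st$brems_keV + st$E_new_keV, 500,
               tolerance = 1e-12)
  # vanishing step: vanishing loss and deflection width
  tiny <- condensed_step(500, pad, 1e-9)
  expect_lt(tiny$de_local_keV, 1e-5)
  expect_lt(tiny$sigma_theta, st$sigma_theta)
  expect_error(condensed_step(500, pad, 0), "step length")

  # Highland width larger in the Bi2O3-doped pad (shorter X0)
  doped <- make_pad_material("cellulose", "Bi2O3", 0.10)
  s1 <- condensed_step(500, pad, 1e-3)$sigma_theta
  s2 <- condensed_step(500, doped, 1e-3)$sigma_theta
  expect_gt(s2, s1)

  # a full track in an unbounded absorber deposits exactly the initial
  # energy across local deposits and bremsstrahlung photons
  set.seed(12)
  E <- 300; dep <- 0; brems <- 0
  while (E > 10) {
    scol <- collision_stopping(pad, E) * 1000
    ds <- 0.05 * E / (scol * pad$density)
    st <- condensed_step(E, pad, ds)
    dep <- dep + st$de_local_keV
    brems <- brems + st$brems_keV
    E <- st$E_new_keV
  }
  expect_equal(dep + brems + E, 300, tolerance = 1e-9)
})
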