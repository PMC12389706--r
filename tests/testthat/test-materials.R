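# Compositions, mixture rules, pad composites and tissue library.

brute_formula <- function(counts, A) {
  # independent oracle: direct weighted sum with explicit atomic masses
  m <- counts * A
  m / sum(m)
}

test_that("formula compositions match brute-force mass arithmetic", {
  w <- composition_from_formula(c(H = 2, O = 1))
  exp_w <- brute_formula(c(2, 1), c(1.008, 15.999))
  expect_equal(unname(w[c("H", "O")]), exp_w, tolerance = 1e-12)
  expect_equal(w[["H"]], 0.1119, tolerance = 1e-3)

  expect_equal(composition_from_formula(c(Bi = 1))[["Bi"]], 1.0)

  bi <- composition_from_formula(c(Bi = 2, O = 3))
  exp_bi <- brute_formula(c(2, 3), c(208.980, 15.999))
  expect_equal(unname(bi[c("Bi", "O")]), exp_bi, tolerance = 1e-12)
  expect_equal(bi[["Bi"]], 0.897, tolerance = 1e-3)

  expect_error(composition_from_formula(c(Xx = 1)), "Xx")
  expect_error(composition_from_formula(c(H = 0, O = 1)), "counts")
})

test_that("mix_by_mass follows the mass-weighted and inverse-volume rules", {
  w <- water_material()
  cel <- library_material("cellulose")
  m <- mix_by_mass(list(w, cel), c(0.8, 0.2))
  # brute-force element-wise expectation
  for (s in names(m$composition)) {
    exp_s <- 0.8 * ifelse(s %in% names(w$composition), w$composition[s], 0) +
      0.2 * ifelse(s %in% names(cel$composition), cel$composition[s], 0)
    expect_equal(m$composition[[s]], unname(exp_s), tolerance = 1e-12)
  }
  expect_equal(m$density, 1 / (0.8 / 1.0 + 0.2 / 1.10), tolerance = 1e-12)
  expect_equal(m$density, 1.0185, tolerance = 1e-4)

  ident <- mix_by_mass(list(w), 1.0)
  expect_equal(ident$composition, w$composition, tolerance = 1e-12)
  expect_equal(ident$density, w$density)

  expect_error(mix_by_mass(list(w, cel), c(0.8, 0.3)), "sum")
})

test_that("mixing is associative in composition", {
  a <- water_material()
  b <- library_material("cellulose")
  c3 <- library_material("Bi2O3")
  two_step <- mix_by_mass(list(mix_by_mass(list(a, b), c(0.5, 0.5)), c3),
                          c(0.8, 0.2))
  direct <- mix_by_mass(list(a, b, c3), c(0.4, 0.4, 0.2))
  for (s in names(direct$composition)) {
    expect_equal(two_step$composition[[s]], direct$composition[[s]],
                 tolerance = 1e-12)
  }
})

test_that("pad materials reproduce the study recipe", {
  p <- make_pad_material("cellulose", "none", 0)
  expect_equal(p$density, 1.0185, tolerance = 1e-4)
  expect_equal(sum(p$composition), 1, tolerance = 1e-12)

  alg <- make_pad_material("alginate", "Bi2O3", 0.10)
  expect_equal(alg$composition[["Bi"]],
               0.10 * composition_from_formula(c(Bi = 2, O = 3))[["Bi"]],
               tolerance = 1e-12)
  expect_equal(alg$composition[["Bi"]], 0.0897, tolerance = 1e-3)

  chz <- make_pad_material("chitosan", "ZnO", 0.05)
  expect_equal(sum(chz$composition), 1, tolerance = 1e-12)

  # zero filler loading leaves the hydrogel unchanged
  g0 <- make_pad_material("alginate", "none", 0)
  expect_equal(make_pad_material("alginate", "ZnO", 0)$composition,
               g0$composition, tolerance = 1e-12)

  expect_error(make_pad_material("alginate", "ZnO", 0.6), "0.5")

  # monotonicity: more Bi2O3 means strictly more Bi in the pad
  wts <- c(0.02, 0.05, 0.08, 0.10, 0.2)
  wbi <- vapply(wts, function(f)
    make_pad_material("alginate", "Bi2O3", f)$composition[["Bi"]], 0)
  expect_true(all(diff(wbi) > 0))

  # density bracket for every grid pad
  for (pol in c("alginate", "chitosan", "cellulose")) {
    for (f in c(0.05, 0.10)) {
      pm <- make_pad_material(pol, "Bi2O3", f)
      expect_gt(pm$density, 1.0)
      expect_lt(pm$density, 8.90)
    }
  }
})

test_that("tissue library matches the phantom definitions", {
  expect_equal(tissue_material("backing")$composition,
               water_material()$composition)
  expect_equal(tissue_material("backing")$density, 1.0)
  mus <- tissue_material("muscle")
  expect_equal(sum(mus$composition), 1, tolerance = 1e-9)
  expect_gt(mus$density, 1.0)
  expect_lt(mus$density, 1.1)
  expect_error(tissue_material("bone"), "unknown tissue layer")
  # thickness is geometry's concern, not the material's
  expect_error(tissue_material("epidermis", thickness = 0.1))
})

test_that("effective parameters follow the mixture rules", {
  ep <- effective_params(water_material())
  expect_equal(ep$z_over_a, 0.555, tolerance = 1e-3)
  # hand check of Bragg additivity for water
  zoa <- 0.111907 * (1 / 1.008) + 0.888093 * (8 / 15.999)
  lni <- (0.111907 * (1 / 1.008) * log(19.2) +
          0.888093 * (8 / 15.999) * log(95)) / zoa
  expect_equal(ep$ln_I, lni, tolerance = 1e-6)

  # single-element material: parameters equal the element's
  bi <- material("bismuth", 9.78, c(Bi = 1))
  el <- element_data()
  row <- el[el$symbol == "Bi", ]
  expect_equal(effective_params(bi)$z_over_a, row$Z / row$A)
  expect_equal(effective_params(bi)$X0_gcm2, row$X0)

  # mixing a material with itself changes nothing
  w <- water_material()
  self <- mix_by_mass(list(w, w), c(0.5, 0.5))
  expect_equal(effective_params(self)$I_eff_eV, ep$I_eff_eV,
               tolerance = 1e-12)
})

test_that("invalid compositions and densities are rejected", {
  expect_error(material("x", -1, c(H = 1)), "density")
  expect_error(material("x", 1, c(H = 0.5, O = 0.6)), "sum")
  expect_error(material("x", 1, setNames(1, "Qq")), "Qq")
})
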