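# Photon cross-section tables, mixture models and interaction sampling.

test_that("embedded tables are valid and span the beam energies", {
  tb <- photon_tables()
  expect_true(all(diff(tb$energy_keV) > 0))
  expect_lte(min(tb$energy_keV), 10)
  expect_gte(max(tb$energy_keV), 2000)
  for (s in names(tb$elements)) {
    expect_true(all(tb$elements[[s]] > 0), info = s)
  }
  # Bi K edge represented by a duplicated-energy pair with a large jump
  gi <- which(abs(tb$energy_keV - 90.526) < 1e-2)
  expect_length(gi, 2)
  jump <- tb$elements$Bi[gi[2], "pe"] / tb$elements$Bi[gi[1], "pe"]
  expect_gt(jump, 3)
})

test_that("mixture rule holds at random energies", {
  set.seed(42)
  tb <- photon_tables()
  pad <- make_pad_material("cellulose", "Bi2O3", 0.10)
  model <- material_photon_model(pad, tb)
  E <- exp(runif(200, log(10.5), log(1999)))
  got <- mu_over_rho(model, E)
  exp_pe <- exp_inc <- exp_coh <- numeric(length(E))
  for (s in names(pad$composition)) {
    em <- material_photon_model(material(s, 1, setNames(1, s)), tb)
    p <- mu_over_rho(em, E)
    w <- pad$composition[[s]]
    exp_pe <- exp_pe + w * p$photoelectric
    exp_inc <- exp_inc + w * p$incoherent
    exp_coh <- exp_coh + w * p$coherent
  }
  expect_equal(got$photoelectric, exp_pe, tolerance = 1e-6)
  expect_equal(got$incoherent, exp_inc, tolerance = 1e-6)
  expect_equal(got$total, exp_pe + exp_inc + exp_coh, tolerance = 1e-6)
})

test_that("interpolation is exact on grid nodes and bounded to the span", {
  tb <- photon_tables()
  w <- material_photon_model(water_material(), tb)
  i <- c(5, 20, 30)
  got <- mu_over_rho(w, tb$energy_keV[i])
  expect_equal(got$photoelectric, w$pe[i], tolerance = 1e-12)
  expect_equal(got$total, w$total[i], tolerance = 1e-12)
  expect_error(mu_over_rho(w, 5), "span")
  expect_error(mu_over_rho(w, 2500), "span")

  # water at 100 keV equals the H/O element-weighted sum
  h <- mu_over_rho(material_photon_model(material("h", 1, c(H = 1)), tb), 100)
  o <- mu_over_rho(material_photon_model(material("o", 1, c(O = 1)), tb), 100)
  wf <- composition_from_formula(c(H = 2, O = 1))
  expect_equal(mu_over_rho(w, 100)$total,
               wf[["H"]] * h$total + wf[["O"]] * o$total, tolerance = 1e-9)
})

test_that("photoelectric regime scaling holds away from edges", {
  tb <- photon_tables()
  bi <- material_photon_model(library_material("Bi2O3"), tb)
  # E^-3 regime check on the edge-free interval above the Bi K edge
  r <- mu_over_rho(bi, 100)$photoelectric / mu_over_rho(bi, 200)$photoelectric
  expect_gt(r, 8 / 3)
  expect_lt(r, 8 * 3)
  # photoelectric share at 50 keV strictly exceeds that at 1000 keV for
  # every pad material in the study grid
  for (pol in c("alginate", "chitosan", "cellulose")) {
    for (fs in list(c("none", 0), c("ZnO", 0.10), c("Bi2O3", 0.10))) {
      m <- material_photon_model(
        make_pad_material(pol, fs[[1]], as.numeric(fs[[2]])), tb)
      lo <- mu_over_rho(m, 50)
      hi <- mu_over_rho(m, 1000)
      expect_gt(lo$photoelectric / lo$total, hi$photoelectric / hi$total)
    }
  }
})

test_that("path lengths are exponential with the right mean", {
  w <- material_photon_model(water_material())
  mu <- mu_over_rho(w, 100)$total * 1.0
  set.seed(1)
  d <- sample_path_length(w, 100, n = 1e6)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 1 / mu), 3 * se)
  expect_lt(median(d), log(2) / mu * 1.01)
  set.seed(9)
  a <- sample_path_length(w, 100, n = 100)
  set.seed(9)
  b <- sample_path_length(w, 100, n = 100)
  expect_identical(a, b)
})

test_that("interaction selection follows the partial fractions", {
  tb <- photon_tables()
  pad <- material_photon_model(make_pad_material("alginate", "Bi2O3", 0.10),
                               tb)
  p <- mu_over_rho(pad, 50)
  set.seed(3)
  draws <- select_interaction(pad, 50, n = 2e5)
  f_pe <- mean(draws == "photoelectric")
  exp_pe <- p$photoelectric / p$total
  se <- sqrt(exp_pe * (1 - exp_pe) / 2e5)
  expect_lt(abs(f_pe - exp_pe), 3 * se)
  # Bi2O3-rich pad at 50 keV: photoelectric dominates incoherent
  expect_gt(f_pe, mean(draws == "incoherent"))
  # disabled coherent channel never fires
  expect_false(any(select_interaction(pad, 50, 1e4,
                                      include_coherent = FALSE) == "coherent"))
})

test_that("Compton sampling matches the Klein-Nishina oracle", {
  # closed-form backscatter: 511 keV at 180 degrees -> 511/3
  a <- 1  # 511/511
  expect_equal(511 / (1 + a * 2), 511 / 3, tolerance = 1e-12)

  set.seed(5)
  s <- sample_compton(100, n = 1e6)
  # exact energy conservation per sample
  expect_equal(s$E_scattered + s$E_electron, rep(100, 1e6),
               tolerance = 1e-12)
  expect_true(all(s$cos_theta_photon >= -1 & s$cos_theta_photon <= 1))
  expect_true(all(s$E_scattered <= 100 + 1e-9))
  expect_true(all(s$E_scattered >= 100 / (1 + 2 * 100 / 511) - 1e-9))

  # quadrature oracle for the mean scattered fraction
  alpha <- 100 / 511
  eps <- function(mu) 1 / (1 + alpha * (1 - mu))
  wfun <- function(mu) {
    e <- eps(mu)
    e^2 * (e + 1 / e - (1 - mu^2))
  }
  num <- integrate(function(mu) eps(mu) * wfun(mu), -1, 1,
                   rel.tol = 1e-10)$value
  den <- integrate(wfun, -1, 1, rel.tol = 1e-10)$value
  oracle <- num / den
  got <- mean(s$E_scattered / 100)
  se <- sd(s$E_scattered / 100) / sqrt(nrow(s))
  expect_lt(abs(got - oracle), 3 * se)
})

test_that("photoelectric events conserve energy and emit K X-rays at the
           fluorescence yield", {
  tb <- photon_tables()
  bi <- material_photon_model(material("bismuth", 9.78, c(Bi = 1)), tb)
  set.seed(6)
  ev <- photoelectric_event(bi, 200, n = 1e5)
  expect_equal(ev$E_electron + ev$E_fluorescence + ev$E_local,
               rep(200, 1e5), tolerance = 1e-12)
  el <- element_data()
  row <- el[el$symbol == "Bi", ]
  p_fl <- row$f_K * row$omega_K
  f <- mean(ev$E_fluorescence > 0)
  se <- sqrt(p_fl * (1 - p_fl) / 1e5)
  expect_lt(abs(f - p_fl), 3 * se)
  # fluorescent X-rays carry the mean K X-ray energy
  expect_equal(unique(ev$E_fluorescence[ev$E_fluorescence > 0]), row$e_Kx)

  # below every K edge in the material: no fluorescence at all
  ev_lo <- photoelectric_event(bi, 50, n = 2e4)
  expect_true(all(ev_lo$E_fluorescence == 0))
})

test_that("coherent angles are Thomson distributed", {
  set.seed(7)
  mu <- sample_coherent_angle(n = 2e5)
  expect_true(all(mu >= -1 & mu <= 1))
  se <- sd(mu) / sqrt(length(mu))
  expect_lt(abs(mean(mu)), 3 * se)
  # variance of (1+mu^2)-weighted distribution: E[mu^2] = 2/5 exactly
  expect_equal(mean(mu^2), 0.4, tolerance = 0.01)
})
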