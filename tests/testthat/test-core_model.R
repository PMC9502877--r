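test_that("Lennard-Jones parameters follow the critical-property estimates", {
  expect_equal(lj_params(compound("x", 1, 1.2593, 1))$sigma_lj, 0.7889e-8)
  expect_equal(lj_params(compound("x", 1, 1.2593, 1))$eps_kb, 1.0)
  expect_equal(lj_params(compound("x", 1, 300, 100))$sigma_lj,
               3.66174943084e-8, tolerance = 1e-10)
  expect_error(compound("x", 1, 300, -1), "positive")
})

test_that("binary combining rules: corrected arithmetic mean and geometric mean", {
  b <- binary_lj(3e-8, 3e-8, 100, 100, k12 = 0)
  expect_equal(b$sigma12, 3e-8)
  expect_equal(binary_lj(3e-8, 5e-8, 1, 1, k12 = 0.1)$sigma12, 3.6e-8)
  expect_equal(binary_lj(1, 1, 100, 400)$eps12, 200)
  expect_error(binary_lj(3e-8, 5e-8, 1, 1, k12 = 1), "k12")
})

test_that("reduced temperature is a plain ratio", {
  expect_equal(reduced_temperature(150, 150), 1.0)
  expect_equal(reduced_temperature(300, 150), 2.0)
  expect_equal(reduced_temperature(313.15, 241.51), 1.29663367976, tolerance = 1e-10)
  expect_error(reduced_temperature(-1, 150), "positive")
})

test_that("effective diameter: exact zero-temperature limit, frozen values, monotone decrease", {
  expect_equal(effective_diameter(2e-8, 0), 1.1532 * 2e-8)
  # frozen from a 40-digit mpmath evaluation of the same expression
  expect_equal(effective_diameter(1, 1), 0.998200880269, tolerance = 1e-10)
  expect_equal(effective_diameter(1, 2), 0.963048565069, tolerance = 1e-10)
  ts <- seq(0, 6, by = 0.05)
  expect_true(all(diff(effective_diameter(3e-8, ts)) < 0))
  expect_error(effective_diameter(3e-8, -0.1), ">= 0")
})

test_that("solvent structure chain: number density, reduced density, packing fraction", {
  st <- solvent_structure(0.6, 44.01, 3.6e-8)
  expect_equal(st$rho_n1, 8.21013865031e21, tolerance = 1e-10)
  st2 <- solvent_structure(8.2102e21 * 44.01 / d12_constants()$avogadro, 44.01, 3.6e-8)
  expect_equal(st2$rho_star, 0.3830550912, tolerance = 1e-9)
  expect_equal(st2$phi, 0.200567176739, tolerance = 1e-9)
  expect_identical(st$phi, pi / 6 * st$rho_star)
  z <- solvent_structure(0, 44.01, 3.6e-8)
  expect_equal(unlist(z), c(rho_n1 = 0, rho_star = 0, phi = 0))
})

test_that("contact value: dilute limit, Carnahan-Starling reduction, large-solute limit", {
  expect_equal(contact_rdf(0, 1, 1), 1.0)
  for (phi in seq(0.1, 0.5, by = 0.1))
    expect_equal(contact_rdf(phi, 2e-8, 2e-8), (1 - phi / 2) / (1 - phi)^3,
                 tolerance = 1e-12)
  expect_equal(contact_rdf(0.3, 1, 1e12), (1 + 0.3) / (1 - 0.3)^3, tolerance = 1e-9)
  expect_error(contact_rdf(1, 1, 1), "phi")
})

test_that("contact value equals the MCSL three-term expansion (algebraic identity)", {
  phis <- seq(0, 0.6, length.out = 20)
  ratios <- exp(seq(log(0.1), log(10), length.out = 20))
  for (phi in phis) for (ra in ratios) {
    r <- 1 / (1 + 1 / ra)  # sigma1 = 1, sigma2 = ra
    mcsl <- 1 / (1 - phi) + 3 * phi * r / (1 - phi)^2 + 2 * phi^2 * r^2 / (1 - phi)^3
    expect_equal(contact_rdf(phi, 1, ra), mcsl, tolerance = 1e-12)
  }
})

test_that("self-diffusion correction factor F11: dilute limit and dense-regime sign change", {
  expect_equal(f11(0), 1.0)
  expect_equal(f11(1), 0.32105, tolerance = 1e-12)
  # frozen from high-precision evaluation of the printed polynomial
  expect_equal(f11(1.1), -0.0170492756475, tolerance = 1e-9)
  expect_true(f11(1.1) < 0)
  expect_true(all(f11(seq(0, 1, by = 0.01)) > 0))
})

test_that("binary correction factor F12: symmetric and dilute limits, frozen asymmetric value", {
  expect_equal(f12(0.5, 3e-8, 3e-8, 1e-22, 1e-22), f11(0.5))
  expect_equal(f12(0, 3e-8, 6e-8, 1e-22, 5e-22), 1.0)
  # frozen from an independent step-by-step mpmath evaluation
  expect_equal(f12(0.5, 1e-8, 2e-8, 1e-22, 2e-22), 2.17537582044, tolerance = 1e-10)
  det <- f12(0.5, 1e-8, 2e-8, 1e-22, 2e-22, details = TRUE)
  expect_equal(det$coeff_a, -1.676382 * 0.5 + 1.638561)
  expect_equal(det$coeff_d, -5.062546 * 0.5 + 5.409662)
})

test_that("reduced mass: equal-mass and disparate-mass limits, molar example", {
  expect_equal(reduced_mass(2e-23, 2e-23), 1e-23)
  expect_equal(reduced_mass(1e-26, 1e-20), 1e-26, tolerance = 1e-6)
  NAv <- d12_constants()$avogadro
  expect_equal(reduced_mass(44.01 / NAv, 46.07 / NAv), 3.73758083089e-23,
               tolerance = 1e-10)
})

test_that("predict_d12 reproduces the frozen CO2/benzene chained-arithmetic value", {
  p <- predict_d12(fix_co2(), fix_benzene(), state_points(313.15, 0.7),
                   model_params(0, 1))
  # frozen from the 40-digit mpmath oracle run before implementation
  expect_equal(p$d12, 5.9365339834323e-5, tolerance = 1e-12)
  expect_equal(p$rho_star, 0.42333390366547, tolerance = 1e-12)
  expect_equal(p$g12, 2.0046363061951, tolerance = 1e-12)
  expect_equal(p$f12, 1.6226881659752, tolerance = 1e-12)
  expect_equal(p$sigma_eff_12, 4.3005614941765e-8, tolerance = 1e-12)
  expect_true(p$valid)
})

test_that("predict_d12 structural limits: pure hard-sphere B12 = 0 and B12 monotonicity", {
  st <- state_points(313.15, 0.7)
  p0 <- predict_d12(fix_co2(), fix_benzene(), st, model_params(0, 0))
  expect_equal(p0$d12, d12_constants()$boltzmann * 313.15 / p0$xi_hard)
  expect_identical(p0$xi_soft, 0)
  p1 <- predict_d12(fix_co2(), fix_benzene(), st, model_params(0, 1))
  p2 <- predict_d12(fix_co2(), fix_benzene(), st, model_params(0, 2))
  expect_true(p2$d12 < p1$d12 && p1$d12 < p0$d12)
})

test_that("predict_d12 matches the independent oracle on 100 seeded random valid inputs", {
  set.seed(2024)
  n_checked <- 0
  while (n_checked < 100) {
    M1 <- runif(1, 16, 400); Tc1 <- runif(1, 150, 800); Vc1 <- runif(1, 50, 900)
    M2 <- runif(1, 16, 1000); Tc2 <- runif(1, 150, 900); Vc2 <- runif(1, 50, 1100)
    T <- runif(1, 280, 700); k12 <- runif(1, -0.3, 0.3); B12 <- runif(1, 0, 5)
    solv <- compound("s", M1, Tc1, Vc1); solu <- compound("u", M2, Tc2, Vc2)
    rho_target <- runif(1, 0.05, 0.95)
    rho1 <- fix_density_for_rho_star(solv, T, rho_target)
    o <- oracle_d12(M1, Tc1, Vc1, M2, Tc2, Vc2, T, rho1, k12, B12)
    if (o$f11 <= 0 || o$f12 <= 0) next
    p <- predict_d12(solv, solu, state_points(T, rho1), model_params(k12, B12))
    expect_equal(p$d12, o$d12, tolerance = 1e-10)
    expect_equal(p$f12, o$f12, tolerance = 1e-10)
    expect_equal(p$g12, o$g12, tolerance = 1e-10)
    n_checked <- n_checked + 1
  }
  expect_identical(n_checked, 100)
})

test_that("d12 decreases with solvent density and stays in a physical range", {
  rhos <- seq(0.2, 0.95, by = 0.05)
  p <- predict_d12(fix_co2(), fix_benzene(),
                   state_points(rep(313.15, length(rhos)), rhos),
                   model_params(0.05, 1.5))
  expect_true(all(p$valid))
  expect_true(all(diff(p$d12) < 0))
  expect_true(all(p$d12 > 1e-7 & p$d12 < 1e-2))
  # liquid fixtures too: ethanol in water near ambient
  pw <- predict_d12(fix_water(), fix_ethanol(),
                    state_points(c(298.15, 323.15), c(0.997, 0.988)),
                    model_params(0, 1))
  expect_true(all(pw$d12 > 1e-7 & pw$d12 < 1e-2))
})

test_that("non-physical correction factors flag the prediction instead of clamping it", {
  t <- 313.15
  rho_bad <- fix_density_for_rho_star(fix_co2(), t, 1.1)
  p <- predict_d12(fix_co2(), fix_benzene(), state_points(t, rho_bad),
                   model_params(0, 1))
  expect_false(p$valid)
  expect_true(p$f11 < 0)
  expect_error(predict_d12(fix_co2(), fix_benzene(),
                           state_points(t, fix_density_for_rho_star(fix_co2(), t, 2.0)),
                           model_params(0, 1)),
               "packing fraction")
})
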