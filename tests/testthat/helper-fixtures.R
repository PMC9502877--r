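# Shared fixture builders: real compound properties used across tests.
fix_co2 <- function() compound("CO2", 44.01, 304.13, 94.07)
fix_benzene <- function() compound("benzene", 78.11, 562.0, 256.0)
fix_water <- function() compound("water", 18.015, 647.1, 55.95)
fix_ethanol <- function() compound("ethanol", 46.07, 513.9, 167.0)

# A noiseless system at known parameters: CO2/benzene over a density and
# temperature sweep in the supercritical regime.
fix_noiseless_system <- function(k12 = 0.05, B12 = 1.5, n = 20) {
  temp <- seq(308.15, 333.15, length.out = n)
  rho <- seq(0.45, 0.95, length.out = n)
  st <- state_points(temp, rho)
  pred <- predict_d12(fix_co2(), fix_benzene(), st, model_params(k12, B12))
  st$d12_exp <- pred$d12
  measurement_set(fix_co2(), fix_benzene(), st, "scco2")
}

# Density giving an exact target rho* for a solvent at temperature t.
fix_density_for_rho_star <- function(solvent, t, rho_star) {
  lj <- lj_params(solvent)
  se1 <- effective_diameter(lj$sigma_lj, reduced_temperature(t, lj$eps_kb))
  rho_star * solvent$molar_mass / (d12_constants()$avogadro * se1^3)
}
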