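#' Lennard-Jones parameters from critical properties
#'
#' Estimates the Lennard-Jones diameter and energy of a pure component from
#' its critical volume and temperature:
#' sigma_LJ = 0.7889e-8 Vc^(1/3) cm (Vc in cm^3/mol) and
#' eps/kB = Tc / 1.2593 K.
#'
#' @param comp A [compound()].
#' @return Named list with `sigma_lj` (cm) and `eps_kb` (K).
#' @export
#' @examples
#' lj_params(compound("CO2", 44.01, 304.13, 94.07))
lj_params <- function(comp) {
  stopifnot(inherits(comp, "d12_compound"))
  list(sigma_lj = 0.7889e-8 * comp$critical_volume^(1 / 3),
       eps_kb = comp$critical_temperature / 1.2593)
}

#' Binary Lennard-Jones parameters
#'
#' Combining rules for the unlike pair: the arithmetic-mean diameter is
#' corrected by the binary interaction parameter k12,
#' sigma12 = (1 - k12)(sigma1 + sigma2)/2, and the energy is the geometric
#' mean, eps12 = sqrt(eps1 eps2).
#'
#' @param sigma1,sigma2 Pure-component LJ diameters, cm.
#' @param eps1,eps2 Pure-component LJ energies, K.
#' @param k12 Binary interaction parameter, k12 < 1.
#' @return Named list with `sigma12` (cm) and `eps12` (K).
#' @export
binary_lj <- function(sigma1, sigma2, eps1, eps2, k12 = 0) {
  if (any(c(sigma1, sigma2, eps1, eps2) <= 0))
    stop("LJ diameters and energies must be positive", call. = FALSE)
  if (k12 >= 1) stop("k12 must be < 1 (binary diameter would be non-positive)", call. = FALSE)
  list(sigma12 = (1 - k12) * (sigma1 + sigma2) / 2,
       eps12 = sqrt(eps1 * eps2))
}

#' Reduced temperature
#'
#' T* = T / (eps/kB), applied with the pure-component energy (j = 1, 2) or
#' the binary energy (j = 12).
#'
#' @param t Temperature, K (vectorised).
#' @param eps_kb LJ energy parameter, K.
#' @return Dimensionless reduced temperature.
#' @export
reduced_temperature <- function(t, eps_kb) {
  if (any(t <= 0) || any(eps_kb <= 0))
    stop("temperature and eps_kb must be positive", call. = FALSE)
  t / eps_kb
}

#' Effective hard-sphere diameter (Ben-Amotz--Herschbach)
#'
#' Maps a soft Lennard-Jones interaction onto an equivalent rigid sphere
#' whose diameter shrinks with temperature:
#' sigma_eff = 1.1532 sigma_LJ \[1 + (1.8975 T*)^(1/2)\]^(-1/6).
#' Strictly decreasing in T*; at T* = 0 the ratio to sigma_LJ is exactly
#' 1.1532.
#'
#' @param sigma_lj LJ diameter, cm.
#' @param t_star Reduced temperature, dimensionless, >= 0 (vectorised).
#' @return Effective diameter, cm.
#' @export
effective_diameter <- function(sigma_lj, t_star) {
  if (any(t_star < 0)) stop("t_star must be >= 0", call. = FALSE)
  1.1532 * sigma_lj * (1 + sqrt(1.8975 * t_star))^(-1 / 6)
}

#' Solvent number density, reduced density and packing fraction
#'
#' Converts the solvent mass density to a number density,
#' rho_n1 = rho1 N_A / M1 (molecules/cm^3), then scales by the cube of the
#' solvent effective diameter to the reduced number density
#' rho* = rho_n1 sigma_eff1^3 and the packing fraction phi = (pi/6) rho*.
#'
#' @param rho1 Solvent mass density, g/cm^3 (vectorised).
#' @param molar_mass1 Solvent molar mass, g/mol.
#' @param sigma_eff_1 Solvent effective diameter, cm (vectorised with rho1).
#' @return Named list with `rho_n1` (cm^-3), `rho_star`, `phi`.
#' @export
solvent_structure <- function(rho1, molar_mass1, sigma_eff_1) {
  if (any(rho1 < 0) || molar_mass1 <= 0 || any(sigma_eff_1 <= 0))
    stop("density must be >= 0 and mass/diameter positive", call. = FALSE)
  rho_n1 <- rho1 * .NAvogadro / molar_mass1
  rho_star <- rho_n1 * sigma_eff_1^3
  list(rho_n1 = rho_n1, rho_star = rho_star, phi = pi / 6 * rho_star)
}

#' Binary contact radial distribution function
#'
#' Value of the solvent-solute pair correlation function at sphere contact
#' for a tracer solute in a hard-sphere solvent. With
#' r = 1 / (1 + sigma_eff1/sigma_eff2),
#' g12 = (1 - phi + 2 phi r)(1 - phi + phi r) / (1 - phi)^3,
#' which expands to the infinite-dilution Mansoori-Carnahan-Starling-Leland
#' contact value and reduces to the Carnahan-Starling form
#' (1 - phi/2)/(1 - phi)^3 for equal diameters.
#'
#' @param phi Solvent packing fraction, 0 <= phi < 1 (vectorised).
#' @param sigma_eff_1,sigma_eff_2 Effective diameters of solvent and solute, cm.
#' @return Dimensionless contact value, >= 1.
#' @export
contact_rdf <- function(phi, sigma_eff_1, sigma_eff_2) {
  if (any(phi < 0) || any(phi >= 1))
    stop("packing fraction must satisfy 0 <= phi < 1", call. = FALSE)
  r <- 1 / (1 + sigma_eff_1 / sigma_eff_2)
  (1 - phi + 2 * phi * r) * (1 - phi + phi * r) / (1 - phi)^3
}

#' Dense-fluid correction factor for solvent self-diffusion
#'
#' Polynomial correction F11 to the Enskog self-diffusion friction of the
#' solvent, as a function of its reduced number density:
#' F11 = 1 + 0.94605 rho*^1.5 + 1.4022 rho*^3 - 5.6898 rho*^5
#'       + 2.6626 rho*^7.
#' The polynomial turns negative slightly above rho* = 1; such values are
#' non-physical and are flagged downstream (never clamped here).
#'
#' @param rho_star Reduced number density, >= 0 (vectorised).
#' @return Dimensionless correction factor (may be <= 0).
#' @export
#' @examples
#' f11(c(0, 0.5, 1))
f11 <- function(rho_star) {
  if (any(rho_star < 0)) stop("rho_star must be >= 0", call. = FALSE)
  1 + 0.94605 * rho_star^1.5 + 1.4022 * rho_star^3 -
    5.6898 * rho_star^5 + 2.6626 * rho_star^7
}

#' Dense-fluid correction factor for binary diffusion
#'
#' Extends [f11()] to the unlike pair with a size/mass asymmetry correction.
#' With L = ln(sigma_eff2/sigma_eff1) and Q = ln(m2/m1),
#' F12 = F11 + rho*^1.7 (a L + b L^2 + c Q) / (1 + rho*^3 d L^2),
#' where a, b, c, d are linear functions of rho*.
#'
#' @param rho_star Solvent reduced number density, >= 0 (vectorised).
#' @param sigma_eff_1,sigma_eff_2 Effective diameters, cm.
#' @param m1,m2 Molecular masses of solvent and solute, g.
#' @param details If `TRUE`, also return the a, b, c, d coefficients.
#' @return F12 (dimensionless), or a list with `f12` and the coefficients.
#' @export
f12 <- function(rho_star, sigma_eff_1, sigma_eff_2, m1, m2, details = FALSE) {
  if (any(rho_star < 0)) stop("rho_star must be >= 0", call. = FALSE)
  if (any(c(sigma_eff_1, sigma_eff_2, m1, m2) <= 0))
    stop("diameters and masses must be positive", call. = FALSE)
  L <- log(sigma_eff_2 / sigma_eff_1)
  Q <- log(m2 / m1)
  a <- -1.676382 * rho_star + 1.638561
  b <- -8.516830 * rho_star + 8.631536
  cc <- -1.320347 * rho_star + 1.351067
  d <- -5.062546 * rho_star + 5.409662
  val <- f11(rho_star) +
    rho_star^1.7 * (a * L + b * L^2 + cc * Q) / (1 + rho_star^3 * d * L^2)
  if (details) list(f12 = val, coeff_a = a, coeff_b = b, coeff_c = cc, coeff_d = d)
  else val
}

#' Reduced mass of the solvent-solute pair
#'
#' m12 = m1 m2 / (m1 + m2), in g/molecule.
#'
#' @param m1,m2 Molecular masses, g.
#' @return Reduced mass, g.
#' @export
reduced_mass <- function(m1, m2) {
  if (any(m1 <= 0) || any(m2 <= 0)) stop("masses must be positive", call. = FALSE)
  m1 * m2 / (m1 + m2)
}

#' Predict tracer diffusion coefficients
#'
#' Evaluates the full correlation for a solvent/solute pair at one or more
#' state points. The friction coefficient is split into a hard-core part,
#' xi_H = (8/3) rho_n1 sigma_eff12^2 sqrt(2 pi m12 kB T) g12 F12,
#' and a soft attractive part of identical prefactor with B12 / T12*^1.5
#' replacing g12 F12; the diffusivity is D12 = kB T / (xi_H + xi_S).
#' Every intermediate quantity of the property chain is returned, one row
#' per state point, so the computation is fully inspectable.
#'
#' State points where the dense-fluid correction factors F11 or F12 are
#' non-positive lie outside the physical domain of the correlation; they are
#' flagged `valid = FALSE` (D12 is still reported, never clamped).
#'
#' @param solvent,solute [compound()] objects.
#' @param states A [state_points()] table (or data.frame with columns
#'   `temperature` and `solvent_density`).
#' @param params A [model_params()] object.
#' @return A data.frame with one row per state point: the inputs, all
#'   intermediates (`sigma_lj_*`, `eps_kb_*`, `t_star_*`, `sigma_eff_*`,
#'   `m_1`, `m_2`, `m_12`, `rho_n1`, `rho_star`, `phi`, `g12`, `f11`, `f12`,
#'   `coeff_a`..`coeff_d`, `xi_hard`, `xi_soft`), the prediction `d12`
#'   (cm^2/s) and the `valid` flag.
#' @export
#' @examples
#' co2 <- compound("CO2", 44.01, 304.13, 94.07)
#' benzene <- compound("benzene", 78.11, 562.0, 256.0)
#' predict_d12(co2, benzene, state_points(313.15, 0.7), model_params(0, 1))
predict_d12 <- function(solvent, solute, states, params) {
  stopifnot(inherits(solvent, "d12_compound"), inherits(solute, "d12_compound"),
            inherits(states, "data.frame"))
  if (!inherits(params, "d12_params")) params <- model_params(params[[1]], params[[2]])

  t <- states$temperature
  rho1 <- states$solvent_density

  lj1 <- lj_params(solvent)
  lj2 <- lj_params(solute)
  bin <- binary_lj(lj1$sigma_lj, lj2$sigma_lj, lj1$eps_kb, lj2$eps_kb, params$k12)

  t1 <- reduced_temperature(t, lj1$eps_kb)
  t2 <- reduced_temperature(t, lj2$eps_kb)
  t12 <- reduced_temperature(t, bin$eps12)

  se1 <- effective_diameter(lj1$sigma_lj, t1)
  se2 <- effective_diameter(lj2$sigma_lj, t2)
  se12 <- effective_diameter(bin$sigma12, t12)

  m1 <- solvent$molar_mass / .NAvogadro
  m2 <- solute$molar_mass / .NAvogadro
  m12 <- reduced_mass(m1, m2)

  st <- solvent_structure(rho1, solvent$molar_mass, se1)
  if (any(st$phi >= 1))
    stop("packing fraction >= 1: state outside any physical regime", call. = FALSE)

  g12 <- contact_rdf(st$phi, se1, se2)
  F11v <- f11(st$rho_star)
  F12l <- f12(st$rho_star, se1, se2, m1, m2, details = TRUE)

  pref <- (8 / 3) * st$rho_n1 * se12^2 * sqrt(2 * pi * m12 * .kB * t)
  xi_hard <- pref * g12 * F12l$f12
  xi_soft <- pref * params$B12 / t12^1.5
  d12 <- .kB * t / (xi_hard + xi_soft)

  out <- data.frame(
    temperature = t, solvent_density = rho1,
    sigma_lj_1 = lj1$sigma_lj, sigma_lj_2 = lj2$sigma_lj, sigma_lj_12 = bin$sigma12,
    eps_kb_1 = lj1$eps_kb, eps_kb_2 = lj2$eps_kb, eps_kb_12 = bin$eps12,
    t_star_1 = t1, t_star_2 = t2, t_star_12 = t12,
    sigma_eff_1 = se1, sigma_eff_2 = se2, sigma_eff_12 = se12,
    m_1 = m1, m_2 = m2, m_12 = m12,
    rho_n1 = st$rho_n1, rho_star = st$rho_star, phi = st$phi,
    g12 = g12, f11 = F11v, f12 = F12l$f12,
    coeff_a = F12l$coeff_a, coeff_b = F12l$coeff_b,
    coeff_c = F12l$coeff_c, coeff_d = F12l$coeff_d,
    xi_hard = xi_hard, xi_soft = xi_soft,
    d12 = d12,
    valid = F11v > 0 & F12l$f12 > 0)
  if (!is.null(states$pressure)) out$pressure <- states$pressure
  if (!is.null(states$d12_exp)) out$d12_exp <- states$d12_exp
  out
}
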