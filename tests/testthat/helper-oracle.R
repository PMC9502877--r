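# Independent straight-line oracle for the full property chain and D12.
# Deliberately written as scalar, step-by-step arithmetic (no calls into the
# package) so it can disagree with the implementation. The contact value is
# computed through the three-term Mansoori-Carnahan-Starling-Leland
# expansion, i.e. a different algebraic route than the package's product
# form.
oracle_d12 <- function(M1, Tc1, Vc1, M2, Tc2, Vc2, T, rho1, k12, B12) {
  kB <- 1.380658e-16
  NAv <- 6.0221367e23

  s1 <- 0.7889e-8 * Vc1^(1 / 3)
  s2 <- 0.7889e-8 * Vc2^(1 / 3)
  e1 <- Tc1 / 1.2593
  e2 <- Tc2 / 1.2593
  s12 <- (1 - k12) * (s1 + s2) / 2
  e12 <- sqrt(e1 * e2)

  t1 <- T / e1
  t2 <- T / e2
  t12 <- T / e12

  bah <- function(s, ts) 1.1532 * s * (1 + (1.8975 * ts)^0.5)^(-1 / 6)
  se1 <- bah(s1, t1)
  se2 <- bah(s2, t2)
  se12 <- bah(s12, t12)

  m1 <- M1 / NAv
  m2 <- M2 / NAv
  m12 <- m1 * m2 / (m1 + m2)

  rn1 <- rho1 * NAv / M1
  rs <- rn1 * se1 * se1 * se1
  phi <- pi / 6 * rs

  # MCSL infinite-dilution contact value, three-term expansion
  r <- se2 / (se1 + se2)
  g <- 1 / (1 - phi) + 3 * phi * r / (1 - phi)^2 + 2 * phi^2 * r^2 / (1 - phi)^3

  F11o <- 1 + 0.94605 * rs^1.5 + 1.4022 * rs^3 - 5.6898 * rs^5 + 2.6626 * rs^7
  L <- log(se2 / se1)
  Q <- log(m2 / m1)
  a <- -1.676382 * rs + 1.638561
  b <- -8.516830 * rs + 8.631536
  cc <- -1.320347 * rs + 1.351067
  d <- -5.062546 * rs + 5.409662
  F12o <- F11o + rs^1.7 * (a * L + b * L^2 + cc * Q) / (1 + rs^3 * d * L^2)

  pref <- 8 / 3 * rn1 * se12^2 * sqrt(2 * pi * m12 * kB * T)
  xiH <- pref * g * F12o
  xiS <- pref * B12 / t12^1.5
  list(d12 = kB * T / (xiH + xiS), f11 = F11o, f12 = F12o, g12 = g,
       rho_star = rs, phi = phi)
}
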