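---
title: "Modelling tracer diffusion in dense solvents with tracerD12"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tracer diffusion in dense solvents with tracerD12}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracerD12)
```

## The physical model

A tracer solute (component 2) at infinite dilution in a dense solvent
(component 1) diffuses according to the Einstein relation D12 = kB·T/ξ.
The friction ξ is decomposed into a hard-core collisional part and a soft
attractive part,

$$\xi = \xi_H + \xi_S, \qquad
\xi_H = \tfrac{8}{3}\,\rho_{n,1}\,\sigma_{\mathrm{eff},12}^2
\sqrt{2\pi m_{12} k_B T}\; g(\sigma_{\mathrm{eff},12})\,F_{12}, \qquad
\xi_S = \tfrac{8}{3}\,\rho_{n,1}\,\sigma_{\mathrm{eff},12}^2
\sqrt{2\pi m_{12} k_B T}\; \frac{B_{12}}{T_{12}^{*1.5}},$$

so that

$$D_{12} = \frac{k_B T}
{\tfrac{8}{3}\rho_{n,1}\sigma_{\mathrm{eff},12}^2\sqrt{2\pi m_{12}k_BT}
\left(g(\sigma_{\mathrm{eff},12})F_{12} + B_{12}/T_{12}^{*1.5}\right)}.$$

The hard part is an Enskog collision rate corrected for dense-fluid caging
(the factor $F_{12}$); the soft part lumps the Lennard-Jones attraction and
any polar (Stockmayer, dipole–dipole) attraction into a single coefficient
$B_{12} = 0.4 + \delta^2$ with the same $T^{*-1.5}$ temperature scaling.
Because $\delta$ never has to be evaluated, no dipole moment is required —
that is precisely what makes the model applicable to water, alcohols and
other hydrogen-bonding solvents for which reliable dipole data are scarce.

The property chain from critical constants to the working quantities is:

* $\sigma_{LJ,j} = 0.7889\times10^{-8}\,V_{c,j}^{1/3}$ cm,
  $\varepsilon_j/k_B = T_{c,j}/1.2593$ K ($j = 1, 2$);
* combining rules $\sigma_{LJ,12} = (1-k_{12})(\sigma_{LJ,1}+\sigma_{LJ,2})/2$,
  $\varepsilon_{12} = \sqrt{\varepsilon_1\varepsilon_2}$;
* reduced temperatures $T_j^* = T/(\varepsilon_j/k_B)$ for $j = 1, 2, 12$;
* the Ben-Amotz–Herschbach effective hard-sphere diameter
  $\sigma_{\mathrm{eff},j} = 1.1532\,\sigma_{LJ,j}
  [1 + (1.8975\,T_j^*)^{1/2}]^{-1/6}$, strictly decreasing in temperature —
  hotter molecules interpenetrate more and act smaller;
* solvent structure $\rho_{n,1} = \rho_1 N_A/M_1$,
  $\rho^* = \rho_{n,1}\sigma_{\mathrm{eff},1}^3$, $\varphi = (\pi/6)\rho^*$;
* the contact value and the correction factors $F_{11}$, $F_{12}$ below.

All internal computation is in cgs units (cm, g, s, K) with
kB = 1.380658e-16 g cm² s⁻² K⁻¹ and N_A = 6.0221367e23 mol⁻¹ (the matching
CODATA vintage); user-facing units are K, bar, g/cm³ and cm²/s. The model
consumes the solvent density directly and never a pressure — estimating
density from (T, P) with an equation of state is deliberately out of scope,
since doing it well is solvent-specific and would contaminate the
correlation's two parameters with equation-of-state error.

## Numerical forms with ambiguous antecedents

Three pieces of the model exist in the literature in several typeset
variants; the package fixes them as follows, each choice validated by limit
checks in the test suite.

**Contact radial distribution function.** With
$r = 1/(1 + \sigma_{\mathrm{eff},1}/\sigma_{\mathrm{eff},2})$,

$$g(\sigma_{\mathrm{eff},12}) =
\frac{(1-\varphi+2\varphi r)(1-\varphi+\varphi r)}{(1-\varphi)^3}.$$

This product form is algebraically identical to the three-term
Mansoori–Carnahan–Starling–Leland contact value at infinite dilution,
$1/(1-\varphi) + 3\varphi r/(1-\varphi)^2 + 2\varphi^2r^2/(1-\varphi)^3$
(the suite asserts agreement to 1e-12 over a 20×20 grid), and reduces to
the Carnahan–Starling expression $(1-\varphi/2)/(1-\varphi)^3$ for equal
diameters.

**Effective-diameter exponent.** The Ben-Amotz–Herschbach form carries the
square root, $[1+(1.8975\,T^*)^{1/2}]^{-1/6}$; the reading without the
radical is rejected because it does not reproduce the published
high-temperature behaviour of the mapping. At $T^* = 0$ the ratio to
$\sigma_{LJ}$ is exactly 1.1532.

**Dense-fluid correction factors.** The solvent self-diffusion factor is
the density polynomial

$$F_{11} = 1 + 0.94605\rho^{*1.5} + 1.4022\rho^{*3} - 5.6898\rho^{*5}
+ 2.6626\rho^{*7},$$

and the binary factor adds a size/mass asymmetry correction over a shared
denominator, with $L = \ln(\sigma_{\mathrm{eff},2}/\sigma_{\mathrm{eff},1})$
and $Q = \ln(m_2/m_1)$:

$$F_{12} = F_{11} + \frac{\rho^{*1.7}(aL + bL^2 + cQ)}{1 + \rho^{*3} d L^2},$$

$a$–$d$ linear in $\rho^*$. $F_{11}$ is positive on $\rho^* \in [0, 1]$ and
turns negative slightly above $\rho^* = 1$ (at $\rho^* = 1.1$,
$F_{11} = -0.0170$). Negative correction factors have no physical meaning;
the package **never clamps them** — the prediction is computed and flagged
invalid, and the fitting layer excludes such points from the objective and
from all reported metrics, logging each exclusion with its state and the
offending factor. The fitting objective re-applies the filter at every
candidate parameter pair as a structural safeguard; in the present model
$F_{11}$ and $F_{12}$ happen to be independent of $(k_{12}, B_{12})$ — they
involve only pure-component diameters, masses and the solvent density — so
the usable set is in fact constant over a fit, and the re-filtering costs
nothing while keeping the code correct under any future factor that does
depend on the parameters.

## Fitting

Each binary system gets its own $(k_{12}, B_{12})$, estimated by
Nelder–Mead simplex minimisation of the AARD over the system's usable
points. Choices that matter:

* **Initial guess** $(k_{12}, B_{12}) = (0, 0.4)$ — no diameter correction
  and the non-polar baseline $\delta = 0$ of the soft term.
* **Bounds.** $k_{12} < 1$ always (the binary diameter must stay positive);
  $B_{12} \ge 0$ by default. The potential picture would imply
  $B_{12} \ge 0.4$, but the coefficient is treated as empirical — small
  fitted values below 0.4 are legitimate for nearly hard-sphere systems.
  Users who want the stricter bound set `b12_lower = 0.4`. Bounds are
  enforced through a large smooth penalty rather than a constrained
  optimiser, which keeps the simplex path deterministic.
* **Convergence.** Absolute tolerance 1e-8 on the objective (the simplex
  `reltol` is tied to it), at most 2000 objective evaluations, and the
  simplex is restarted from its own optimum until the restart stops
  improving the objective by more than the tolerance. Restarting is the
  standard cure for premature simplex collapse and makes the fit
  deterministic and initial-geometry-independent; on noiseless synthetic
  systems it recovers generating parameters to ~1e-10.
* **Degenerate inputs.** Fewer than two usable points leaves the problem
  underdetermined: the fit warns and returns anyway (the two parameters
  then trade off freely). An objective undefined everywhere errors.

Metrics are pooled over *points*, never over unweighted system means: the
global AARD is the mean absolute relative residual over every usable point
in the database, which is why the report's global value equals the value
recomputed from raw residuals identically.

## The synthetic-data generator

Real D12 compilations are inaccessible from code (they live in hundreds of
primary papers), so the package ships a seeded generator that emulates
their *structure*: systems split across the four conventional solvent
subsets (polar excluding water, water, non-polar excluding supercritical
CO2, and SC-CO2), each with 5–100 state points, solvent/solute properties
drawn uniformly from realistic ranges (M ∈ [16, 1000] g/mol,
Tc ∈ [150, 900] K, Vc ∈ [50, 1100] cm³/mol), true parameters
k12 ∈ [−0.3, 0.3] and B12 ∈ [0.4, 5], and multiplicative log-normal
measurement noise (default coefficient of variation 3%, matching the
relative-error character of diffusion measurements that motivates the AARD
objective in the first place). Default density ranges per subset —
SC-CO2-like 0.1–1.0 g/cm³, water-like 0.85–1.05, organic liquids 0.5–1.1 —
keep states mostly inside the valid $\rho^* < 1$ regime; densities that
would leave it are re-drawn (deterministically under the stream seed).
Each system lives on an arithmetically derived sub-stream of the master
seed, so enlarging a database never changes the systems already drawn.

What the generator does *not* emulate: equation-of-state-consistent
(T, P, ρ) triples, correlated noise within a data source, systematic
inter-laboratory offsets, or any dependence of measurement error on the
state point. Passing the recovery and noise-floor tests therefore
demonstrates that the estimator is correct and efficient under the stated
noise model — not that the model reproduces any particular experimental
database.

## Problem sizes and verification

The test suite checks, among others: every closed-form limit of the
factors; the contact-value identity; agreement of the full prediction
chain with an independently written straight-line oracle to 1e-10 on 100
seeded random states; noiseless parameter recovery (|Δk12| ≤ 1e-5,
|ΔB12| ≤ 1e-4, AARD ≤ 1e-6%) on a 20-point system; a 200-replicate
noise-floor study (50 points/system, 3% noise) whose median fitted AARD
must land in [2.0%, 2.8%] around the population value
E|N(0, 0.03)| = 2.39%; superiority of the simplex optimum over a 41×51
brute-force parameter grid on five seeded systems; and exact exclusion
accounting for states forced to $\rho^* = 1.1$. The accompanying
`scripts/acceptance.R` re-runs the pipeline at the same sizes (a 12-system
database, 20 recovery systems, 200 noise replicates) and writes every
quantity it computes as JSON.

The fitted AARD under 3% noise sits slightly *below* the population mean
absolute deviation because two fitted parameters absorb part of the noise —
the expected and observed behaviour of any 2-parameter correlation fitted
to a finite sample.

## Known limitations

* The correlation is for tracer (infinite-dilution) diffusion only;
  concentration dependence and mutual diffusion are out of scope.
* The user must supply the solvent density; no equation of state is
  included.
* The dense-fluid polynomials lose physical meaning above $\rho^* \approx 1$
  (very dense, often high-pressure liquid states); such points are excluded
  rather than extrapolated.
* Subset labels are reporting metadata supplied by the user; the package
  never infers solvent polarity from the compound properties.
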