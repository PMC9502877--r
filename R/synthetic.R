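# Child seeds are derived arithmetically from the master seed and a stream
# index (system number, with an offset per purpose) so that adding systems
# to a config never perturbs the draws of earlier systems.
.child_seed <- function(seed, index, offset = 0L) {
  m <- 2147483647
  ((as.numeric(seed) %% m) * 48271 + 1000003 * index + 7919 * offset) %% m
}

.default_density_ranges <- list(
  scco2 = c(0.1, 1.0),     # supercritical CO2-like: gas to liquid-like
  water = c(0.85, 1.05),   # ambient-to-hot liquid water
  nonpolar = c(0.5, 1.1),  # organic liquids
  polar = c(0.6, 1.1))     # polar organic liquids

#' Configuration of the synthetic-database generator
#'
#' Describes a seeded synthetic measurement database mimicking the structure
#' of experimental D12 compilations: systems grouped into four solvent
#' subsets, each with a handful to a hundred state points spanning liquid
#' and supercritical densities, with per-system true parameters and
#' multiplicative measurement noise.
#'
#' @param seed Integer master seed; every draw derives from it.
#' @param n_systems Number of binary systems.
#' @param points_per_system Length-2 range of points per system (inclusive).
#' @param subset_mix Named proportions over
#'   `c("polar","water","nonpolar","scco2")`; must sum to 1.
#' @param molar_mass_range,tc_range,vc_range Compound property ranges
#'   (g/mol, K, cm^3/mol).
#' @param temperature_range State temperature range, K.
#' @param density_ranges Named list of density ranges (g/cm^3) per subset.
#' @param k12_range,b12_range Ranges of the true system parameters.
#' @param noise_cv Fractional standard deviation of the multiplicative
#'   measurement noise (0.03 = 3 percent).
#' @return Object of class `d12_genconfig`.
#' @export
generator_config <- function(seed = 1L, n_systems = 10L,
                             points_per_system = c(5L, 100L),
                             subset_mix = c(polar = 0.25, water = 0.25,
                                            nonpolar = 0.25, scco2 = 0.25),
                             molar_mass_range = c(16, 1000),
                             tc_range = c(150, 900),
                             vc_range = c(50, 1100),
                             temperature_range = c(280, 700),
                             density_ranges = .default_density_ranges,
                             k12_range = c(-0.3, 0.3),
                             b12_range = c(0.4, 5),
                             noise_cv = 0.03) {
  subset_mix <- subset_mix[c("polar", "water", "nonpolar", "scco2")]
  if (anyNA(subset_mix) || abs(sum(subset_mix) - 1) > 1e-9)
    stop("subset_mix must cover the four subsets and sum to 1", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  rngs <- list(points_per_system, molar_mass_range, tc_range, vc_range,
               temperature_range, k12_range, b12_range)
  if (any(vapply(rngs, function(r) length(r) != 2L || r[2] < r[1], logical(1))))
    stop("ranges must be length-2 and non-decreasing", call. = FALSE)
  structure(list(seed = as.integer(seed), n_systems = as.integer(n_systems),
                 points_per_system = as.integer(points_per_system),
                 subset_mix = subset_mix,
                 molar_mass_range = molar_mass_range, tc_range = tc_range,
                 vc_range = vc_range, temperature_range = temperature_range,
                 density_ranges = density_ranges,
                 k12_range = k12_range, b12_range = b12_range,
                 noise_cv = noise_cv),
            class = "d12_genconfig")
}

#' Draw a random compound
#'
#' Samples molar mass, critical temperature and critical volume uniformly
#' within the configured ranges. Deterministic given (config seed, stream).
#'
#' @param config A [generator_config()].
#' @param stream Integer sub-stream index (e.g. system number).
#' @param role `"solvent"` or `"solute"`; the two roles use disjoint
#'   sub-streams so a system's solvent and solute are independent.
#' @return A [compound()].
#' @export
gen_compound <- function(config, stream = 1L, role = c("solvent", "solute")) {
  stopifnot(inherits(config, "d12_genconfig"))
  role <- match.arg(role)
  off <- if (role == "solvent") 1L else 2L
  runif2 <- function(r) stats::runif(1, r[1], r[2])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.child_seed(config$seed, stream, off))
  compound(name = sprintf("%s-%03d", role, stream),
           molar_mass = runif2(config$molar_mass_range),
           critical_temperature = runif2(config$tc_range),
           critical_volume = runif2(config$vc_range))
}

#' Generate one synthetic binary system
#'
#' Draws a solvent, a solute, true parameters (k12, B12) and a set of state
#' points, then produces noisy pseudo-measurements through the forward
#' model: d12_exp = D12(model) * exp(eps), eps ~ N(0, noise_cv) per point.
#' The multiplicative noise guarantees d12_exp > 0 and reproduces the
#' relative-error character of diffusion measurements.
#'
#' Densities are sampled in the subset's range and re-drawn (deterministic
#' rejection under the stream seed) until the reduced number density stays
#' below 1, keeping the state inside the physical domain of the correction
#' factors. `n_invalid` forces that many points to exactly rho* = 1.1
#' instead, where F11 < 0 — useful for testing exclusion handling; their
#' d12_exp is the absolute value of the (non-physical) forward model.
#'
#' @param config A [generator_config()].
#' @param stream Integer sub-stream index (system number).
#' @param subset_tag Subset for the system (affects the density range and
#'   reporting only; the model is subset-agnostic).
#' @param n_points Number of points; default drawn from
#'   `config$points_per_system`.
#' @param n_invalid Number of points forced to rho* = 1.1 (default 0).
#' @return List with `system` (a [measurement_set()]) and `truth`
#'   (the generating [model_params()]).
#' @export
gen_system <- function(config, stream = 1L, subset_tag = "scco2",
                       n_points = NULL, n_invalid = 0L) {
  stopifnot(inherits(config, "d12_genconfig"))
  subset_tag <- match.arg(subset_tag, names(config$density_ranges))
  solvent <- gen_compound(config, stream, "solvent")
  solute <- gen_compound(config, stream, "solute")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.child_seed(config$seed, stream, 3L))

  truth <- model_params(stats::runif(1, config$k12_range[1], config$k12_range[2]),
                        stats::runif(1, config$b12_range[1], config$b12_range[2]))
  if (is.null(n_points))
    n_points <- sample(config$points_per_system[1]:config$points_per_system[2], 1L)
  if (n_invalid > n_points) stop("n_invalid exceeds n_points", call. = FALSE)

  temp <- stats::runif(n_points, config$temperature_range[1], config$temperature_range[2])
  dr <- config$density_ranges[[subset_tag]]
  rho <- stats::runif(n_points, dr[1], dr[2])

  # solvent geometry fixes the rho -> rho* map at each temperature
  lj1 <- lj_params(solvent)
  se1 <- effective_diameter(lj1$sigma_lj, reduced_temperature(temp, lj1$eps_kb))
  rho_star <- function(r) r * .NAvogadro / solvent$molar_mass * se1^3
  for (tries in 1:50) {
    bad <- rho_star(rho) >= 1
    if (!any(bad)) break
    rho[bad] <- stats::runif(sum(bad), dr[1], dr[2])
  }
  if (any(rho_star(rho) >= 1)) {
    # range itself forces dense states; compress into the valid regime
    cap <- 0.95 / (.NAvogadro / solvent$molar_mass * se1^3)
    rho <- pmin(rho, cap)
  }
  if (n_invalid > 0L) {
    idx <- seq_len(n_invalid)
    rho[idx] <- 1.1 / (.NAvogadro / solvent$molar_mass * se1[idx]^3)
  }

  states <- state_points(temp, rho)
  pred <- predict_d12(solvent, solute, states, truth)
  noise <- stats::rnorm(n_points, 0, config$noise_cv)
  d12_exp <- abs(pred$d12) * exp(noise)
  d12_exp[d12_exp == 0] <- .Machine$double.xmin
  states$d12_exp <- d12_exp

  list(system = measurement_set(solvent, solute, states, subset_tag,
                                system_id = sprintf("sys-%03d", stream)),
       truth = truth)
}

#' Generate a synthetic measurement database
#'
#' Produces `n_systems` synthetic systems with subset tags drawn from
#' `subset_mix`, fully reproducible from the master seed; each system lives
#' on its own sub-stream, so enlarging the database never changes the
#' systems already generated.
#'
#' @param config A [generator_config()].
#' @return List with `systems` (list of [measurement_set()]) and `truths`
#'   (list of the generating [model_params()]).
#' @export
#' @examples
#' db <- gen_database(generator_config(seed = 42, n_systems = 3,
#'                                     points_per_system = c(5, 10)))
gen_database <- function(config) {
  stopifnot(inherits(config, "d12_genconfig"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  tags <- character(config$n_systems)
  for (i in seq_len(config$n_systems)) {
    set.seed(.child_seed(config$seed, i, 4L))
    tags[i] <- sample(names(config$subset_mix), 1L, prob = config$subset_mix)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out <- lapply(seq_len(config$n_systems), function(i)
    gen_system(config, stream = i, subset_tag = tags[i]))
  list(systems = lapply(out, `[[`, "system"),
       truths = lapply(out, `[[`, "truth"))
}
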