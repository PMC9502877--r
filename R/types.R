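#' Define a chemical compound by its critical properties
#'
#' A compound enters the model through three properties only: molar mass,
#' critical temperature and critical volume. The Lennard-Jones diameter and
#' energy are estimated from `Tc` and `Vc` by [lj_params()], and the
#' per-molecule mass from `M`.
#'
#' @param name Compound identifier (unique within a registry).
#' @param molar_mass Molar mass M, g/mol.
#' @param critical_temperature Critical temperature Tc, K.
#' @param critical_volume Critical volume Vc, cm^3/mol.
#' @return Object of class `d12_compound`.
#' @export
#' @examples
#' co2 <- compound("CO2", 44.01, 304.13, 94.07)
compound <- function(name, molar_mass, critical_temperature, critical_volume) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (v in c(molar_mass = molar_mass, critical_temperature = critical_temperature,
              critical_volume = critical_volume)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("compound properties must be finite, strictly positive numbers", call. = FALSE)
  }
  structure(
    list(name = name, molar_mass = as.numeric(molar_mass),
         critical_temperature = as.numeric(critical_temperature),
         critical_volume = as.numeric(critical_volume)),
    class = "d12_compound")
}

#' @export
print.d12_compound <- function(x, ...) {
  cat(sprintf("<compound> %s: M = %g g/mol, Tc = %g K, Vc = %g cm3/mol\n",
              x$name, x$molar_mass, x$critical_temperature, x$critical_volume))
  invisible(x)
}

#' Thermodynamic state points of the solvent
#'
#' Builds the table of state points at which D12 is measured or predicted.
#' The model consumes temperature and solvent mass density; pressure is
#' carried along as metadata only (it is never used in any computation, the
#' user supplies the density at that pressure).
#'
#' @param temperature Temperature, K (vector).
#' @param solvent_density Solvent mass density rho1, g/cm^3 (vector).
#' @param pressure Optional pressure, bar; metadata only. `NA` allowed.
#' @param d12_exp Optional experimental D12, cm^2/s; required for fitting,
#'   absent (`NA`) for prediction-only use.
#' @return A `data.frame` of class `d12_states` with one row per point.
#' @export
#' @examples
#' state_points(c(313.15, 323.15), c(0.7, 0.65))
state_points <- function(temperature, solvent_density, pressure = NA_real_,
                         d12_exp = NA_real_) {
  n <- length(temperature)
  df <- data.frame(temperature = as.numeric(temperature),
                   pressure = rep_len(as.numeric(pressure), n),
                   solvent_density = as.numeric(solvent_density),
                   d12_exp = rep_len(as.numeric(d12_exp), n))
  if (nrow(df) < 1L) stop("at least one state point is required", call. = FALSE)
  if (any(!is.finite(df$temperature)) || any(df$temperature <= 0))
    stop("temperature must be finite and > 0", call. = FALSE)
  if (any(!is.finite(df$solvent_density)) || any(df$solvent_density <= 0))
    stop("solvent_density must be finite and > 0", call. = FALSE)
  bad <- !is.na(df$d12_exp) & df$d12_exp <= 0
  if (any(bad)) stop("d12_exp must be > 0 when present", call. = FALSE)
  class(df) <- c("d12_states", "data.frame")
  df
}

#' Model parameters (k12, B12)
#'
#' The two fitted constants of the correlation: `k12` is the binary
#' interaction parameter in the Lennard-Jones diameter combining rule
#' (must be < 1 so the binary diameter stays positive) and `B12` is the
#' attractive-friction coefficient absorbing the Lennard-Jones and polar
#' (Stockmayer) soft contributions, B12 = 0.4 + delta^2 in the underlying
#' potential picture, hence non-negative.
#'
#' @param k12 Dimensionless binary interaction parameter, k12 < 1.
#' @param B12 Dimensionless attractive-friction coefficient, B12 >= 0.
#' @return Object of class `d12_params`.
#' @export
#' @examples
#' model_params(0.05, 1.5)
model_params <- function(k12, B12) {
  stopifnot(is.numeric(k12), length(k12) == 1L, is.finite(k12),
            is.numeric(B12), length(B12) == 1L, is.finite(B12))
  if (k12 >= 1) stop("k12 must be < 1 (binary LJ diameter must stay positive)", call. = FALSE)
  if (B12 < 0) stop("B12 must be >= 0", call. = FALSE)
  structure(list(k12 = as.numeric(k12), B12 = as.numeric(B12)),
            class = "d12_params")
}

#' @export
print.d12_params <- function(x, ...) {
  cat(sprintf("<model params> k12 = %.6g, B12 = %.6g\n", x$k12, x$B12))
  invisible(x)
}

.subset_tags <- c("polar", "water", "nonpolar", "scco2", "unspecified")

#' A measured binary system
#'
#' Bundles one solvent/solute pair with its measured state points and a
#' subset tag used only for reporting. Tags follow the usual partition of
#' diffusion databases by solvent nature: `polar` (polar solvents excluding
#' water), `water`, `nonpolar` (non-polar and weakly polar excluding
#' supercritical CO2) and `scco2`; the tag is user-supplied metadata and is
#' never inferred from the compounds.
#'
#' @param solvent,solute [compound()] objects.
#' @param points [state_points()] table; every row must carry `d12_exp` when
#'   the system is to be fitted.
#' @param subset_tag One of `"polar"`, `"water"`, `"nonpolar"`, `"scco2"`,
#'   `"unspecified"`.
#' @param system_id Optional identifier; defaults to "solvent/solute".
#' @return Object of class `d12_system`.
#' @export
measurement_set <- function(solvent, solute, points,
                            subset_tag = "unspecified", system_id = NULL) {
  stopifnot(inherits(solvent, "d12_compound"), inherits(solute, "d12_compound"),
            inherits(points, "data.frame"))
  subset_tag <- match.arg(subset_tag, .subset_tags)
  if (nrow(points) < 1L) stop("a system needs at least one state point", call. = FALSE)
  if (is.null(system_id)) system_id <- paste0(solvent$name, "/", solute$name)
  structure(list(system_id = system_id, solvent = solvent, solute = solute,
                 points = points, subset_tag = subset_tag),
            class = "d12_system")
}

#' @export
print.d12_system <- function(x, ...) {
  cat(sprintf("<system> %s [%s]: %d point(s), T %g-%g K, rho1 %g-%g g/cm3\n",
              x$system_id, x$subset_tag, nrow(x$points),
              min(x$points$temperature), max(x$points$temperature),
              min(x$points$solvent_density), max(x$points$solvent_density)))
  invisible(x)
}
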