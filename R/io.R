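# Tabular formats are plain CSV (RFC 4180, "." decimal separator) with
# mandatory headers; units are fixed in the column names so files cannot
# drift silently between unit conventions.
.registry_cols <- c("name", "M_g_mol", "Tc_K", "Vc_cm3_mol")
.measurement_cols <- c("system_id", "subset", "solvent", "solute",
                       "T_K", "P_bar", "rho1_g_cm3", "D12_cm2_s")

#' Read a compound property registry
#'
#' Reads a CSV with columns `name, M_g_mol, Tc_K, Vc_cm3_mol` into a named
#' list of [compound()] objects. Every error names the offending row.
#'
#' @param path Path to the registry CSV.
#' @return Named list of `d12_compound` objects (names are compound names).
#' @export
read_compound_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.registry_cols, names(df))
  if (length(missing_cols))
    stop("registry is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$name))
    stop("duplicate compound name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "), call. = FALSE)
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    out[[i]] <- tryCatch(
      compound(df$name[i], df$M_g_mol[i], df$Tc_K[i], df$Vc_cm3_mol[i]),
      error = function(e) stop(sprintf("registry row %d (%s): %s",
                                       i, df$name[i], conditionMessage(e)),
                               call. = FALSE))
  }
  names(out) <- df$name
  out
}

#' Write a compound registry
#'
#' @param compounds Named list of [compound()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compound_registry <- function(compounds, path) {
  df <- do.call(rbind, lapply(compounds, function(cp)
    data.frame(name = cp$name, M_g_mol = cp$molar_mass,
               Tc_K = cp$critical_temperature, Vc_cm3_mol = cp$critical_volume)))
  df[-1] <- lapply(df[-1], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read measurement tables into systems
#'
#' Reads a CSV of D12 measurements (columns `system_id, subset, solvent,
#' solute, T_K, P_bar, rho1_g_cm3, D12_cm2_s`), resolves compound names
#' against a registry and groups rows into [measurement_set()] objects.
#' Original row order is preserved within each system. `P_bar` may be empty
#' (the model never uses pressure); missing density or temperature is an
#' error naming the row.
#'
#' @param path Path to the measurement CSV.
#' @param registry Named list of compounds from [read_compound_registry()].
#' @return List of `d12_system` objects, in order of first appearance.
#' @export
read_measurements <- function(path, registry) {
  if (!file.exists(path)) stop("measurement file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(.measurement_cols, "P_bar"), names(df))
  if (length(missing_cols))
    stop("measurement table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(df$P_bar)) df$P_bar <- NA_real_
  for (i in seq_len(nrow(df))) {
    for (nm in c("solvent", "solute")) {
      if (!df[[nm]][i] %in% names(registry))
        stop(sprintf("row %d: unknown %s '%s' (not in registry)", i, nm, df[[nm]][i]),
             call. = FALSE)
    }
    for (nm in c("T_K", "rho1_g_cm3", "D12_cm2_s")) {
      v <- df[[nm]][i]
      if (is.na(v) || v <= 0)
        stop(sprintf("row %d: %s must be present and > 0 (got %s)", i, nm, v),
             call. = FALSE)
    }
  }
  ids <- unique(df$system_id)
  lapply(ids, function(id) {
    rows <- df[df$system_id == id, , drop = FALSE]
    tag <- rows$subset[1]
    if (!tag %in% .subset_tags) tag <- "unspecified"
    measurement_set(registry[[rows$solvent[1]]], registry[[rows$solute[1]]],
                    state_points(rows$T_K, rows$rho1_g_cm3,
                                 pressure = rows$P_bar, d12_exp = rows$D12_cm2_s),
                    subset_tag = tag, system_id = id)
  })
}

#' Write systems to a measurement table
#'
#' Inverse of [read_measurements()]; values round-trip to at least 12
#' significant digits.
#'
#' @param systems List of [measurement_set()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(systems, path) {
  rows <- do.call(rbind, lapply(systems, function(s)
    data.frame(system_id = s$system_id, subset = s$subset_tag,
               solvent = s$solvent$name, solute = s$solute$name,
               T_K = s$points$temperature, P_bar = s$points$pressure,
               rho1_g_cm3 = s$points$solvent_density,
               D12_cm2_s = s$points$d12_exp)))
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], function(x)
    ifelse(is.na(x), "", sprintf("%.15g", x)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the compound registry of a set of systems
#'
#' @param systems List of [measurement_set()] objects.
#' @return Named list of unique compounds.
#' @export
registry_of <- function(systems) {
  comps <- list()
  for (s in systems) for (cp in list(s$solvent, s$solute))
    if (is.null(comps[[cp$name]])) comps[[cp$name]] <- cp
  comps
}

#' Write a fit report
#'
#' Writes the per-system table of a [evaluate_database()] report as CSV and,
#' optionally, a machine-readable JSON run summary carrying the pooled
#' subset and global metrics alongside the per-system parameters.
#'
#' @param report A `d12_report`.
#' @param path Output CSV path for the per-system table.
#' @param summary_path Optional path for the JSON run summary.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, summary_path = NULL) {
  stopifnot(inherits(report, "d12_report"))
  tab <- report$systems
  num <- vapply(tab, is.numeric, logical(1)) & !names(tab) %in% c("ndp", "n_excluded")
  tab[num] <- lapply(tab[num], function(x) sprintf("%.15g", x))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      list(systems = report$systems, subsets = report$subsets,
           global = report$global),
      summary_path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML configuration consumed by the command-line interface. Recognised
#' keys: `registry`, `measurements`, `output_dir`, `seed`, and a `fit`
#' block (`k12_init`, `b12_init`, `tolerance`, `max_evals`, `b12_lower`).
#' Command-line flags override config values.
#'
#' @param path Path to the YAML file.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$fit$tolerance) && cfg$fit$tolerance <= 0)
    stop("config: fit tolerance must be > 0", call. = FALSE)
  cfg
}
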