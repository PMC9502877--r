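#' Partition state points by physical validity
#'
#' A state point is usable only where both dense-fluid correction factors
#' are physical: it is excluded iff F11 <= 0 or F12 <= 0 at its state under
#' the given parameters. The partition is exhaustive and disjoint; excluded
#' points carry the offending factor and its value so exclusions can be
#' logged and audited.
#'
#' @param system A [measurement_set()].
#' @param params A [model_params()] object.
#' @return List with `usable` (prediction rows for retained points),
#'   `excluded` (rows with columns `cause` in `{"F11","F12"}` and
#'   `cause_value`), and `n_excluded`.
#' @export
validity_filter <- function(system, params) {
  stopifnot(inherits(system, "d12_system"))
  pred <- predict_d12(system$solvent, system$solute, system$points, params)
  bad <- !pred$valid
  excluded <- pred[bad, , drop = FALSE]
  if (nrow(excluded)) {
    # F11 failure takes precedence as cause: F12 inherits F11's divergence
    excluded$cause <- ifelse(excluded$f11 <= 0, "F11", "F12")
    excluded$cause_value <- ifelse(excluded$f11 <= 0, excluded$f11, excluded$f12)
  } else {
    excluded$cause <- character(0)
    excluded$cause_value <- numeric(0)
  }
  list(usable = pred[!bad, , drop = FALSE],
       excluded = excluded,
       n_excluded = sum(bad))
}

# AARD objective over the system's usable points at candidate (k12, B12).
# Points invalid under the candidate are dropped from that evaluation;
# out-of-bounds candidates and empty usable sets get a large smooth penalty
# so the simplex is pushed back into the feasible region.
.fit_objective <- function(par, system, b12_lower) {
  k12 <- par[1]; B12 <- par[2]
  if (k12 >= 1 || B12 < b12_lower || !all(is.finite(par)))
    return(1e6 + 1e3 * (max(0, k12 - 1) + max(0, b12_lower - B12)))
  pred <- predict_d12(system$solvent, system$solute, system$points,
                      structure(list(k12 = k12, B12 = B12), class = "d12_params"))
  ok <- pred$valid & is.finite(pred$d12) & pred$d12 > 0
  if (!any(ok)) return(1e6)
  aard(pred$d12[ok], pred$d12_exp[ok])
}

#' Fit (k12, B12) to one system by simplex minimisation of AARD
#'
#' Estimates the two model parameters for a single binary system with the
#' Nelder-Mead simplex, using AARD over the system's usable points as the
#' objective. The validity filter is re-applied at every candidate: points
#' whose correction factors turn non-physical under that candidate are
#' dropped from that evaluation. The simplex is restarted from its own
#' optimum until the objective stops improving, which makes convergence to
#' the tight tolerances deterministic and independent of simplex geometry.
#'
#' Bounds are enforced by penalty: k12 < 1 always, and B12 >= `b12_lower`
#' (0 by default; set 0.4 to impose the attractive-potential lower bound
#' B = 0.4 + delta^2 of the soft-friction term).
#'
#' @param system A [measurement_set()] whose points all carry `d12_exp`.
#' @param init Initial guess, a [model_params()]; default (k12 = 0,
#'   B12 = 0.4), the physical baseline of a non-polar solute (delta = 0).
#' @param tolerance Absolute convergence tolerance on the objective and
#'   parameters (default 1e-8).
#' @param max_evals Maximum objective evaluations across restarts
#'   (default 2000).
#' @param b12_lower Lower bound for B12 (default 0).
#' @return Object of class `d12_fit`: `params` ([model_params()]),
#'   `metrics` (list `aard`, `ard`, `ndp` over the points usable at the
#'   fitted parameters), `n_excluded`, `converged`, `n_evaluations`,
#'   `system_id`, `subset_tag`, and `excluded` (the audit rows of
#'   [validity_filter()]).
#' @export
fit_params <- function(system, init = model_params(0, 0.4),
                       tolerance = 1e-8, max_evals = 2000, b12_lower = 0) {
  stopifnot(inherits(system, "d12_system"))
  if (any(is.na(system$points$d12_exp)))
    stop("all state points need d12_exp to fit", call. = FALSE)
  if (!inherits(init, "d12_params")) init <- model_params(init[[1]], init[[2]])
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)

  n0 <- validity_filter(system, init)
  if (nrow(n0$usable) < 2L)
    warning("fewer than 2 usable points: fit is underdetermined", call. = FALSE)

  evals <- 0L
  obj <- function(par) {
    evals <<- evals + 1L
    .fit_objective(par, system, b12_lower)
  }

  par <- c(init$k12, init$B12)
  fval <- obj(par)
  converged <- FALSE
  # deterministic restarts: Nelder-Mead re-started at its own optimum until
  # no further improvement beyond the absolute tolerance
  for (round in 1:8) {
    if (evals >= max_evals) break
    res <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = max(50, max_evals - evals),
                                       reltol = max(1e-14, tolerance * 1e-4),
                                       abstol = tolerance / 10,
                                       alpha = 1, beta = 0.5, gamma = 2))
    improved <- fval - res$value
    par <- res$par; fval <- res$value
    if (res$convergence == 0 && round > 1 && improved <= tolerance) {
      converged <- TRUE
      break
    }
  }

  params <- model_params(par[1], max(par[2], b12_lower))
  filt <- validity_filter(system, params)
  u <- filt$usable
  metrics <- list(aard = aard(u$d12, u$d12_exp),
                  ard = ard(u$d12, u$d12_exp),
                  ndp = nrow(u))
  structure(list(params = params, metrics = metrics,
                 n_excluded = filt$n_excluded, converged = converged,
                 n_evaluations = evals,
                 system_id = system$system_id, subset_tag = system$subset_tag,
                 excluded = filt$excluded),
            class = "d12_fit")
}

#' @export
print.d12_fit <- function(x, ...) {
  cat(sprintf("<fit> %s [%s]: k12 = %.6g, B12 = %.6g | AARD = %.4g%%, ARD = %.4g%%, NDP = %d, excluded = %d%s\n",
              x$system_id, x$subset_tag, x$params$k12, x$params$B12,
              x$metrics$aard, x$metrics$ard, x$metrics$ndp, x$n_excluded,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Evaluate a database of fitted systems
#'
#' Aggregates per-system results into subset and global performance tables.
#' Pooling follows the definition of AARD/ARD: deviations are averaged over
#' points (NDP in the denominator), never over unweighted system means, so
#' the global AARD recomputed from raw residuals equals the reported value
#' identically.
#'
#' @param systems List of [measurement_set()] objects.
#' @param fits Matching list of `d12_fit` objects (same order), e.g. from
#'   `lapply(systems, fit_params)`.
#' @return Object of class `d12_report`: `systems` (one row per system:
#'   `system_id`, `subset`, `ndp`, `n_excluded`, `k12`, `B12`, `aard`,
#'   `ard`), `subsets` and `global` (rows with `n_systems`, `ndp`,
#'   `n_excluded`, `aard`, `ard`).
#' @export
evaluate_database <- function(systems, fits) {
  if (length(systems) == 0L) stop("empty database", call. = FALSE)
  if (length(systems) != length(fits))
    stop("one fit per system is required", call. = FALSE)

  resid <- vector("list", length(systems))
  sys_rows <- vector("list", length(systems))
  for (i in seq_along(systems)) {
    s <- systems[[i]]; f <- fits[[i]]
    filt <- validity_filter(s, f$params)
    u <- filt$usable
    rel <- (u$d12 - u$d12_exp) / u$d12_exp
    resid[[i]] <- data.frame(subset = s$subset_tag, rel = rel)
    sys_rows[[i]] <- data.frame(
      system_id = s$system_id, subset = s$subset_tag,
      ndp = nrow(u), n_excluded = filt$n_excluded,
      k12 = f$params$k12, B12 = f$params$B12,
      aard = 100 * mean(abs(rel)), ard = 100 * mean(rel))
  }
  sys_tab <- do.call(rbind, sys_rows)
  res_tab <- do.call(rbind, resid)

  pool <- function(rows, rel) {
    data.frame(n_systems = nrow(rows), ndp = sum(rows$ndp),
               n_excluded = sum(rows$n_excluded),
               aard = 100 * mean(abs(rel)), ard = 100 * mean(rel))
  }
  subs <- unique(sys_tab$subset)
  sub_tab <- do.call(rbind, lapply(subs, function(tag) {
    cbind(subset = tag,
          pool(sys_tab[sys_tab$subset == tag, , drop = FALSE],
               res_tab$rel[res_tab$subset == tag]))
  }))
  structure(list(systems = sys_tab, subsets = sub_tab,
                 global = pool(sys_tab, res_tab$rel)),
            class = "d12_report")
}

#' @export
print.d12_report <- function(x, ...) {
  cat(sprintf("<database report> %d system(s), NDP = %d, excluded = %d\n",
              x$global$n_systems, x$global$ndp, x$global$n_excluded))
  cat(sprintf("global AARD = %.4g%%, ARD = %.4g%%\n", x$global$aard, x$global$ard))
  for (i in seq_len(nrow(x$subsets)))
    cat(sprintf("  %-11s Nsys = %3d, NDP = %5d, AARD = %.4g%%, ARD = %.4g%%\n",
                x$subsets$subset[i], x$subsets$n_systems[i], x$subsets$ndp[i],
                x$subsets$aard[i], x$subsets$ard[i]))
  invisible(x)
}
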