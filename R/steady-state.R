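#' Find a steady state of the pathway model
#'
#' Integrates the mass-balance ODEs toward quiescence and (by default)
#' refines the endpoint by Newton root-finding on the derivative map, with
#' the ACP conservation constraint substituted for holo-ACP so the reduced
#' system is square.  Integration is in log-increasing time chunks; the
#' refinement works in log-concentration space, which keeps iterates
#' positive.
#'
#' @param model A [pathway_model()].
#' @param init Named nonnegative initial state (uM); defaults to an even
#'   split of the ACP pool and 1 uM for each PL intermediate.  The conserved
#'   ACP total of the result equals `total_acp(init)`.
#' @param tol Convergence tolerance on the residual `max |dx/dt|` (uM/min).
#' @param t_max Integration horizon (min); if the residual still exceeds
#'   `tol` at `t_max` the result is returned with `converged = FALSE`
#'   rather than as an error.
#' @param method `"hybrid"` (integrate then Newton-refine, the default),
#'   `"integrate"` (quiescence only) or `"refine"` (Newton from `init`).
#'   The two pure routes exist so they can be cross-checked against each
#'   other.
#' @return An object of class `ss_fit`: concentrations, per-reaction fluxes,
#'   `pe_flux` (PSD rate), `lps_flux` (LPXC rate), `converged`, `residual`.
#' @examples
#' ss <- find_steady_state(pathway_model())
#' glance(ss)
#' @export
find_steady_state <- function(model, init = NULL, tol = 1e-9, t_max = 1e6,
                              method = c("hybrid", "integrate", "refine")) {
  stopifnot(inherits(model, "pathway_model"), tol > 0, t_max > 0)
  method <- match.arg(method)
  if (is.null(init)) init <- .default_init(model)
  init <- .as_state(init)
  if (any(init < 0)) stop("init must be nonnegative", call. = FALSE)

  y <- init
  if (method %in% c("hybrid", "integrate")) {
    # looser interior target for the hybrid route; Newton finishes the job
    target <- if (method == "hybrid") max(tol, 1e-7) else tol
    y <- .integrate_to_quiescence(model, init, target, t_max)
  }
  if (method %in% c("hybrid", "refine")) {
    y <- .refine_root(model, y)
  }
  y <- pmax(y, 0)
  resid <- max(abs(time_derivatives(y, model)))
  fluxes <- .rates(y, model)
  structure(
    list(concentrations = y, fluxes = fluxes,
         pe_flux = unname(fluxes["PSD"]), lps_flux = unname(fluxes["LPXC"]),
         converged = resid <= tol, residual = resid,
         acp_total = total_acp(y), tol = tol, method = method, model = model),
    class = "ss_fit"
  )
}

.default_init <- function(model) {
  y <- stats::setNames(rep(1, length(DYNAMIC_SPECIES)), DYNAMIC_SPECIES)
  y[ACP_SPECIES] <- model$acp_total / length(ACP_SPECIES)
  y
}

.ode_rhs <- function(t, y, parms) {
  list(drop(parms$S %*% .rates(y, parms$model)))
}

.integrate_to_quiescence <- function(model, init, target, t_max) {
  parms <- list(S = model$stoichiometry, model = model)
  t0 <- 0
  y <- init
  horizons <- unique(pmin(10^seq(1, ceiling(log10(t_max)), by = 1), t_max))
  for (t1 in horizons) {
    out <- deSolve::lsoda(y, times = c(t0, t1), func = .ode_rhs,
                          parms = parms, rtol = 1e-10, atol = 1e-12)
    y <- stats::setNames(as.numeric(out[nrow(out), -1]), DYNAMIC_SPECIES)
    if (max(abs(time_derivatives(pmax(y, 0), model))) <= target) break
    t0 <- t1
  }
  pmax(y, 0)
}

# Newton refinement in log space on the conservation-reduced system:
# holo-ACP is eliminated via the conserved total carried by the start point.
.refine_root <- function(model, y) {
  total <- total_acp(y)
  free <- setdiff(DYNAMIC_SPECIES, "holo_acp")
  y0 <- pmax(y[free], 1e-12)
  fn <- function(u) {
    st <- exp(u)
    names(st) <- free
    holo <- total - sum(st[setdiff(ACP_SPECIES, "holo_acp")])
    if (holo <= 0) return(rep(1e6, length(free)))
    full <- c(holo_acp = holo, st)[DYNAMIC_SPECIES]
    d <- drop(model$stoichiometry %*% .rates(full, model))
    d[free]
  }
  sol <- tryCatch(
    pracma::fsolve(fn, log(y0), tol = .Machine$double.eps^0.8),
    error = function(e) NULL
  )
  if (is.null(sol)) return(y)  # keep integration endpoint; residual decides
  st <- exp(sol$x)
  names(st) <- free
  holo <- total - sum(st[setdiff(ACP_SPECIES, "holo_acp")])
  cand <- c(holo_acp = holo, st)[DYNAMIC_SPECIES]
  # accept only if it actually improves the residual
  if (holo > 0 &&
      max(abs(time_derivatives(cand, model))) <
        max(abs(time_derivatives(y, model)))) cand else y
}

#' Steady-state pathway output fluxes
#'
#' @param ss A converged [find_steady_state()] result.
#' @return A one-row tibble with `pe_flux` (phospholipid output, the PSD
#'   rate) and `lps_flux` (the lumped LpxA/LpxC rate), in uM/min.
#' @export
pathway_fluxes <- function(ss) {
  stopifnot(inherits(ss, "ss_fit"))
  if (!ss$converged) {
    stop("steady state did not converge (residual ", format(ss$residual),
         "); fluxes are undefined", call. = FALSE)
  }
  tibble::tibble(pe_flux = ss$pe_flux, lps_flux = ss$lps_flux)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname find_steady_state
#' @param x An `ss_fit` object.
#' @param ... Unused.
#' @method tidy ss_fit
#' @export
tidy.ss_fit <- function(x, ...) {
  tibble::tibble(
    species = names(x$concentrations),
    concentration = unname(x$concentrations),
    in_acp_pool = names(x$concentrations) %in% ACP_SPECIES
  )
}

#' @rdname find_steady_state
#' @method glance ss_fit
#' @export
glance.ss_fit <- function(x, ...) {
  tibble::tibble(pe_flux = x$pe_flux, lps_flux = x$lps_flux,
                 converged = x$converged, residual = x$residual,
                 acp_total = x$acp_total, method = x$method)
}

#' @export
print.ss_fit <- function(x, ...) {
  cat("<ss_fit> steady state (", if (x$converged) "converged" else
    "NOT converged", ", residual ", format(x$residual, digits = 3), ")\n",
    sep = "")
  cat("  PE flux:  ", format(x$pe_flux, digits = 6), "uM/min\n")
  cat("  LPS flux: ", format(x$lps_flux, digits = 6), "uM/min\n")
  invisible(x)
}

#' Scan steady-state response to an enzyme Vmax or boundary input
#'
#' Recomputes the steady state for each multiplier applied to the target
#' (a reaction Vmax, `"PLSB"` for the shared PlsB scale, or a fixed input
#' such as `"acetyl_coa"`), warm-starting each solve from the previous
#' solution for speed and branch continuity.
#'
#' @param model A [pathway_model()].
#' @param target Reaction id, `"PLSB"`, or a fixed-input name.
#' @param factors Positive multipliers; should include 1 for a baseline row.
#' @param tol,t_max Passed to [find_steady_state()].
#' @return A tibble of class `vmax_scan`: one row per factor with `pe_flux`,
#'   `lps_flux`, `converged` and one column per dynamic species.
#' @examples
#' \donttest{
#' scan <- scan_vmax(pathway_model(), "PLSB", factors = c(0.5, 1, 2, 4))
#' autoplot(scan)
#' }
#' @export
scan_vmax <- function(model, target, factors = c(0.25, 0.5, 1, 2, 4),
                      tol = 1e-9, t_max = 1e6) {
  stopifnot(inherits(model, "pathway_model"), all(factors > 0))
  ord <- order(factors)
  init <- NULL
  rows <- vector("list", length(factors))
  for (i in ord) {
    m_i <- .apply_factor(model, target, factors[i])
    ss <- find_steady_state(m_i, init = init, tol = tol, t_max = t_max)
    if (ss$converged) init <- ss$concentrations
    rows[[i]] <- tibble::tibble(
      target = target, factor = factors[i],
      pe_flux = ss$pe_flux, lps_flux = ss$lps_flux,
      converged = ss$converged, residual = ss$residual,
      !!!as.list(ss$concentrations)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("vmax_scan", class(out))
  out
}

#' Flux control coefficients by log-space finite differences
#'
#' Computes `C_i^J = d ln J / d ln Vmax_i` for every reaction by centred
#' finite differences with a small symmetric log perturbation.  Because all
#' rate laws are homogeneous of degree one in their Vmax, the coefficients
#' for each flux obey the summation theorem (they sum to 1).
#'
#' @param model A [pathway_model()].
#' @param delta Relative Vmax perturbation (default 1\%).
#' @param tol,t_max Passed to [find_steady_state()].
#' @return A tibble of class `control_coefficients` with columns `reaction`,
#'   `pe_flux` and `lps_flux` (the coefficients); coefficients at
#'   non-converged perturbed points are `NA`.
#' @export
flux_control_coefficients <- function(model, delta = 0.01, tol = 1e-9,
                                      t_max = 1e6) {
  stopifnot(inherits(model, "pathway_model"), delta > 0, delta < 1)
  base <- find_steady_state(model, tol = tol, t_max = t_max)
  if (!base$converged) stop("baseline steady state did not converge",
                            call. = FALSE)
  h <- log(1 + delta)
  one_side <- function(rxn, sgn) {
    m <- .apply_factor(model, rxn, exp(sgn * h))
    find_steady_state(m, init = base$concentrations, tol = tol, t_max = t_max)
  }
  coef_row <- function(rxn) {
    up <- one_side(rxn, +1)
    dn <- one_side(rxn, -1)
    if (!up$converged || !dn$converged) {
      return(tibble::tibble(reaction = rxn, pe_flux = NA_real_,
                            lps_flux = NA_real_))
    }
    tibble::tibble(
      reaction = rxn,
      pe_flux = (log(up$pe_flux) - log(dn$pe_flux)) / (2 * h),
      lps_flux = (log(up$lps_flux) - log(dn$lps_flux)) / (2 * h)
    )
  }
  out <- purrr::map_dfr(REACTIONS, coef_row)
  class(out) <- c("control_coefficients", class(out))
  attr(out, "delta") <- delta
  out
}

#' Summation-theorem summary of control coefficients
#'
#' @param x A `control_coefficients` tibble.
#' @param ... Unused.
#' @return One-row tibble with the coefficient sums per flux and the number
#'   of reactions whose coefficients could not be computed.
#' @method glance control_coefficients
#' @export
glance.control_coefficients <- function(x, ...) {
  tibble::tibble(
    sum_pe = sum(x$pe_flux, na.rm = TRUE),
    sum_lps = sum(x$lps_flux, na.rm = TRUE),
    n_missing = sum(is.na(x$pe_flux) | is.na(x$lps_flux))
  )
}

#' Predicted concentration trends along a flux driver
#'
#' Scans a driver (PlsB or ACC Vmax, or the acetyl-CoA boundary
#' concentration) across a factor grid spanning the baseline, and expresses
#' each species' steady-state concentration against the PE flux, both as
#' log2 ratios to baseline.  These are the model's testable trend
#' predictions: the sign of each species' slope says whether it should rise
#' or fall with phospholipid flux if that driver is what couples flux to
#' growth.
#'
#' @param model A [pathway_model()].
#' @param driver `"PLSB"`, `"ACC"` or `"acetyl_coa"`.
#' @param factors Positive multipliers spanning 1.
#' @param tol,t_max Passed to [find_steady_state()].
#' @return A tibble of class `trend_curves`: `driver`, `factor`, `species`,
#'   `log2_flux`, `log2_conc` (both 0 at the baseline).
#' @export
predict_trends <- function(model, driver = c("PLSB", "ACC", "acetyl_coa"),
                           factors = 2^seq(-1, 1, by = 0.25),
                           tol = 1e-9, t_max = 1e6) {
  driver <- match.arg(driver)
  if (min(factors) > 1 || max(factors) < 1) {
    stop("the factor grid must span the baseline (include values on both ",
         "sides of 1)", call. = FALSE)
  }
  scan <- scan_vmax(model, driver, factors = sort(unique(c(1, factors))),
                    tol = tol, t_max = t_max)
  base <- scan[scan$factor == 1, ]
  long <- tidyr::pivot_longer(scan, cols = dplyr::all_of(DYNAMIC_SPECIES),
                              names_to = "species", values_to = "conc")
  base_conc <- stats::setNames(as.numeric(base[1, DYNAMIC_SPECIES]),
                               DYNAMIC_SPECIES)
  out <- dplyr::transmute(
    long,
    driver = driver, factor = .data$factor, species = .data$species,
    converged = .data$converged,
    log2_flux = log2(.data$pe_flux / base$pe_flux[1]),
    log2_conc = log2(.data$conc / base_conc[.data$species])
  )
  class(out) <- c("trend_curves", class(out))
  out
}

#' Sign and slope of each species' trend against PE flux
#'
#' Least-squares slope of `log2_conc` on `log2_flux` per species from a
#' [predict_trends()] result.
#'
#' @param trends A `trend_curves` tibble.
#' @return Tibble with `species`, `slope` and `sign` (-1, 0 or +1).
#' @export
trend_signs <- function(trends) {
  stopifnot(inherits(trends, "trend_curves"))
  ok <- trends[trends$converged, ]
  dplyr::summarise(
    dplyr::group_by(ok, .data$species),
    slope = {
      fx <- .data$log2_flux
      cc <- .data$log2_conc
      sum((fx - mean(fx)) * (cc - mean(cc))) / sum((fx - mean(fx))^2)
    },
    sign = sign(ifelse(abs(.data$slope) < 1e-8, 0, .data$slope)),
    .groups = "drop"
  )
}

#' Robustness of PlsB-driven trend signs to parameter variation
#'
#' Resamples every kinetic parameter (Vmax, Km, Ki) log-uniformly within a
#' fold-range centred on its default, recomputes the PlsB-driver trend
#' signs for each sampled parameter set, and reports, per species, the
#' fraction of converged samples whose sign matches the unperturbed model.
#'
#' @param model A [pathway_model()].
#' @param range Total fold-span of the perturbation (4 = each parameter
#'   multiplied by a factor in `[1/2, 2]`); `range = 1` leaves parameters
#'   untouched.
#' @param n_samples Number of parameter sets to draw.
#' @param seed Integer seed; the report is bit-identical for a fixed seed.
#' @param factors Driver factor grid handed to [predict_trends()].
#' @return A tibble of class `robustness_report`: `species`,
#'   `baseline_sign`, `agree_fraction`, `n_used`; attributes carry `seed`,
#'   `range` and the count of non-converged (excluded) samples.
#' @export
robustness_analysis <- function(model, range = 4, n_samples = 100, seed = 1,
                                factors = c(0.5, 1, 2)) {
  stopifnot(inherits(model, "pathway_model"), range >= 1, n_samples >= 1)
  base_sign <- trend_signs(predict_trends(model, "PLSB", factors = factors))
  half_log <- log(range) / 2
  draw <- function(m) {
    for (rxn in REACTIONS) {
      for (fld in intersect(names(m$kinetics[[rxn]]),
                            c("vmax", "km_a", "km_b", "ki_ppgpp"))) {
        m$kinetics[[rxn]][[fld]] <-
          m$kinetics[[rxn]][[fld]] * exp(stats::runif(1, -half_log, half_log))
      }
      if (!is.null(m$kinetics[[rxn]]$inhibitors)) {
        ki <- m$kinetics[[rxn]]$inhibitors$ki
        m$kinetics[[rxn]]$inhibitors$ki <-
          ki * exp(stats::runif(length(ki), -half_log, half_log))
      }
    }
    m
  }
  signs <- matrix(NA_real_, nrow = n_samples,
                  ncol = length(DYNAMIC_SPECIES),
                  dimnames = list(NULL, DYNAMIC_SPECIES))
  n_failed <- 0L
  .with_seed(seed, {
    for (i in seq_len(n_samples)) {
      m_i <- draw(model)
      tr <- tryCatch(predict_trends(m_i, "PLSB", factors = factors),
                     error = function(e) NULL)
      if (is.null(tr) || !all(tr$converged)) {
        n_failed <- n_failed + 1L
        next
      }
      sg <- trend_signs(tr)
      signs[i, sg$species] <- sg$sign
    }
  })
  used <- !is.na(signs[, 1, drop = TRUE])
  out <- tibble::tibble(
    species = base_sign$species,
    baseline_sign = base_sign$sign,
    agree_fraction = vapply(base_sign$species, function(sp) {
      mean(signs[used, sp] == base_sign$sign[base_sign$species == sp])
    }, numeric(1)),
    n_used = sum(used)
  )
  class(out) <- c("robustness_report", class(out))
  attr(out, "seed") <- seed
  attr(out, "range") <- range
  attr(out, "n_excluded") <- n_failed
  out
}

# evaluate expr under a fixed RNG state, restoring the caller's state after
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
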