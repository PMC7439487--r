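#' Specification for a synthetic steady-state condition table
#'
#' Describes the structure the generator emulates: a set of steady-state
#' growth conditions spanning a 3-fold range of growth rates, a few
#' biological replicate series each sampled in triplicate, LC/MS-style
#' counts with multiplicative lognormal noise, and a growth-rate-to-PlsB
#' activity mapping under which PL flux spans about 2-fold (the flux rises
#' more slowly than growth because membrane per biomass falls with growth
#' rate).
#'
#' @param n_conditions Number of growth conditions (default 6).
#' @param mu_range Growth-rate range in 1/h; default `c(0.3, 0.9)` (3-fold).
#' @param n_bio Biological replicate series per condition (default 2).
#' @param n_tech Sampling replicates per culture (default 3).
#' @param noise_cv Fractional measurement CV of the multiplicative lognormal
#'   noise (default 0.1).
#' @param bio_cv Extra lognormal CV shared within a biological replicate
#'   series (default 0.05).
#' @param seed Integer seed; a fixed seed gives a bit-identical table.
#' @param vmax_fold_range Total fold-span of PlsB Vmax across the mu range
#'   (default 4, i.e. factors from 1/2 to 2 around baseline), under which
#'   the calibrated model's PE flux spans about 2-fold.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_conditions = 6, mu_range = c(0.3, 0.9),
                           n_bio = 2, n_tech = 3, noise_cv = 0.1,
                           bio_cv = 0.05, seed = 1, vmax_fold_range = 4) {
  stopifnot(n_conditions >= 2, length(mu_range) == 2, all(mu_range > 0),
            mu_range[2] > mu_range[1], n_bio >= 1, n_tech >= 1,
            noise_cv >= 0, bio_cv >= 0, vmax_fold_range >= 1)
  structure(
    list(n_conditions = n_conditions, mu_range = mu_range, n_bio = n_bio,
         n_tech = n_tech, noise_cv = noise_cv, bio_cv = bio_cv,
         seed = as.integer(seed), vmax_fold_range = vmax_fold_range),
    class = "synthetic_spec"
  )
}

# solve the per-condition steady states implied by the mu -> PlsB mapping
.condition_states <- function(spec, model) {
  mu <- exp(seq(log(spec$mu_range[1]), log(spec$mu_range[2]),
                length.out = spec$n_conditions))
  half <- log(spec$vmax_fold_range) / 2
  fac <- exp(seq(-half, half, length.out = spec$n_conditions))
  init <- NULL
  rows <- vector("list", spec$n_conditions)
  for (i in seq_len(spec$n_conditions)) {
    m_i <- .apply_factor(model, "PLSB", fac[i])
    ss <- find_steady_state(m_i, init = init)
    if (!ss$converged) {
      stop("steady state did not converge for condition ", i,
           " (mu = ", signif(mu[i], 3), ", PlsB factor = ",
           signif(fac[i], 3), ")", call. = FALSE)
    }
    init <- ss$concentrations
    rows[[i]] <- tibble::tibble(
      condition = sprintf("C%d", i), mu = mu[i], plsb_factor = fac[i],
      pe_flux = ss$pe_flux, lps_flux = ss$lps_flux,
      !!!as.list(ss$concentrations)
    )
  }
  dplyr::bind_rows(rows)
}

# analyte panel: model species plus flat enzyme/nucleotide surrogates
.analyte_panel <- function(states) {
  mu <- states$mu
  species <- tibble::tibble(
    analyte = rep(DYNAMIC_SPECIES, each = nrow(states)),
    condition = rep(states$condition, times = length(DYNAMIC_SPECIES)),
    conc = unlist(lapply(DYNAMIC_SPECIES, function(sp) states[[sp]])),
    class = rep(ifelse(DYNAMIC_SPECIES %in% PL_SPECIES,
                       "pl_intermediate", "soluble"),
                each = nrow(states))
  )
  extras <- dplyr::bind_rows(
    tibble::tibble(analyte = "plsb", condition = states$condition,
                   conc = 1, class = "enzyme"),
    tibble::tibble(analyte = "lpxc", condition = states$condition,
                   conc = 1, class = "enzyme"),
    tibble::tibble(analyte = "ppgpp", condition = states$condition,
                   conc = 1 / mu, class = "soluble"),
    tibble::tibble(analyte = "acetyl_coa", condition = states$condition,
                   conc = 1, class = "soluble")
  )
  dplyr::bind_rows(species, extras)
}

#' Generate a synthetic steady-state condition table with planted truth
#'
#' Maps each condition's growth rate to a PlsB Vmax multiplier (log-linear
#' across the spec's fold range), solves the model steady state, converts
#' concentrations to LC/MS-style counts via per-analyte response factors,
#' adds multiplicative lognormal measurement noise plus a shared
#' biological-replicate factor, and emits a tidy condition table together
#' with the noiseless planted truth.  Total-PE counts are constructed so
#' that operational PL flux (total PE x mu) equals the model's PE flux,
#' which makes total PE per OD decline gently as mu rises.
#'
#' @param spec A [synthetic_spec()].
#' @param model A [pathway_model()]; the default calibrated model.
#' @param states Optional precomputed per-condition steady states (the
#'   `states` element of a previous run's truth with the same spec/model),
#'   to skip re-solving when generating many noise realizations.
#' @return A list with `table` (the condition table) and `truth`
#'   (`states`, per-condition steady states and fluxes;
#'   `report`, the noiseless correlation report with planted `r` and
#'   `sign`; `response_factors`).
#' @export
generate_steady_state_dataset <- function(spec = synthetic_spec(),
                                          model = pathway_model(),
                                          states = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(states)) states <- .condition_states(spec, model)
  panel <- .analyte_panel(states)
  analytes <- unique(panel$analyte)
  flux <- stats::setNames(states$pe_flux, states$condition)
  mu <- stats::setNames(states$mu, states$condition)
  pe_od <- flux / mu   # total PE per biomass, declines with mu

  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  sdlog_bio <- sqrt(log(1 + spec$bio_cv^2))

  .with_seed(spec$seed, {
    rf <- stats::setNames(10^stats::runif(length(analytes), 3, 5), analytes)
    rf_pe <- 10^stats::runif(1, 3, 5)
    is_rf <- stats::setNames(10^stats::runif(length(analytes), 3, 5),
                             analytes)
    is_pe <- 10^stats::runif(1, 3, 5)

    grid <- tidyr::expand_grid(
      condition = states$condition,
      bio_rep = sprintf("B%d", seq_len(spec$n_bio)),
      tech_rep = sprintf("S%d", seq_len(spec$n_tech))
    )
    grid$od <- 0.4 * exp(stats::rnorm(nrow(grid), 0, 0.05))

    bio_fac <- tidyr::expand_grid(
      analyte = c(analytes, "total_pe"),
      bio_rep = sprintf("B%d", seq_len(spec$n_bio))
    )
    bio_fac$bfac <- exp(stats::rnorm(nrow(bio_fac), 0, sdlog_bio))

    rows <- dplyr::inner_join(grid, panel, by = "condition",
                              relationship = "many-to-many")
    rows <- dplyr::left_join(rows, bio_fac, by = c("analyte", "bio_rep"))
    rows$mu <- mu[rows$condition]
    rows$counts <- rows$conc * rows$od * rf[rows$analyte] * rows$bfac *
      exp(stats::rnorm(nrow(rows), 0, sdlog))
    rows$is_counts <- is_rf[rows$analyte]

    pe_rows <- grid
    pe_rows <- dplyr::left_join(
      pe_rows, bio_fac[bio_fac$analyte == "total_pe", ], by = "bio_rep"
    )
    pe_rows$analyte <- "total_pe"
    pe_rows$class <- "total_pe"
    pe_rows$mu <- mu[pe_rows$condition]
    pe_rows$conc <- pe_od[pe_rows$condition]
    pe_rows$counts <- pe_rows$conc * pe_rows$od * rf_pe * pe_rows$bfac *
      exp(stats::rnorm(nrow(pe_rows), 0, sdlog))
    pe_rows$is_counts <- is_pe
  })

  table <- dplyr::bind_rows(rows, pe_rows)[, CONDITION_TABLE_COLS]
  table <- dplyr::arrange(table, .data$condition, .data$bio_rep,
                          .data$tech_rep, .data$analyte)

  # planted truth: the same table without any noise, run through the pipeline
  noiseless <- dplyr::bind_rows(
    dplyr::mutate(dplyr::inner_join(grid[, 1:3], panel, by = "condition",
                                    relationship = "many-to-many"),
                  od = 0.4, mu = mu[.data$condition],
                  counts = .data$conc * 0.4 * rf[.data$analyte],
                  is_counts = is_rf[.data$analyte]),
    dplyr::mutate(grid[, 1:3],
                  analyte = "total_pe", class = "total_pe", od = 0.4,
                  mu = mu[.data$condition],
                  counts = pe_od[.data$condition] * 0.4 * rf_pe,
                  is_counts = is_pe)
  )[, CONDITION_TABLE_COLS]
  truth_report <- correlation_report(noiseless)
  truth_report$sign <- sign(truth_report$r)

  list(
    table = table,
    truth = list(states = states, report = truth_report,
                 response_factors = c(rf, total_pe = rf_pe))
  )
}

#' Tiny deterministic fixture table
#'
#' A 3-condition, 2-analyte condition table (plus the required total-PE
#' rows) for unit tests and examples.  Analyte `up` rises with flux,
#' analyte `down` falls.
#'
#' @param seed Integer seed.
#' @return A condition table tibble.
#' @export
generate_fixture_table <- function(seed = 1) {
  mu <- c(C1 = 0.3, C2 = 0.5, C3 = 0.9)
  flux <- c(C1 = 1, C2 = 1.4, C3 = 2)
  .with_seed(seed, {
    grid <- tidyr::expand_grid(condition = names(mu),
                               bio_rep = c("B1", "B2"), tech_rep = "S1")
    grid$mu <- mu[grid$condition]
    grid$od <- 0.4
    noise <- function(n) exp(stats::rnorm(n, 0, 0.05))
    up <- dplyr::mutate(grid, analyte = "up", class = "soluble",
                        counts = 1000 * flux[.data$condition] *
                          noise(nrow(grid)),
                        is_counts = 500)
    down <- dplyr::mutate(grid, analyte = "down", class = "soluble",
                          counts = 1000 / flux[.data$condition] *
                            noise(nrow(grid)),
                          is_counts = 500)
    pe <- dplyr::mutate(grid, analyte = "total_pe", class = "total_pe",
                        counts = 2000 * flux[.data$condition] /
                          mu[.data$condition] * noise(nrow(grid)) * .data$od,
                        is_counts = 800)
  })
  dplyr::bind_rows(up, down, pe)[, CONDITION_TABLE_COLS]
}
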