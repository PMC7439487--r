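# shared fixtures: built in code, no files

default_model <- function() pathway_model()

# kinetics with every Vmax = 1, every Km = 1, no inhibition: rates are
# hand-evaluable products of simple saturation factors
unit_kinetics <- function() {
  k <- default_kinetics()
  for (rxn in names(k)) {
    k[[rxn]]$vmax <- 1
    k[[rxn]]$km_a <- 1
    if (!is.null(k[[rxn]]$km_b)) k[[rxn]]$km_b <- 1
    k[[rxn]]$inhibitors <- NULL
  }
  k$ACC$inhibitors <- NULL
  k
}

unit_state <- function(value = 1) {
  stats::setNames(rep(value, length(dynamic_species())), dynamic_species())
}

# random nonnegative states with the default ACP total, reproducible
random_states <- function(n, seed = 42) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      acp <- stats::runif(6)
      acp <- acp / sum(acp) * 30
      st <- c(acp, stats::runif(4, 0, 5))
      stats::setNames(st, dynamic_species())
    })
  })
}

# model with every kinetic parameter jittered log-uniformly within `fold`
perturbed_model <- function(seed, fold = 2) {
  m <- pathway_model()
  half <- log(fold) / 2
  withr::with_seed(seed, {
    for (rxn in reaction_ids()) {
      for (fld in intersect(names(m$kinetics[[rxn]]),
                            c("vmax", "km_a", "km_b", "ki_ppgpp"))) {
        m$kinetics[[rxn]][[fld]] <-
          m$kinetics[[rxn]][[fld]] * exp(stats::runif(1, -half, half))
      }
    }
  })
  m
}

# minimal condition table from per-condition values of one analyte,
# with flat total-PE rows so PL flux is computable
mini_table <- function(values, mu = NULL, od = 1, analyte = "x",
                       class = "soluble", pe_counts = 100) {
  n <- length(values)
  conditions <- sprintf("C%d", seq_len(n))
  if (is.null(mu)) mu <- seq(0.3, 0.9, length.out = n)
  dplyr::bind_rows(
    tibble::tibble(condition = conditions, bio_rep = "B1", tech_rep = "S1",
                   mu = mu, od = od, analyte = analyte, counts = values,
                   is_counts = 1, class = class),
    tibble::tibble(condition = conditions, bio_rep = "B1", tech_rep = "S1",
                   mu = mu, od = od, analyte = "total_pe",
                   counts = pe_counts, is_counts = 1, class = "total_pe")
  )
}
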