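#' Irreversible Michaelis-Menten rate with competitive inhibition
#'
#' Computes `vmax * s / (km * (1 + sum(i_conc / i_ki)) + s)`: the standard
#' irreversible single-substrate Michaelis-Menten rate law with any number of
#' competitive inhibitors acting on the substrate site (each inhibitor scales
#' the apparent Km by `1 + I/Ki`).
#'
#' @param vmax Maximal rate (uM/min), must be positive.
#' @param s Substrate concentration (uM), must be nonnegative.
#' @param km Michaelis constant (uM), must be positive.
#' @param inhibitors Optional inhibitor spec: a data frame / tibble with
#'   columns `conc` and `ki`, or a list of length-2 numeric vectors
#'   `c(conc, ki)`. All `ki` must be positive and `conc` nonnegative.
#'
#' @return The reaction rate (uM/min), a single nonnegative number.
#'   Monotone increasing in `s`, decreasing in every inhibitor concentration.
#' @examples
#' competitive_mm_rate(1, s = 2, km = 2)                    # half-saturation
#' competitive_mm_rate(1, s = 2, km = 2,
#'   inhibitors = data.frame(conc = 1, ki = 1))             # apparent Km doubles
#' @export
competitive_mm_rate <- function(vmax, s, km, inhibitors = NULL) {
  inh <- .parse_inhibitors(inhibitors)
  .check_kinetic_args(vmax, km, inh$ki)
  if (any(s < 0) || any(inh$conc < 0)) {
    stop("substrate and inhibitor concentrations must be nonnegative",
         call. = FALSE)
  }
  .mm(vmax, s, km, inh$conc, inh$ki)
}

#' Two-substrate irreversible Michaelis-Menten rate
#'
#' Separable double-saturation rate law
#' `vmax * [a / (km_a * (1 + sum(I/Ki)) + a)] * [b / (km_b + b)]`,
#' with competitive inhibitors (if any) acting on the first substrate's site.
#'
#' @param vmax Maximal rate (uM/min), positive.
#' @param a,b Substrate concentrations (uM), nonnegative.
#' @param km_a,km_b Michaelis constants (uM), positive.
#' @param inhibitors_on_a Competitive inhibitors of the `a` site, same format
#'   as in [competitive_mm_rate()].
#'
#' @return The reaction rate (uM/min).
#' @export
two_substrate_mm_rate <- function(vmax, a, km_a, b, km_b,
                                  inhibitors_on_a = NULL) {
  inh <- .parse_inhibitors(inhibitors_on_a)
  .check_kinetic_args(vmax, c(km_a, km_b), inh$ki)
  if (any(c(a, b) < 0) || any(inh$conc < 0)) {
    stop("substrate and inhibitor concentrations must be nonnegative",
         call. = FALSE)
  }
  .mm(vmax, a, km_a, inh$conc, inh$ki) * b / (km_b + b)
}

# fast internal kernel: no validation, plain numerics (hot path of the ODE RHS)
.mm <- function(vmax, s, km, i_conc = numeric(0), i_ki = numeric(0)) {
  alpha <- if (length(i_conc)) 1 + sum(i_conc / i_ki) else 1
  vmax * s / (km * alpha + s)
}

.parse_inhibitors <- function(inhibitors) {
  if (is.null(inhibitors) || (is.data.frame(inhibitors) && !nrow(inhibitors))) {
    return(list(conc = numeric(0), ki = numeric(0)))
  }
  if (is.data.frame(inhibitors)) {
    stopifnot(all(c("conc", "ki") %in% names(inhibitors)))
    return(list(conc = as.numeric(inhibitors$conc),
                ki = as.numeric(inhibitors$ki)))
  }
  if (is.list(inhibitors)) {
    m <- do.call(rbind, lapply(inhibitors, function(x) as.numeric(x[1:2])))
    return(list(conc = m[, 1], ki = m[, 2]))
  }
  stop("inhibitors must be NULL, a data frame with columns conc/ki, ",
       "or a list of c(conc, ki) pairs", call. = FALSE)
}

.check_kinetic_args <- function(vmax, km, ki) {
  if (any(!is.finite(vmax)) || any(vmax <= 0)) {
    stop("vmax must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(km)) || any(km <= 0)) {
    stop("all Km must be positive and finite", call. = FALSE)
  }
  if (length(ki) && (any(!is.finite(ki)) || any(ki <= 0))) {
    stop("all Ki must be positive and finite", call. = FALSE)
  }
  invisible(TRUE)
}
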