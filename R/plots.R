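#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot flux response curves from a Vmax scan
#'
#' PE and LPS steady-state fluxes, relative to the factor-1 baseline, against
#' the scan multiplier (log2 axes).
#'
#' @param object A [scan_vmax()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vmax_scan
#' @export
autoplot.vmax_scan <- function(object, ...) {
  base <- object[object$factor == 1, ]
  if (!nrow(base)) stop("scan has no factor-1 baseline row", call. = FALSE)
  d <- tidyr::pivot_longer(
    dplyr::transmute(object, factor = .data$factor,
                     PE = .data$pe_flux / base$pe_flux[1],
                     LPS = .data$lps_flux / base$lps_flux[1]),
    cols = c("PE", "LPS"), names_to = "flux", values_to = "rel"
  )
  ggplot2::ggplot(d, ggplot2::aes(log2(.data$factor), log2(.data$rel),
                                  colour = .data$flux)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = bquote(log[2] ~ "factor on" ~ .(object$target[1])),
                  y = expression(log[2] ~ "flux / baseline"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot predicted concentration-versus-flux trends
#'
#' One line per species: log2 concentration change against log2 PE-flux
#' change along the driver scan; all curves pass through the origin at the
#' baseline.
#'
#' @param object A [predict_trends()] result.
#' @param species Species subset to show; defaults to all.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trend_curves
#' @export
autoplot.trend_curves <- function(object, species = NULL, ...) {
  d <- if (is.null(species)) object else
    object[object$species %in% species, ]
  ggplot2::ggplot(d[d$converged, ],
                  ggplot2::aes(.data$log2_flux, .data$log2_conc,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = expression(log[2] ~ "PE flux / baseline"),
                  y = expression(log[2] ~ "concentration / baseline"),
                  title = paste("driver:", object$driver[1])) +
    ggplot2::theme_minimal()
}

#' Plot baseline-normalized perturbation trajectories
#'
#' @param object A [simulate_timecourse()] result.
#' @param species Species subset; defaults to the conserved-pool species.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trajectories
#' @export
autoplot.trajectories <- function(object, species = ACP_SPECIES, ...) {
  d <- object[object$type == "concentration" & object$name %in% species, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$normalized,
                                       colour = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "concentration / pre-event baseline",
                  colour = NULL) +
    ggplot2::theme_minimal()
  ev <- attr(object, "first_event")
  if (is.finite(ev)) p <- p + ggplot2::geom_vline(xintercept = ev,
                                                  linetype = 2)
  p
}

#' Plot a correlation report
#'
#' Per-analyte Pearson r, ordered, coloured by two-tailed significance at
#' the 5\% level.
#'
#' @param object A [correlation_report()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot correlation_report
#' @export
autoplot.correlation_report <- function(object, ...) {
  d <- dplyr::mutate(object,
                     analyte = stats::reorder(.data$analyte, .data$r),
                     significant = .data$p < 0.05)
  ggplot2::ggplot(d, ggplot2::aes(.data$r, .data$analyte,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Pearson r with PL flux", y = NULL,
                  fill = "P < 0.05") +
    ggplot2::theme_minimal()
}
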