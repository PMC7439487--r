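#' Event schedule for dynamic perturbations
#'
#' A schedule of step changes to the model's fixed boundary inputs, e.g. a
#' ppGpp step emulating induced alarmone synthesis, or an acetyl-CoA step
#' emulating carbon overflow after translation inhibition.
#'
#' @param time Event times (min), strictly increasing.
#' @param input Fixed-input names (`"acetyl_coa"`, `"g3p"`, `"c16_1_acp"`,
#'   `"ppgpp"`).
#' @param value New values (uM), nonnegative.
#' @return A tibble of class `event_schedule`.
#' @examples
#' event_schedule(time = 0, input = "ppgpp", value = 500)
#' @export
event_schedule <- function(time = numeric(0), input = character(0),
                           value = numeric(0)) {
  stopifnot(length(time) == length(input), length(time) == length(value))
  if (length(time)) {
    if (any(diff(time) <= 0)) {
      stop("event times must be strictly increasing", call. = FALSE)
    }
    if (any(value < 0)) stop("event values must be >= 0", call. = FALSE)
    bad <- setdiff(input, FIXED_SPECIES)
    if (length(bad)) {
      stop("unknown fixed input(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  out <- tibble::tibble(time = time, input = input, value = value)
  class(out) <- c("event_schedule", class(out))
  out
}

#' Simulate a perturbation time course
#'
#' Piecewise ODE integration of the pathway from a steady state, restarting
#' the integrator exactly at each scheduled boundary-input step.  Output
#' series are also reported normalized to the pre-event baseline (the mean
#' over grid times before the first event, or the initial state when the
#' first event is at the grid start), so a value of 1 means "unchanged from
#' before the perturbation".
#'
#' @param model A [pathway_model()] describing the pre-event system.
#' @param init Initial state; defaults to the model's computed steady state
#'   (recommended, so that pre-event series are flat).
#' @param events An [event_schedule()] (possibly empty).
#' @param grid Output time grid (min), increasing; events must not precede
#'   the grid start.
#' @return A tidy tibble of class `trajectories`: columns `time`, `name`,
#'   `type` (`"concentration"` or `"flux"`), `value`, `normalized`.
#' @export
simulate_timecourse <- function(model, init = NULL,
                                events = event_schedule(),
                                grid = seq(0, 60, by = 0.5)) {
  stopifnot(inherits(model, "pathway_model"), length(grid) >= 2,
            all(diff(grid) > 0))
  if (!inherits(events, "event_schedule")) {
    stop("events must be an event_schedule()", call. = FALSE)
  }
  if (nrow(events) && events$time[1] < grid[1]) {
    stop("event at t = ", events$time[1], " precedes the grid start",
         call. = FALSE)
  }
  if (is.null(init)) {
    ss <- find_steady_state(model)
    if (!ss$converged) stop("could not converge the pre-event steady state",
                            call. = FALSE)
    init <- ss$concentrations
  } else if (inherits(init, "ss_fit")) {
    init <- init$concentrations
  }
  init <- .as_state(init)

  if (nrow(events) && any(events$time >= grid[length(grid)])) {
    events <- events[events$time < grid[length(grid)], ]
  }
  breaks <- sort(unique(c(grid[1], if (nrow(events)) events$time,
                          grid[length(grid)])))
  y <- init
  m <- model
  conc_rows <- list()
  seen_first <- FALSE
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]
    t1 <- breaks[i + 1]
    ev <- if (nrow(events)) events[events$time == t0, ] else events
    for (j in seq_len(nrow(ev))) m$fixed[[ev$input[j]]] <- ev$value[j]
    seg_times <- sort(unique(c(t0, grid[grid > t0 & grid <= t1], t1)))
    out <- deSolve::lsoda(y, times = seg_times, func = .ode_rhs,
                          parms = list(S = m$stoichiometry, model = m),
                          rtol = 1e-10, atol = 1e-12)
    y <- stats::setNames(as.numeric(out[nrow(out), -1]), DYNAMIC_SPECIES)
    keep <- out[, "time"] %in% grid &
      (!seen_first | out[, "time"] > t0)   # avoid duplicating break rows
    seen_first <- TRUE
    conc_rows[[i]] <- list(times = out[keep, "time"],
                           states = out[keep, -1, drop = FALSE],
                           model = m)
  }
  times <- unlist(lapply(conc_rows, `[[`, "times"))
  states <- do.call(rbind, lapply(conc_rows, `[[`, "states"))
  seg_id <- rep(seq_along(conc_rows),
                vapply(conc_rows, function(s) length(s$times), integer(1)))
  fluxes <- t(vapply(seq_along(times), function(i) {
    st <- stats::setNames(pmax(as.numeric(states[i, ]), 0), DYNAMIC_SPECIES)
    .rates(st, conc_rows[[seg_id[i]]]$model)
  }, numeric(length(REACTIONS))))
  colnames(fluxes) <- REACTIONS

  first_event <- if (nrow(events)) events$time[1] else Inf
  pre <- times < first_event
  base_of <- function(mat) {
    if (any(pre)) colMeans(mat[pre, , drop = FALSE]) else mat[1, ]
  }
  conc_base <- base_of(states)
  flux_base <- base_of(fluxes)

  long <- function(mat, base, type) {
    tibble::tibble(
      time = rep(times, times = ncol(mat)),
      name = rep(colnames(mat), each = length(times)),
      type = type,
      value = as.numeric(mat),
      normalized = as.numeric(sweep(mat, 2, base, "/"))
    )
  }
  out <- dplyr::bind_rows(
    long(states, conc_base, "concentration"),
    long(fluxes, flux_base, "flux")
  )
  out <- dplyr::arrange(out, .data$type, .data$name, .data$time)
  class(out) <- c("trajectories", class(out))
  attr(out, "first_event") <- first_event
  out
}

#' Order of species depletion after a perturbation
#'
#' Finds, for each requested species, the first time its baseline-normalized
#' concentration falls below a threshold, interpolating linearly between
#' grid points, and returns the species sorted by that crossing time.
#' Species that never cross are listed last with `crossing_time = NA`.
#'
#' @param traj A [simulate_timecourse()] result.
#' @param species Character vector of dynamic species to rank.
#' @param threshold Fraction of baseline in `(0, 1)`; default 0.5.
#' @return Tibble with `species`, `crossing_time` (min), `crossed`.
#' @export
depletion_order <- function(traj, species = PL_SPECIES, threshold = 0.5) {
  stopifnot(inherits(traj, "trajectories"),
            threshold > 0, threshold < 1)
  if (!nrow(traj)) stop("empty trajectory", call. = FALSE)
  cross_time <- function(sp) {
    d <- traj[traj$name == sp & traj$type == "concentration", ]
    if (!nrow(d)) stop("species not in trajectory: ", sp, call. = FALSE)
    below <- which(d$normalized < threshold)
    if (!length(below)) return(NA_real_)
    i <- below[1]
    if (i == 1) return(d$time[1])
    t0 <- d$time[i - 1]; t1 <- d$time[i]
    v0 <- d$normalized[i - 1]; v1 <- d$normalized[i]
    t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
  }
  out <- tibble::tibble(
    species = species,
    crossing_time = unname(vapply(species, cross_time, numeric(1)))
  )
  out$crossed <- !is.na(out$crossing_time)
  dplyr::arrange(out, !.data$crossed, .data$crossing_time)
}
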