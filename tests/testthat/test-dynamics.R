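test_that("an event-free time course stays at the steady state", {
  m <- default_model()
  ss <- find_steady_state(m)
  tr <- simulate_timecourse(m, init = ss, grid = seq(0, 200, by = 2))
  conc <- tr[tr$type == "concentration", ]
  drift <- abs(conc$normalized - 1)
  expect_lt(max(drift), 1e-6)
})

test_that("event validation catches malformed schedules", {
  expect_error(event_schedule(time = c(2, 1), input = c("ppgpp", "ppgpp"),
                              value = c(1, 1)), "increasing")
  expect_error(event_schedule(time = 1, input = "nonsense", value = 1),
               "unknown fixed input")
  expect_error(event_schedule(time = 1, input = "ppgpp", value = -1), ">= 0")
  m <- default_model()
  expect_error(
    simulate_timecourse(m, events = event_schedule(-5, "ppgpp", 100),
                        grid = seq(0, 10, by = 1)),
    "precedes"
  )
})

test_that("a saturating ppGpp step reproduces the stringent-response cascade", {
  m <- default_model()
  ss <- find_steady_state(m)
  ki <- m$kinetics$PLSB_C16$ki_ppgpp
  ev <- event_schedule(time = 2, input = "ppgpp", value = 20 * ki)
  tr <- simulate_timecourse(m, init = ss, events = ev,
                            grid = seq(0, 60, by = 0.1))
  end_norm <- function(nm, type = "concentration") {
    d <- tr[tr$name == nm & tr$type == type, ]
    d$normalized[nrow(d)]
  }
  # PlsB inhibition: its acyl-ACP substrates pile up ...
  expect_gt(end_norm("c16_acp"), 1)
  expect_gt(end_norm("c18_acp"), 1)
  # ... which inhibits ACC and drains malonyl-ACP
  expect_lt(end_norm("malonyl_acp"), 1)
  # PE flux is strictly lower after the step
  expect_lt(end_norm("PSD", "flux"), 1)
  # ACP conservation holds along the whole event trajectory
  acp_rows <- tr$type == "concentration" & tr$name %in% acp_species()
  totals <- tapply(tr$value[acp_rows], tr$time[acp_rows], sum)
  expect_lt(max(abs(totals - 30)) / 30, 1e-6)
})

test_that("PL intermediates deplete in pathway order after PlsB shutdown", {
  m <- default_model()
  ss <- find_steady_state(m)
  ki <- m$kinetics$PLSB_C16$ki_ppgpp
  ev <- event_schedule(time = 1, input = "ppgpp", value = 20 * ki)
  tr <- simulate_timecourse(m, init = ss, events = ev,
                            grid = seq(0, 10, by = 0.01))
  ord <- depletion_order(tr, pl_species())
  expect_true(all(ord$crossed))
  expect_equal(ord$species, c("lpa", "pa", "cdp_dag", "ps"))
  expect_true(all(diff(ord$crossing_time) > 0))
})

test_that("depletion_order interpolates hand-set crossings correctly", {
  # constructed two-species fixture: linear decays crossing 0.5 at t = 2 and 4
  traj <- tibble::tibble(
    time = rep(seq(0, 5, by = 1), times = 2),
    name = rep(c("fast", "slow"), each = 6),
    type = "concentration",
    value = 1,
    normalized = c(1 - 0.25 * (0:5), 1 - 0.125 * (0:5))
  )
  class(traj) <- c("trajectories", class(traj))
  ord <- depletion_order(traj, c("slow", "fast"))
  expect_equal(ord$species, c("fast", "slow"))
  expect_equal(ord$crossing_time, c(2, 4))
  # constant trajectories never cross
  traj$normalized <- 1
  ord2 <- depletion_order(traj, c("fast", "slow"))
  expect_true(all(!ord2$crossed))
  expect_true(all(is.na(ord2$crossing_time)))
})
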