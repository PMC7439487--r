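test_that("the calibrated baseline state is a fixed point of the solver", {
  m <- default_model()
  expect_equal(max(abs(time_derivatives(baseline_state(), m))), 0)
  ss <- find_steady_state(m, init = baseline_state())
  expect_true(ss$converged)
  expect_lte(ss$residual, 1e-9)
  expect_equal(ss$concentrations, baseline_state(), tolerance = 1e-8)
  expect_equal(pathway_fluxes(ss)$pe_flux, 10, tolerance = 1e-8)
  expect_equal(pathway_fluxes(ss)$lps_flux, 3, tolerance = 1e-8)
})

test_that("downstream pools match the closed-form s* = Km*J/(V - J)", {
  # each irreversible consumer at steady state satisfies
  # J = V * s / (Km + s)  =>  s* = Km * J / (V - J); for the branch species
  # two consumers with a shared Km give s* = Km * J / (V1 + V2 - J)
  m <- default_model()
  ss <- find_steady_state(m)
  J <- ss$pe_flux
  for (sp_rxn in list(c("ps", "PSD"), c("pa", "CDSA"))) {
    k <- m$kinetics[[sp_rxn[2]]]
    expect_equal(ss$concentrations[[sp_rxn[1]]],
                 k$km_a * J / (k$vmax - J), tolerance = 1e-7)
  }
  kf <- m$kinetics$FABZ
  kl <- m$kinetics$LPXC
  J_branch <- ss$fluxes[["FABZ"]] + ss$fluxes[["LPXC"]]
  expect_equal(ss$concentrations[["c14_oh_acp"]],
               kf$km_a * J_branch / (kf$vmax + kl$vmax - J_branch),
               tolerance = 1e-7)
})

test_that("steady-state fluxes balance at every internal node", {
  m <- default_model()
  for (seed in c(1, 7)) {
    ss <- find_steady_state(perturbed_model(seed))
    expect_true(ss$converged)
    f <- ss$fluxes
    expect_equal(f[["PSD"]], f[["PLSB_C16"]] + f[["PLSB_C18"]],
                 tolerance = 1e-7)
    expect_equal(f[["ELONG_C14OH"]], f[["FABZ"]] + f[["LPXC"]],
                 tolerance = 1e-7)
    expect_equal(f[["ACC"]],
                 f[["ELONG_C14OH"]] + f[["ELONG_C16"]] + f[["ELONG_C18"]],
                 tolerance = 1e-7)
  }
})

test_that("integration and root-refinement routes agree", {
  for (m in list(default_model(), perturbed_model(3), perturbed_model(11))) {
    a <- find_steady_state(m, method = "integrate")
    b <- find_steady_state(m, method = "hybrid")
    expect_true(a$converged && b$converged)
    expect_equal(a$concentrations, b$concentrations, tolerance = 1e-6)
    expect_equal(a$pe_flux, b$pe_flux, tolerance = 1e-6)
  }
})

test_that("solver conserves the ACP total of its starting point", {
  m <- default_model()
  for (st in random_states(5)) {
    ss <- find_steady_state(m, init = st)
    expect_true(ss$converged)
    expect_equal(total_acp(ss$concentrations), total_acp(st),
                 tolerance = 1e-6)
  }
})

test_that("scan at factor 1 reproduces the baseline exactly", {
  m <- default_model()
  base <- find_steady_state(m)
  sc <- scan_vmax(m, "PLSB", factors = c(0.5, 1, 2))
  row1 <- sc[sc$factor == 1, ]
  expect_equal(row1$pe_flux, base$pe_flux, tolerance = 1e-7)
  expect_equal(row1$lps_flux, base$lps_flux, tolerance = 1e-7)
  expect_true(all(sc$converged))
  expect_error(scan_vmax(m, "NOT_A_TARGET", 1), "unknown")
})

test_that("PE flux responds monotonically to PlsB and acetyl-CoA", {
  m <- default_model()
  for (tg in c("PLSB", "acetyl_coa")) {
    sc <- scan_vmax(m, tg, factors = 2^seq(-2, 2, by = 0.5))
    expect_true(all(sc$converged))
    expect_true(all(diff(sc$pe_flux[order(sc$factor)]) >= 0))
  }
})

test_that("control coefficients respect the summation theorem", {
  fcc <- flux_control_coefficients(default_model())
  g <- glance(fcc)
  expect_equal(g$sum_pe, 1, tolerance = 1e-3)
  expect_equal(g$sum_lps, 1, tolerance = 1e-3)
  expect_equal(g$n_missing, 0)
})

test_that("trend curves pass through the origin at baseline", {
  tr <- predict_trends(default_model(), "PLSB", factors = c(0.5, 1, 2))
  at_base <- tr[tr$factor == 1, ]
  expect_true(all(abs(at_base$log2_flux) < 1e-9))
  expect_true(all(abs(at_base$log2_conc) < 1e-9))
  expect_error(predict_trends(default_model(), "PLSB", factors = c(2, 4)),
               "span")
})

test_that("robustness report is deterministic and trivial at range 1", {
  m <- default_model()
  r0 <- robustness_analysis(m, range = 1, n_samples = 3, seed = 5)
  expect_true(all(r0$agree_fraction == 1))
  expect_equal(attr(r0, "n_excluded"), 0L)
  a <- robustness_analysis(m, range = 4, n_samples = 5, seed = 9)
  b <- robustness_analysis(m, range = 4, n_samples = 5, seed = 9)
  expect_identical(a, b)
})
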