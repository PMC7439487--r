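test_that("stoichiometry closes the ACP pool in every reaction", {
  m <- default_model()
  acp_net <- colSums(m$stoichiometry[acp_species(), ])
  expect_true(all(acp_net == 0))
  # each reaction moves at least one species
  expect_true(all(colSums(abs(m$stoichiometry)) >= 1))
})

test_that("rates vanish at the zero state and stay nonnegative elsewhere", {
  m <- default_model()
  zero <- unit_state(0)
  expect_true(all(reaction_rates(zero, m) == 0))
  for (st in random_states(10)) {
    expect_true(all(reaction_rates(st, m) >= 0))
  }
})

test_that("ACC rate with unit parameters matches the hand evaluation", {
  # all Vmax = Km = 1, no inhibitors, acetyl-CoA = holo-ACP = 1:
  # rate = (1/(1+1)) * (1/(1+1)) = 0.25
  m <- pathway_model(kinetics = unit_kinetics(),
                     fixed = fixed_inputs(acetyl_coa = 1, g3p = 1,
                                          c16_1_acp = 1),
                     acp_total = 6)
  v <- reaction_rates(unit_state(1), m)
  expect_equal(unname(v["ACC"]), 0.25)
  # single-substrate reactions at s = Km: half of Vmax
  expect_equal(unname(v["FABZ"]), 0.5)
  # PLSB with g3p = km_b = 1: 0.5 * 0.5 = 0.25
  expect_equal(unname(v["PLSB_C16"]), 0.25)
})

test_that("derivatives are stoichiometry times rates and conserve ACP", {
  m <- default_model()
  for (st in random_states(10)) {
    d <- time_derivatives(st, m)
    expect_equal(sum(d[acp_species()]), 0, tolerance = 1e-12)
    expect_equal(d, drop(m$stoichiometry %*% reaction_rates(st, m)))
  }
  # product formation in an isolated step: only cdp_dag present, so
  # d(ps)/dt equals the PSSA rate evaluated by hand
  st <- unit_state(0)
  st["cdp_dag"] <- 3
  k <- m$kinetics$PSSA
  expect_equal(time_derivatives(st, m)[["ps"]],
               k$vmax * 3 / (k$km_a + 3))
})

test_that("total_acp sums exactly the six pool members", {
  expect_equal(total_acp(unit_state(0)), 0)
  expect_equal(total_acp(unit_state(1)), 6)
  st <- baseline_state()
  expect_equal(total_acp(st), 30)
  st["lpa"] <- 99  # non-pool species do not contribute
  expect_equal(total_acp(st), 30)
})

test_that("rates scale linearly with Vmax (degree-1 homogeneity)", {
  m <- default_model()
  m2 <- m
  for (rxn in reaction_ids()) m2$kinetics[[rxn]]$vmax <-
      2 * m2$kinetics[[rxn]]$vmax
  st <- baseline_state()
  expect_equal(reaction_rates(st, m2), 2 * reaction_rates(st, m))
})

test_that("model validation reports the offending reaction and key", {
  k <- default_kinetics()
  k$PSD$vmax <- 0
  expect_error(pathway_model(kinetics = k), "PSD.*vmax")
  k <- default_kinetics()
  k$FABZ$inhibitors <- data.frame(species = "c16_acp", ki = 1)
  expect_error(pathway_model(kinetics = k), "only ACC")
  k <- default_kinetics()
  k$BOGUS <- list(vmax = 1, km_a = 1)
  expect_error(pathway_model(kinetics = k), "unknown reaction")
  expect_error(pathway_model(kinetics = default_kinetics()[-1]), "ACC")
  expect_error(fixed_inputs(ppgpp = -1), "nonnegative")
})

test_that("model config round-trips losslessly through YAML", {
  m <- default_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(m, path)
  m2 <- parse_model_config(path)
  expect_equal(m2$kinetics, m$kinetics, tolerance = 1e-12)
  expect_equal(unclass(m2$fixed), unclass(m$fixed))
  expect_equal(m2$acp_total, m$acp_total)
  # and the reloaded model computes identical rates
  expect_equal(reaction_rates(baseline_state(), m2),
               reaction_rates(baseline_state(), m))
})

test_that("config validation catches bad files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  m <- default_model()
  m$kinetics$CDSA$vmax <- 0  # writer does not re-validate; loader must
  write_model_config(m, path)
  expect_error(parse_model_config(path), "CDSA")
  yaml::write_yaml(list(reactions = list(), junk = 1), path)
  expect_error(parse_model_config(path), "junk")
  expect_error(parse_model_config("no/such/file.yaml"), "not found")
})
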