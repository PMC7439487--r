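test_that("operational PL flux is the product of total-PE signal and mu", {
  expect_equal(compute_pl_flux(1e6, 0.5), 5e5)
  expect_equal(compute_pl_flux(123, 0), 0)
  expect_equal(compute_pl_flux(2 * 7, 0.3), 2 * compute_pl_flux(7, 0.3))
  expect_error(compute_pl_flux(-1, 0.5), "nonnegative")
})

test_that("normalization reproduces the hand-computed centred log2 series", {
  # counts {2, 4, 8}, OD and IS all 1: mean is 14/3, ratios {3/7, 6/7, 12/7},
  # log2 -> symmetric {-1, 0, +1}
  tb <- mini_table(c(2, 4, 8))
  ns <- normalize_series(tb, "x", basis = "per_od")
  expect_equal(ns$log2_value, c(-1, 0, 1))
  expect_equal(mean(ns$log2_value), 0)
})

test_that("constant analytes centre to zero and exclusions re-centre", {
  tb <- mini_table(c(5, 5, 5, 5))
  expect_equal(normalize_series(tb, "x")$log2_value, rep(0, 4))
  tb2 <- mini_table(c(2, 4, 8))
  ns <- normalize_series(tb2, "x", exclude_conditions = "C3")
  expect_equal(nrow(ns), 2)
  expect_equal(mean(ns$log2_value), 0)
  expect_equal(ns$log2_value, c(-0.5, 0.5))
})

test_that("normalization is invariant to analyte and IS scale", {
  tb <- mini_table(c(3, 9, 27))
  a <- normalize_series(tb, "x")
  tb_scaled <- tb
  sel <- tb_scaled$analyte == "x"
  tb_scaled$counts[sel] <- tb_scaled$counts[sel] * 1234
  tb_scaled$is_counts[sel] <- tb_scaled$is_counts[sel] * 9.9
  b <- normalize_series(tb_scaled, "x")
  expect_equal(a$log2_value, b$log2_value, tolerance = 1e-12)
})

test_that("per-total-PE basis divides by the matched sample's PE ratio", {
  tb <- mini_table(c(4, 4, 4), pe_counts = c(1, 2, 4))
  ns <- normalize_series(tb, "x", basis = "per_total_pe")
  # 4/pe = {4, 2, 1} -> centred log2 {+1, 0, -1}
  expect_equal(ns$log2_value, c(1, 0, -1))
})

test_that("pearson r and its two-tailed t-based P match hand calculations", {
  expect_equal(pearson_with_significance(1:3, c(2, 4, 6))$r, 1)
  st <- pearson_with_significance(1:3, c(1, 3, 2))
  expect_equal(st$r, 0.5)
  # textbook formula cross-check at n = 5
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  st2 <- pearson_with_significance(x, y)
  tstat <- st2$r * sqrt(3) / sqrt(1 - st2$r^2)
  expect_equal(st2$p, 2 * stats::pt(-abs(tstat), df = 3))
  expect_equal(st2$p, stats::cor.test(x, y)$p.value, tolerance = 1e-12)
  expect_error(pearson_with_significance(1:2, 1:2), "at least 3")
  expect_error(pearson_with_significance(rep(1, 5), 1:5), "zero variance")
})

test_that("t-based P agrees with a permutation null at n = 12", {
  withr::with_seed(7, {
    x <- rnorm(12)
    y <- 0.6 * x + rnorm(12, sd = 0.8)
    st <- pearson_with_significance(x, y)
    r_obs <- abs(st$r)
    perm <- replicate(10000, abs(stats::cor(x, sample(y))))
    p_perm <- mean(perm >= r_obs)
    expect_lt(abs(st$p - p_perm), 0.01)
  })
})

test_that("the report is row-order invariant and accounts for analytes", {
  ds <- generate_steady_state_dataset(synthetic_spec(seed = 3))
  tb <- ds$table
  rep_a <- correlation_report(tb)
  withr::with_seed(1, {
    tb_shuffled <- tb[sample(nrow(tb)), ]
  })
  rep_b <- correlation_report(tb_shuffled)
  ord <- order(rep_a$analyte)
  expect_equal(rep_a$r[ord],
               rep_b$r[order(rep_b$analyte)], tolerance = 1e-12)
  # configured-but-absent analytes are skipped with a warning
  cfg <- tibble::tibble(analyte = c("lpa", "ghost"),
                        basis = c("per_total_pe", "per_od"))
  expect_warning(rep_c <- correlation_report(tb, config = cfg), "ghost")
  expect_equal(nrow(rep_c), 1)
  expect_equal(rep_c$analyte, "lpa")
})

test_that("an analyte tracking flux exactly gives r = 1", {
  flux_vals <- c(1, 1.3, 1.7, 2.2)
  mu <- seq(0.3, 0.9, length.out = 4)
  # total-PE counts chosen so pe_ratio * mu is proportional to flux_vals,
  # and the analyte itself proportional to flux_vals
  tb <- mini_table(flux_vals, mu = mu, pe_counts = flux_vals * 100 / mu)
  rep <- correlation_report(tb)
  expect_equal(rep$r[rep$analyte == "x"], 1, tolerance = 1e-9)
  expect_lt(rep$p[rep$analyte == "x"], 1e-6)
})
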