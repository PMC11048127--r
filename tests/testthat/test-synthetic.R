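test_that("endpoint datasets honour the configured law and dimensions", {
  cfg <- endpoint_sim_config(noise_sd = 0)
  tbl <- simulate_endpoint_dataset(cfg)
  expect_equal(nrow(tbl), 18L)
  expect_equal(sort(unique(tbl$concentration_cells_per_ml)),
               c(0.25, 0.5, 1, 2, 4, 8) * 1e6)
  expect_equal(tbl$f_res_ghz,
               cfg$true_slope * tbl$concentration_cells_per_ml +
                 cfg$true_intercept)
  expect_error(endpoint_sim_config(noise_sd = -0.1), ">= 0")
})

test_that("identical seeds give identical datasets and traces", {
  a <- simulate_endpoint_dataset(endpoint_sim_config(seed = 7))
  b <- simulate_endpoint_dataset(endpoint_sim_config(seed = 7))
  expect_identical(a, b)
  c <- simulate_endpoint_dataset(endpoint_sim_config(seed = 8))
  expect_false(identical(a, c))
  t1 <- simulate_evaporation_trace(
    evaporation_sim_config(1e6, noise_sd = 0.001, seed = 3)
  )
  t2 <- simulate_evaporation_trace(
    evaporation_sim_config(1e6, noise_sd = 0.001, seed = 3)
  )
  expect_identical(t1, t2)
})

test_that("evaporation traces downshift while wet then jump to a plateau", {
  tr <- simulate_evaporation_trace(evaporation_sim_config(1e6))
  wet <- tr$f0_ghz[tr$phase == "wet"]
  dry <- tr$f0_ghz[tr$phase == "dry"]
  expect_true(all(diff(wet) <= 0))
  expect_gt(dry[1], wet[length(wet)]) # upward jump at dry-out
  expect_equal(sd(dry), 0)            # stable plateau (noiseless)
  # bare-chip resonance bounds the whole trace from above
  expect_true(all(tr$f0_ghz < 1.28))
})

test_that("dry plateaus order by concentration with PBS in between", {
  plateau <- function(cfg) {
    tr <- simulate_evaporation_trace(cfg)
    mean(tr$f0_ghz[tr$phase == "dry"])
  }
  p1 <- plateau(evaporation_sim_config(1e6))
  p2 <- plateau(evaporation_sim_config(2e6))
  p_pbs <- plateau(evaporation_sim_config(0))
  expect_gt(p1, p2) # more cells -> lower plateau
  expect_gt(p_pbs, p2)
  expect_lt(p_pbs, p1)
  # the PBS residue permittivity must sit strictly between its neighbours
  expect_error(
    evaporation_sim_config(0, pbs_residue_permittivity = 50),
    "strictly between"
  )
  expect_error(evaporation_sim_config(1e6, eps_solute = 10, eps_wet = 76),
               "inconsistent permittivity")
})

test_that("wet monotonicity and the single jump hold across random configs", {
  set.seed(29)
  for (i in 1:100) {
    cfg <- evaporation_sim_config(
      concentration = runif(1, 0.1e6, 8e6),
      dry_time = runif(1, 120, 900),
      sample_interval = 10,
      eps_wet = runif(1, 40, 80),
      eps_solute = runif(1, 90, 200),
      residue_eps_scale = runif(1, 2, 30),
      kappa = runif(1, 0.005, 0.05),
      volume_decay = sample(c("exponential", "linear"), 1)
    )
    tr <- simulate_evaporation_trace(cfg)
    wet <- tr$f0_ghz[tr$phase == "wet"]
    expect_true(all(diff(wet) <= 1e-12))
    d <- diff(tr$f0_ghz)
    expect_equal(sum(d > 1e-9), 1L) # exactly one upward jump
  }
})

test_that("endpoints extracted from traces feed the calibration unchanged", {
  tr <- simulate_evaporation_trace(evaporation_sim_config(1e6))
  ep <- endpoint_from_traces(tr)
  expect_equal(ep$f_res_ghz, mean(tr$f0_ghz[tr$phase == "dry"]))
  expect_equal(ep$concentration_cells_per_ml, 1e6)
  # truncated trace: no plateau to average
  truncated <- dplyr::filter(tr, time_s < 500)
  expect_error(endpoint_from_traces(truncated), "plateau")
})

test_that("the full trace-to-calibration loop is monotone and tightly linear", {
  traces <- lapply(concentration_ladder(), function(conc) {
    simulate_evaporation_trace(evaporation_sim_config(conc))
  })
  ep <- endpoint_from_traces(traces)
  expect_equal(nrow(ep), 6L)
  expect_true(all(diff(ep$f_res_ghz) < 0))
  fit <- fit_calibration(ep)
  expect_lt(fit$slope, 0)
  expect_gt(fit$r_squared, 0.99)
  # inverting the fitted curve recovers the deposited ladder closely
  est <- invert_concentration(fit, ep$f_res_ghz)
  expect_equal(est$estimate, concentration_ladder(), tolerance = 0.05)
})
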