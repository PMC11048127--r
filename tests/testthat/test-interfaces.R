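test_that("Touchstone round trips preserve the sweep", {
  sw <- synth_s11(vna_grid(), 1.28e9, 80, 0.9)
  p <- withr::local_tempfile(fileext = ".s1p")
  write_touchstone(sw, p, unit = "Hz", format = "RI")
  back <- read_touchstone(p)
  expect_identical(back$frequency_hz, sw$frequency_hz)
  expect_lt(max(Mod(back$s11 - sw$s11)) / max(Mod(sw$s11)), 1e-12)
  expect_equal(attr(back, "z0"), 50)
})

test_that("all three dialects and unit declarations parse consistently", {
  sw <- synth_s11(seq(1e9, 2e9, by = 1e6), 1.5e9, 50, 0.8)
  p_db <- withr::local_tempfile(fileext = ".s1p")
  p_ri <- withr::local_tempfile(fileext = ".s1p")
  p_ma <- withr::local_tempfile(fileext = ".s1p")
  write_touchstone(sw, p_db, unit = "GHz", format = "DB")
  write_touchstone(sw, p_ri, unit = "MHz", format = "RI")
  write_touchstone(sw, p_ma, unit = "kHz", format = "MA")
  a <- read_touchstone(p_db)
  b <- read_touchstone(p_ri)
  c_ <- read_touchstone(p_ma)
  expect_equal(a$frequency_hz, b$frequency_hz, tolerance = 1e-12)
  expect_lt(max(Mod(a$s11 - b$s11)), 1e-9)
  expect_lt(max(Mod(a$s11 - c_$s11)), 1e-9)
})

test_that("malformed Touchstone input is rejected with a clear error", {
  p <- withr::local_tempfile(fileext = ".s1p")
  writeLines(c("! comment only", "# GHZ S RI R 50"), p)
  expect_error(read_touchstone(p), "empty data")
  writeLines(c("# GHZ S RI R 50",
               "1.0 0.1 0.0 0.2 0.0 0.3 0.0 0.4 0.0"), p)
  expect_error(read_touchstone(p), "one-port")
  writeLines(c("# GHZ S RI R 50", "1.0 0.1 0.0", "0.9 0.2 0.0"), p)
  expect_error(read_touchstone(p), "monotone")
})

test_that("measurement tables round trip through the CSV schema", {
  tbl <- simulate_endpoint_dataset(endpoint_sim_config(seed = 5))
  p <- withr::local_tempfile(fileext = ".csv")
  write_measurement_csv(tbl, p)
  expect_equal(readLines(p, n = 1L),
               "concentration_cells_per_mL,f_res_GHz,replicate")
  back <- read_measurement_csv(p)
  expect_equal(back$concentration_cells_per_ml,
               tbl$concentration_cells_per_ml)
  expect_equal(back$f_res_ghz, tbl$f_res_ghz)
})

test_that("permittivity tables round trip through CSV", {
  tbl <- tibble::tibble(frequency_hz = c(1e6, 1e9),
                        eps_real = c(80, 60), eps_imag = c(0.1, 12))
  p <- withr::local_tempfile(fileext = ".csv")
  write_permittivity_csv(tbl, p)
  expect_equal(read_permittivity_csv(p), tbl)
})

test_that("run configs load, validate and round trip idempotently", {
  cfg <- default_run_config()
  p <- withr::local_tempfile(fileext = ".json")
  write_run_config(cfg, p)
  cfg2 <- load_run_config(p)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_run_config(cfg2, p2)
  expect_identical(readLines(p), readLines(p2))
  # overrides merge section-wise
  writeLines('{"sample": {"volume": 2}}', p)
  cfg3 <- load_run_config(p)
  expect_equal(cfg3$sample$volume, 2)
  expect_equal(cfg3$sample$cell_diameter, 15e-6)
  writeLines('{"bogus_section": {}}', p)
  expect_error(load_run_config(p), "unknown config section")
  writeLines('{"simulation": {"eps_solute": 10}}', p)
  expect_error(load_run_config(p), "eps_solute")
})

test_that("the CLI fits, inverts and reports errors via exit status", {
  tbl <- simulate_endpoint_dataset(endpoint_sim_config(noise_sd = 0))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_measurement_csv(tbl, csv)
  out <- withr::local_tempfile(fileext = ".json")
  status <- suppressMessages(
    wbc_cli(c("fit", "--input", csv, "--output", out))
  )
  expect_equal(status, 0L)
  curve <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(curve$sensitivity_hz, 25.06, tolerance = 1e-9)
  # invert through the serialized curve
  inv_out <- withr::local_tempfile(fileext = ".json")
  status <- suppressMessages(
    wbc_cli(c("invert", "--curve", out, "--y", "-1.67981",
              "--output", inv_out))
  )
  expect_equal(status, 0L)
  est <- jsonlite::read_json(inv_out, simplifyVector = TRUE)
  expect_equal(est$estimate, 1e6, tolerance = 1e-6)
  # a zero-slope curve is not invertible
  flat <- withr::local_tempfile(fileext = ".json")
  writeLines('{"slope_GHz_per_cells_mL": 0, "intercept_GHz": -1.6}', flat)
  expect_equal(
    suppressMessages(wbc_cli(c("invert", "--curve", flat, "--y", "-1.7"))),
    1L
  )
  expect_equal(suppressMessages(wbc_cli("frobnicate")), 1L)
  expect_equal(suppressMessages(wbc_cli(character())), 1L)
})

test_that("the CLI design and geometry subcommands print valid JSON", {
  design_txt <- capture.output(suppressMessages(wbc_cli("design")))
  design <- jsonlite::fromJSON(paste(design_txt, collapse = "\n"))
  expect_gt(design$L_total_H, 0)
  expect_gt(design$C_total_F, 0)
  expect_gt(design$f0_GHz, 0)
  geom_txt <- capture.output(suppressMessages(wbc_cli("geometry")))
  geom <- jsonlite::fromJSON(paste(geom_txt, collapse = "\n"))
  expect_equal(geom$monolayer_capacity_3sf, 5660)
  expect_equal(geom$deposited_counts, c(250, 500, 1000, 2000, 4000, 8000))
})

test_that("CLI simulation runs are seed-deterministic", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- suppressMessages(wbc_cli(c("simulate", "--type", "endpoint",
                                   "--seed", "7", "--out", d1)))
  s2 <- suppressMessages(wbc_cli(c("simulate", "--type", "endpoint",
                                   "--seed", "7", "--out", d2)))
  expect_equal(c(s1, s2), c(0L, 0L))
  expect_identical(
    readLines(file.path(d1, "endpoint_measurements.csv")),
    readLines(file.path(d2, "endpoint_measurements.csv"))
  )
})

test_that("CLI trace simulation writes Touchstone files and an index", {
  cfg_path <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0(
    '{"simulation": {"dry_time": 60, "sample_interval": 10,',
    ' "post_dry_time": 40}}'
  ), cfg_path)
  d <- withr::local_tempdir()
  status <- suppressMessages(
    wbc_cli(c("simulate", "--type", "traces", "--config", cfg_path,
              "--concentration", "1e6", "--seed", "4", "--out", d))
  )
  expect_equal(status, 0L)
  index <- readr::read_csv(file.path(d, "trace_index.csv"),
                           show_col_types = FALSE)
  expect_true(all(file.exists(file.path(d, index$file))))
  sw <- read_touchstone(file.path(d, index$file[1]))
  expect_equal(nrow(sw), 10001L)
  # extracted resonances in the index match the model trajectory shape
  expect_gt(index$f0_GHz[nrow(index)], index$f0_GHz[which(index$time_s == 50)])
})
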