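test_that("parameter draws honour the configured populations", {
  # zero-width distributions return the medians exactly
  pop0 <- population_spec(epithelial = list(R2_median = 2000, R2_gsd = 1),
                          endothelial = list(R2_median = 150, R2_gsd = 1),
                          R1_gsd = 1, C1_gsd = 1, C2_gsd = 1)
  p <- draw_params("epithelial", pop0, seed = 1)
  expect_equal(unpack_params(p), c(R1 = 120, C1 = 1e-5, R2 = 2000, C2 = 1e-6))

  # determinism under a fixed seed
  expect_identical(unpack_params(draw_params("endothelial", seed = 7)),
                   unpack_params(draw_params("endothelial", seed = 7)))

  expect_error(draw_params("mesothelial"), "unknown barrier kind")
  expect_error(population_spec(epithelial = list(R2_median = 100, R2_gsd = 1.3)),
               "epithelial R2 median > endothelial")

  # law of large numbers: sample median near configured median
  r2s <- vapply(1:10000, function(s) draw_params("epithelial", seed = s)$R2,
                numeric(1))
  expect_lt(abs(stats::median(r2s) / 2000 - 1), 0.05)
})

test_that("spectrum generation applies polar noise and is reproducible", {
  g <- default_grid()
  p <- epi_params()
  # zero noise: bitwise equal to the forward model
  expect_identical(gen_spectrum(p, g, noise_spec(0, 0, 0))$z,
                   impedance(p, g)$z)
  # same seed, same spectrum
  expect_identical(gen_spectrum(p, g, seed = 3)$z, gen_spectrum(p, g, seed = 3)$z)

  # modulus CV close to the configured 2 percent
  g1 <- frequency_grid(c(10, 20))
  mods <- vapply(1:1000, function(s)
    Mod(gen_spectrum(p, g1, noise_spec(), seed = s)$z[1]), numeric(1))
  cv <- stats::sd(log(mods))
  expect_lt(abs(cv / 0.02 - 1), 0.10)
})

test_that("scenario specs validate their structure", {
  expect_error(scenario_spec("x", list(control = list(apical = c("0h" = 1)))),
               "every timepoint")
  eff <- list(apical = c("0h" = 1, "24h" = 1.2, "48h" = 1.2),
              basal = c("0h" = 1, "24h" = 1, "48h" = 1))
  expect_error(scenario_spec("x", list(control = eff)), "control condition")

  scen <- scenario_template("butyrate")
  expect_equal(scen$n_wells[["butyrate"]], 12L)
  expect_equal(scen$electrodes_per_well, 3L)
  expect_equal(scen$conditions$butyrate$apical[["48h"]], 1.2)
  scen_p <- scenario_template("palmitic")
  expect_equal(scen_p$n_wells[["palmitic"]], 11L)
  expect_equal(scen_p$conditions$palmitic$basal[["48h"]], 0.8)
})

test_that("experiments have the right bookkeeping and deterministic output", {
  scen <- scenario_template("butyrate")
  e <- gen_experiment(scen, seed = 17)
  # 2 conditions x 12 wells x 2 sides x 3 timepoints x 3 electrodes spectra
  expect_length(e$spectra, 2 * 12 * 2 * 3 * 3)
  expect_equal(nrow(e$truth), 2 * 12 * 2 * 3)

  # byte-identical CSVs on regeneration under the master seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_spectra(e$spectra[1:20], f1)
  write_spectra(gen_experiment(scen, seed = 17)$spectra[1:20], f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("condition effects act multiplicatively on the true barrier resistance", {
  # with the well fluctuation disabled the generator identity is exact
  scen <- scenario_template("palmitic")
  scen0 <- scenario_spec(scen$name, scen$conditions, control = scen$control,
                         n_wells = 3L, electrodes_per_well = 1L,
                         timepoints = c("0h", "48h"), well_fluctuation_cv = 0)
  e <- gen_experiment(scen0, seed = 5)
  tr <- e$truth[e$truth$condition == "palmitic" & e$truth$timepoint == "48h", ]
  expect_equal(tr$r2_true, tr$R2_baseline * 0.8, tolerance = 1e-12)
  expect_true(all(tr$effect == 0.8))

  # all effects = 1: treated and control ground truth identical in law
  eff1 <- list(apical = c("0h" = 1, "48h" = 1), basal = c("0h" = 1, "48h" = 1))
  null_scen <- scenario_spec("null", list(control = eff1, treated = eff1),
                             n_wells = 12L, electrodes_per_well = 1L,
                             timepoints = c("0h", "48h"))
  ks_ok <- 0L
  for (s in 1:50) {
    tr <- gen_experiment(null_scen, seed = s, sides = "apical")$truth
    tr <- tr[tr$timepoint == "48h", ]
    p <- suppressWarnings(stats::ks.test(tr$r2_true[tr$condition == "treated"],
                                         tr$r2_true[tr$condition == "control"])$p.value)
    ks_ok <- ks_ok + (p > 0.01)
  }
  expect_gte(ks_ok, 45L)
})

test_that("EGTA timecourses collapse and recover the barrier", {
  p <- epi_params()
  expect_error(gen_egta_timecourse(p, disruption_factor = 0), "disruption_factor")

  # factor 1, zero noise: three identical spectra
  tc1 <- gen_egta_timecourse(p, disruption_factor = 1, recovery_factor = 1,
                             noise = noise_spec(0, 0, 0))
  expect_identical(tc1$baseline$z, tc1$egta_30min$z)
  expect_identical(tc1$baseline$z, tc1$recovered$z)

  # zero noise, factor 0.1: fitted disrupted R2 = 0.1 x baseline to < 0.1%
  tc <- gen_egta_timecourse(p, noise = noise_spec(0, 0, 0))
  r2 <- vapply(tc, function(sp) fit_spectrum(sp)$params$R2, numeric(1))
  expect_lt(abs(r2[["egta_30min"]] / (0.1 * p$R2) - 1), 1e-3)
  expect_lt(abs(r2[["recovered"]] / (0.9 * p$R2) - 1), 1e-3)
})

test_that("synthetic EVOM readings are consistent with their ground truth", {
  rd <- gen_evom_readings(n_wells = 50, seed = 4)
  teer <- suppressWarnings(teer_from_evom(rd$measured_ohm, rd$blank_ohm, rd$area_cm2))
  expect_equal(teer, rd$teer_true, tolerance = 0.05)
})
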