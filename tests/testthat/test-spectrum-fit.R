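test_that("initial guess lands within an order of magnitude on clean spectra", {
  g <- default_grid()
  guess <- initial_guess(impedance(epi_params(), g))
  truth <- unpack_params(epi_params())
  expect_true(all(abs(log10(unpack_params(guess) / truth)) < 1))

  # purely resistive input: R1 ~ R, R2 clipped to its floor
  cfg <- fit_config()
  flat <- impedance_spectrum(g, rep(500 + 0i, length(g)))
  gflat <- initial_guess(flat, cfg)
  expect_equal(gflat$R1, 500, tolerance = 1e-6)
  expect_equal(gflat$R2, cfg$lower[["R2"]])

  expect_error(initial_guess(impedance(epi_params(), frequency_grid(c(1, 2, 3, 4, 5, 6, 7, 8)))),
               "3 decades")
})

test_that("noise-free spectra are recovered essentially exactly", {
  g <- default_grid()
  set.seed(101)
  for (k in 1:50) {
    p <- circuit_params(10^runif(1, 1.5, 2.5), 10^runif(1, -5.5, -4.5),
                        10^runif(1, 1, 4), 10^runif(1, -6.5, -5.5))
    fr <- fit_spectrum(impedance(p, g))
    expect_true(fr$converged)
    expect_lt(max(abs(unpack_params(fr$params) - unpack_params(p)) /
                    unpack_params(p)), 1e-3)
  }
})

test_that("unit and modulus weighting agree at zero noise", {
  sp <- impedance(endo_params())
  f1 <- fit_spectrum(sp, fit_config(weighting = "modulus"))
  f2 <- fit_spectrum(sp, fit_config(weighting = "unit"))
  expect_lt(max(abs(unpack_params(f1$params) / unpack_params(f2$params) - 1)),
            1e-3)
})

test_that("fitting is deterministic given spectrum, config and init", {
  sp <- gen_spectrum(epi_params(), noise = noise_spec(), seed = 5)
  init <- initial_guess(sp)
  f1 <- fit_spectrum(sp, init = init)
  f2 <- fit_spectrum(sp, init = init)
  expect_identical(unpack_params(f1$params), unpack_params(f2$params))
  expect_identical(f1$residual_norm, f2$residual_norm)
  expect_identical(f1$standard_errors, f2$standard_errors)
})

test_that("unresolved barrier plateaus are flagged", {
  g <- default_grid()
  # characteristic frequency below the sweep window
  slow <- circuit_params(120, 1e-5, 1e4, 1e-3)
  expect_lt(characteristic_frequency(slow), 0.1)
  fr <- fit_spectrum(impedance(slow, g))
  expect_true(fr$condition_warning)

  # blank well: fitted R2 near the generator floor, flagged
  blank <- circuit_params(120, 1e-5, 1, 1e-6)
  fb <- fit_spectrum(gen_spectrum(blank, g, noise_spec(), seed = 3))
  expect_lt(fb$params$R2, 50)
  expect_true(fb$condition_warning)
})

test_that("non-finite spectra are rejected as data errors", {
  sp <- impedance(epi_params())
  sp$z[3] <- NA_complex_
  expect_error(fit_spectrum(sp), "non-finite")
})

test_that("well aggregation averages survivors and logs exclusions", {
  g <- default_grid()
  sp <- impedance(epi_params(), g, well = "w1", electrode = "e1",
                  side = "apical", timepoint = "0h")
  base <- fit_spectrum(sp)

  # three identical converged fits
  wf <- aggregate_well(list(base, base, base))
  expect_equal(wf$r2, base$params$R2)
  expect_equal(wf$r2_sem, 0)
  expect_equal(wf$n_used, 3L)

  # two converged + one non-converged
  bad <- base; bad$converged <- FALSE; bad$electrode <- "e3"
  wf2 <- aggregate_well(list(base, base, bad))
  expect_equal(wf2$n_used, 2L)
  expect_equal(nrow(wf2$exclusions), 1L)
  expect_equal(wf2$exclusions$reason, "not converged")

  # four electrodes with distinct R2: aggregate is their mean, SEM textbook
  set.seed(55)
  r2s <- stats::rnorm(4, 1000, 50)
  fits <- lapply(r2s, function(r2)
    fit_spectrum(impedance(circuit_params(120, 1e-5, r2, 1e-6), g)))
  wf3 <- aggregate_well(fits)
  expect_equal(wf3$r2, mean(r2s), tolerance = 1e-6)
  expect_equal(wf3$r2_sem, stats::sd(r2s) / 2, tolerance = 1e-4)

  # residual-norm outliers are excluded
  noisy <- gen_spectrum(epi_params(), g,
                        noise_spec(modulus_sd = 0.3, phase_sd_deg = 10),
                        seed = 9, electrode = "e9")
  fits4 <- list(fit_spectrum(gen_spectrum(epi_params(), g, seed = 1, noise = noise_spec())),
                fit_spectrum(gen_spectrum(epi_params(), g, seed = 2, noise = noise_spec())),
                fit_spectrum(gen_spectrum(epi_params(), g, seed = 4, noise = noise_spec())),
                fit_spectrum(noisy))
  wf4 <- aggregate_well(fits4)
  expect_equal(wf4$n_used, 3L)
  expect_true("residual norm outlier" %in% wf4$exclusions$reason)

  # empty survivor set: missing aggregate, never fabricated
  allbad <- base; allbad$converged <- FALSE
  wf5 <- aggregate_well(list(allbad))
  expect_true(is.na(wf5$r2))
  expect_error(classify_barrier(wf5), "refused")
})

test_that("barrier classification separates the two populations", {
  thr <- default_r2_threshold()
  expect_equal(thr, sqrt(2000 * 150))

  g <- default_grid()
  sp <- impedance(epi_params(), g)
  wf <- aggregate_well(list(fit_spectrum(sp)))
  # boundary inclusive
  wf$r2 <- thr
  expect_equal(classify_barrier(wf), "epithelial-like")

  classify_or_na <- function(fit)
    tryCatch(classify_barrier(aggregate_well(list(fit))),
             error = function(e) NA_character_)
  n_ok_epi <- n_ok_endo <- 0L
  for (s in 1:100) {
    pe <- draw_params("epithelial", seed = s)
    fe <- fit_spectrum(gen_spectrum(pe, g, noise_spec(), seed = s + 10000))
    n_ok_epi <- n_ok_epi +
      isTRUE(classify_or_na(fe) == "epithelial-like")
    pn <- draw_params("endothelial", seed = s + 20000)
    fn <- fit_spectrum(gen_spectrum(pn, g, noise_spec(), seed = s + 30000))
    n_ok_endo <- n_ok_endo +
      isTRUE(classify_or_na(fn) == "endothelial-like")
  }
  expect_gte(n_ok_epi, 99L)
  expect_gte(n_ok_endo, 99L)
})
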