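# Seed plumbing: a single master seed fans out to per-(condition, well, side,
# timepoint, electrode) child seeds through this documented splitting rule, so
# any subset of a generated experiment is reproducible in isolation. All
# arithmetic stays below 2^53 (exact in doubles); results are mapped into
# [1, 2^31 - 2] for set.seed().
.child_seed <- function(master, ...) {
  x <- as.double(master) %% 2147483647
  for (idx in c(...)) x <- (x * 69069 + as.double(idx) * 30103 + 1) %% 2147483647
  as.integer(x) + 1L
}

# evaluate expr under a temporary RNG state seeded with `seed` (NULL = use the
# current RNG stream untouched)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

# log-normal draw parameterized by median and geometric SD (gsd = 1 is exact)
.rlnorm_med <- function(n, median, gsd) median * exp(stats::rnorm(n) * log(gsd))

#' Synthetic barrier-parameter populations
#'
#' Per-barrier-kind log-normal populations for the four circuit elements. The
#' numeric defaults are invented generator values (the source measurements are
#' wet-lab data); they are chosen so that epithelial and endothelial wells
#' produce Bode spectra with clearly separated resistive plateaus: a
#' high-resistance epithelial barrier (R2 median 2000 ohm), a low-resistance
#' endothelial barrier (median 150 ohm), and a blank floor of 1 ohm.
#'
#' @param epithelial,endothelial lists with \code{R2_median} (ohm) and
#'   \code{R2_gsd} (geometric SD, dimensionless).
#' @param blank list with the blank (no-barrier) \code{R2_floor} in ohm.
#' @param R1_median,R1_gsd series-resistance population (ohm).
#' @param C1_median,C1_gsd series interfacial capacitance population (F).
#' @param C2_median,C2_gsd barrier capacitance population (F).
#' @return an object of class \code{population_spec}.
#' @export
population_spec <- function(epithelial = list(R2_median = 2000, R2_gsd = 1.3),
                            endothelial = list(R2_median = 150, R2_gsd = 1.3),
                            blank = list(R2_floor = 1),
                            R1_median = 120, R1_gsd = 1.2,
                            C1_median = 1e-5, C1_gsd = 1.2,
                            C2_median = 1e-6, C2_gsd = 1.2) {
  if (!(epithelial$R2_median > endothelial$R2_median &&
        endothelial$R2_median > blank$R2_floor))
    stop("population must satisfy epithelial R2 median > endothelial R2 median > blank floor",
         call. = FALSE)
  structure(list(epithelial = epithelial, endothelial = endothelial,
                 blank = blank,
                 R1_median = R1_median, R1_gsd = R1_gsd,
                 C1_median = C1_median, C1_gsd = C1_gsd,
                 C2_median = C2_median, C2_gsd = C2_gsd),
            class = "population_spec")
}

#' Synthetic measurement-noise model
#'
#' The instrument noise model is an assumption (no noise figures are reported
#' for the measurement campaign): multiplicative log-normal noise on the
#' modulus and additive Gaussian noise on the phase, i.e. noise in polar
#' coordinates so that the error scales with |Z| across decades, plus a
#' per-electrode placement offset on the barrier resistance.
#'
#' @param modulus_sd log-scale SD of the multiplicative modulus noise
#'   (default 0.02, i.e. about 2 percent).
#' @param phase_sd_deg SD of the additive phase noise in degrees (default 1).
#' @param electrode_cv coefficient of variation of the per-electrode R2
#'   placement offset (default 0.05).
#' @return an object of class \code{noise_spec}.
#' @export
noise_spec <- function(modulus_sd = 0.02, phase_sd_deg = 1, electrode_cv = 0.05) {
  if (modulus_sd < 0 || phase_sd_deg < 0 || electrode_cv < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  structure(list(modulus_sd = modulus_sd, phase_sd_deg = phase_sd_deg,
                 electrode_cv = electrode_cv), class = "noise_spec")
}

#' Draw one set of circuit parameters from a population
#'
#' @param kind \code{"epithelial"}, \code{"endothelial"} or \code{"blank"}.
#' @param population a [population_spec()].
#' @param seed optional integer seed (the draw is reproducible given the seed
#'   and leaves the caller's RNG stream untouched).
#' @return a [circuit_params()].
#' @export
draw_params <- function(kind, population = population_spec(), seed = NULL) {
  if (!kind %in% c("epithelial", "endothelial", "blank"))
    stop(sprintf("unknown barrier kind '%s'", kind), call. = FALSE)
  .with_seed(seed, {
    R1 <- .rlnorm_med(1, population$R1_median, population$R1_gsd)
    C1 <- .rlnorm_med(1, population$C1_median, population$C1_gsd)
    if (kind == "blank") {
      R2 <- population$blank$R2_floor
      C2 <- population$C2_median
    } else {
      pk <- population[[kind]]
      R2 <- .rlnorm_med(1, pk$R2_median, pk$R2_gsd)
      C2 <- .rlnorm_med(1, population$C2_median, population$C2_gsd)
    }
    circuit_params(R1 = R1, C1 = C1, R2 = R2, C2 = C2)
  })
}

#' Generate one noisy spectrum from known circuit parameters
#'
#' Noise is applied in polar form: \eqn{|Z| \cdot e^{N(0,\sigma_m)}} on the
#' modulus and \eqn{+N(0,\sigma_\varphi)} on the phase. With both noise terms
#' zero the exact forward model is returned unchanged.
#'
#' @param params a [circuit_params()].
#' @param grid a [frequency_grid()].
#' @param noise a [noise_spec()].
#' @param seed optional integer seed.
#' @param ... metadata passed to [impedance_spectrum()].
#' @return an [impedance_spectrum()].
#' @export
gen_spectrum <- function(params, grid = default_grid(), noise = noise_spec(),
                         seed = NULL, ...) {
  clean <- impedance(params, grid, ...)
  if (noise$modulus_sd == 0 && noise$phase_sd_deg == 0) return(clean)
  .with_seed(seed, {
    n <- length(clean$frequency_hz)
    m <- Mod(clean$z) * exp(stats::rnorm(n, 0, noise$modulus_sd))
    ph <- Arg(clean$z) + stats::rnorm(n, 0, noise$phase_sd_deg * pi / 180)
    impedance_spectrum(frequency_grid(clean$frequency_hz,
                                      window = range(clean$frequency_hz)),
                       complex(modulus = m, argument = ph), ...)
  })
}

#' Treatment-scenario specification
#'
#' Describes one simulated treatment experiment: conditions with per-side,
#' per-timepoint multiplicative effects on the true barrier resistance, wells
#' per condition, electrode replicates per well, and a per-measurement-occasion
#' biological/placement fluctuation of the well-level R2.
#'
#' @param name scenario label.
#' @param conditions named list; each condition is a list with elements
#'   \code{apical} and \code{basal}, each a named numeric vector of
#'   multiplicative R2 effects per timepoint (all > 0). The control condition
#'   must have all effects equal to 1.
#' @param control name of the control condition.
#' @param n_wells wells per condition (single value or named per condition).
#' @param electrodes_per_well working-electrode replicates (default 3).
#' @param timepoints character vector of timepoint labels; the first is the
#'   baseline.
#' @param well_fluctuation_cv CV of the log-normal well-level R2 fluctuation
#'   applied independently at every measurement occasion (default 0.06).
#' @return an object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(name, conditions, control = names(conditions)[1],
                          n_wells = 12L, electrodes_per_well = 3L,
                          timepoints = c("0h", "24h", "48h"),
                          well_fluctuation_cv = 0.06) {
  stopifnot(is.list(conditions), length(conditions) >= 1L,
            control %in% names(conditions))
  if (is.null(names(n_wells)))
    n_wells <- stats::setNames(rep(as.integer(n_wells), length(conditions)),
                               names(conditions))
  for (cn in names(conditions)) {
    for (sd_ in c("apical", "basal")) {
      eff <- conditions[[cn]][[sd_]]
      if (is.null(eff) || !all(timepoints %in% names(eff)))
        stop(sprintf("condition '%s' lacks %s effects for every timepoint", cn, sd_),
             call. = FALSE)
      if (any(eff <= 0)) stop("effects must be > 0", call. = FALSE)
      if (cn == control && any(eff[timepoints] != 1))
        stop("control condition must have all effects = 1", call. = FALSE)
    }
  }
  structure(list(name = name, conditions = conditions, control = control,
                 n_wells = n_wells,
                 electrodes_per_well = as.integer(electrodes_per_well),
                 timepoints = timepoints,
                 well_fluctuation_cv = well_fluctuation_cv),
            class = "scenario_spec")
}

#' Built-in treatment-scenario templates
#'
#' Templates emulating the study designs of the treatment experiments:
#' \describe{
#'   \item{butyrate}{2 conditions, n = 12 wells each, 0/24/48 h. Apical
#'     (epithelial) barrier resistance raised by 15 percent at 24 h and
#'     20 percent at 48 h; a small non-significant upward basal trend
#'     (1/1.5 percent).}
#'   \item{palmitic}{2 conditions, n = 11 wells, 0/24/48 h. Both barriers
#'     reduced to 80 percent of baseline at 48 h (90 percent at 24 h).}
#'   \item{supernatant}{6 conditions (growth-medium control n = 12, four
#'     single-organism supernatants and a synthetic community, n = 9), with the
#'     community raising the apical barrier by 20 percent at 48 h.}
#' }
#' Effect sizes are generator choices consistent with the qualitative response
#' patterns of the emulated experiments.
#'
#' @param name one of \code{"butyrate"}, \code{"palmitic"},
#'   \code{"supernatant"}.
#' @return a [scenario_spec()].
#' @export
scenario_template <- function(name = c("butyrate", "palmitic", "supernatant")) {
  name <- match.arg(name)
  tp <- c("0h", "24h", "48h")
  eff <- function(t24a, t48a, t24b, t48b)
    list(apical = c("0h" = 1, "24h" = t24a, "48h" = t48a),
         basal = c("0h" = 1, "24h" = t24b, "48h" = t48b))
  ctrl <- eff(1, 1, 1, 1)
  switch(name,
    butyrate = scenario_spec("butyrate",
      conditions = list(control = ctrl,
                        butyrate = eff(1.15, 1.20, 1.01, 1.015)),
      n_wells = 12L, timepoints = tp),
    palmitic = scenario_spec("palmitic",
      conditions = list(control = ctrl,
                        palmitic = eff(0.95, 0.80, 0.95, 0.80)),
      n_wells = 11L, timepoints = tp),
    supernatant = scenario_spec("supernatant",
      conditions = list(mGam = ctrl,
                        s_copri = eff(1.0, 1.03, 1, 1),
                        r_intestinalis = eff(1.0, 1.05, 1, 1),
                        p_merdae = eff(1.0, 1.04, 1, 1),
                        b_caccae = eff(1.0, 1.02, 1, 1),
                        community = eff(1.1, 1.20, 1, 1)),
      n_wells = c(mGam = 12L, s_copri = 9L, r_intestinalis = 9L,
                  p_merdae = 9L, b_caccae = 9L, community = 9L),
      control = "mGam", timepoints = tp))
}

#' Generate a full synthetic treatment experiment
#'
#' Per well and side, a baseline [circuit_params()] is drawn from the
#' population (apical wells are epithelial, basal endothelial by default); per
#' timepoint the true well R2 is the baseline scaled by the condition effect
#' and a log-normal well fluctuation; per electrode an additional placement
#' offset is applied before the noisy spectrum is generated.
#'
#' @param scenario a [scenario_spec()].
#' @param population a [population_spec()].
#' @param noise a [noise_spec()].
#' @param seed master integer seed (fans out to reproducible child seeds).
#' @param grid a [frequency_grid()].
#' @param sides which sides to simulate (default apical and basal).
#' @return a list with \code{spectra} (list of [impedance_spectrum()]) and
#'   \code{truth} (data.frame of condition, well, side, timepoint, true well
#'   R2, applied effect, and baseline parameters).
#' @export
gen_experiment <- function(scenario, population = population_spec(),
                           noise = noise_spec(), seed = 1L,
                           grid = default_grid(),
                           sides = c("apical", "basal")) {
  stopifnot(inherits(scenario, "scenario_spec"))
  kind_by_side <- c(apical = "epithelial", basal = "endothelial")
  sdlog_well <- sqrt(log(1 + scenario$well_fluctuation_cv^2))
  sdlog_elec <- sqrt(log(1 + noise$electrode_cv^2))

  spectra <- list()
  truth <- list()
  cond_names <- names(scenario$conditions)
  for (ci in seq_along(cond_names)) {
    cn <- cond_names[ci]
    for (wi in seq_len(scenario$n_wells[[cn]])) {
      well_id <- sprintf("%s_w%02d", cn, wi)
      for (si in seq_along(sides)) {
        side <- sides[si]
        base <- draw_params(kind_by_side[[side]], population,
                            seed = .child_seed(seed, ci, wi, si))
        for (ti in seq_along(scenario$timepoints)) {
          tp <- scenario$timepoints[ti]
          effect <- scenario$conditions[[cn]][[side]][[tp]]
          fluct <- .with_seed(.child_seed(seed, ci, wi, si, ti),
                              exp(stats::rnorm(1, 0, sdlog_well)))
          r2_well <- base$R2 * effect * fluct
          for (ei in seq_len(scenario$electrodes_per_well)) {
            es <- .child_seed(seed, ci, wi, si, ti, ei)
            r2_elec <- .with_seed(es, r2_well * exp(stats::rnorm(1, 0, sdlog_elec)))
            p_e <- circuit_params(base$R1, base$C1, r2_elec, base$C2)
            sp <- gen_spectrum(p_e, grid, noise, seed = es + 1L,
                               well = well_id, electrode = sprintf("e%d", ei),
                               side = side, timepoint = tp)
            spectra[[length(spectra) + 1L]] <- sp
          }
          truth[[length(truth) + 1L]] <- data.frame(
            condition = cn, well = well_id, side = side, timepoint = tp,
            r2_true = r2_well, effect = effect,
            R1 = base$R1, C1 = base$C1, R2_baseline = base$R2, C2 = base$C2,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(spectra = spectra, truth = do.call(rbind, truth), scenario = scenario)
}

#' Generate a calcium-switch (EGTA) disruption/recovery timecourse
#'
#' Emulates transient tight-junction disruption by calcium chelation: a
#' baseline measurement, a measurement after 30 min of EGTA exposure with the
#' barrier resistance collapsed to \code{disruption_factor} times baseline, and
#' a post-washout measurement recovered to \code{recovery_factor} times
#' baseline.
#'
#' @param params baseline [circuit_params()].
#' @param disruption_factor multiplicative R2 drop during exposure, in (0, 1]
#'   (default 0.1).
#' @param recovery_factor R2 level after overnight recovery relative to
#'   baseline (default 0.9).
#' @param noise a [noise_spec()].
#' @param seed optional integer seed.
#' @param grid a [frequency_grid()].
#' @param well well label for the emitted spectra.
#' @return list of three labelled [impedance_spectrum()] objects (timepoints
#'   \code{baseline}, \code{egta_30min}, \code{recovered}) with a
#'   \code{truth} attribute carrying the true R2 sequence.
#' @export
gen_egta_timecourse <- function(params, disruption_factor = 0.1,
                                recovery_factor = 0.9, noise = noise_spec(),
                                seed = NULL, grid = default_grid(),
                                well = "w01") {
  stopifnot(inherits(params, "circuit_params"))
  if (disruption_factor <= 0 || disruption_factor > 1)
    stop("disruption_factor must be in (0, 1]", call. = FALSE)
  labels <- c("baseline", "egta_30min", "recovered")
  factors <- c(1, disruption_factor, recovery_factor)
  out <- vector("list", 3L)
  for (k in 1:3) {
    pk <- circuit_params(params$R1, params$C1, params$R2 * factors[k], params$C2)
    out[[k]] <- gen_spectrum(pk, grid, noise,
                             seed = if (is.null(seed)) NULL else .child_seed(seed, k),
                             well = well, electrode = "e1", side = "apical",
                             timepoint = labels[k])
  }
  names(out) <- labels
  attr(out, "truth") <- data.frame(timepoint = labels,
                                   r2_true = params$R2 * factors)
  out
}

#' Generate synthetic EVOM chopstick-electrode readings
#'
#' Bulk resistance readings across the whole insert (both barriers in series),
#' with a shared blank value, for exercising the TEER conversion.
#'
#' @param n_wells number of wells.
#' @param teer_median median true TEER in ohm cm^2.
#' @param teer_gsd geometric SD of the across-well TEER distribution.
#' @param blank_ohm blank (cell-free insert) resistance, ohm.
#' @param area_cm2 insert growth area (default 0.33 cm^2).
#' @param reading_sd_ohm additive Gaussian instrument noise on the reading, ohm.
#' @param seed optional integer seed.
#' @param timepoint timepoint label.
#' @return data.frame with columns \code{well}, \code{timepoint},
#'   \code{measured_ohm}, \code{blank_ohm}, \code{area_cm2}, \code{teer_true}.
#' @export
gen_evom_readings <- function(n_wells = 12L, teer_median = 100, teer_gsd = 1.2,
                              blank_ohm = 120, area_cm2 = 0.33,
                              reading_sd_ohm = 2, seed = NULL,
                              timepoint = "0h") {
  .with_seed(seed, {
    teer <- .rlnorm_med(n_wells, teer_median, teer_gsd)
    measured <- blank_ohm + teer / area_cm2 +
      stats::rnorm(n_wells, 0, reading_sd_ohm)
    data.frame(well = sprintf("w%02d", seq_len(n_wells)), timepoint = timepoint,
               measured_ohm = measured, blank_ohm = blank_ohm,
               area_cm2 = area_cm2, teer_true = teer, stringsAsFactors = FALSE)
  })
}
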