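#' Configuration for complex nonlinear least-squares fitting
#'
#' @param weighting residual weighting: \code{"modulus"} (default,
#'   \eqn{w_f = 1/|Z_f|^2}, standard for spectra spanning orders of magnitude),
#'   \code{"unit"} (unweighted), or \code{"proportional"} (weights from the
#'   model modulus, re-evaluated at each iterate).
#' @param max_iterations Levenberg-Marquardt iteration cap.
#' @param tol convergence tolerance on the relative parameter change.
#' @param lower,upper named parameter bounds (ohm / F), strictly positive.
#' @param log_transform fit in log-parameter space (default TRUE; parameters
#'   span decades and the transform enforces positivity).
#' @param aggregate well-level central statistic, \code{"mean"} (default) or
#'   \code{"median"}.
#' @param residual_multiple electrodes whose residual norm exceeds this multiple
#'   of the within-well median are excluded from the aggregate.
#' @return an object of class \code{fit_config}.
#' @export
fit_config <- function(weighting = c("modulus", "unit", "proportional"),
                       max_iterations = 200L, tol = 1e-12,
                       lower = c(R1 = 1e-3, C1 = 1e-12, R2 = 1e-2, C2 = 1e-12),
                       upper = c(R1 = 1e9, C1 = 1, R2 = 1e9, C2 = 1),
                       log_transform = TRUE,
                       aggregate = c("mean", "median"),
                       residual_multiple = 5) {
  weighting <- match.arg(weighting)
  aggregate <- match.arg(aggregate)
  nm <- c("R1", "C1", "R2", "C2")
  lower <- lower[nm]; upper <- upper[nm]
  if (any(!is.finite(lower)) || any(lower <= 0))
    stop("lower bounds must be positive and finite", call. = FALSE)
  if (any(upper <= lower)) stop("upper bounds must exceed lower bounds", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  structure(list(weighting = weighting, max_iterations = as.integer(max_iterations),
                 tol = tol, lower = lower, upper = upper,
                 log_transform = isTRUE(log_transform), aggregate = aggregate,
                 residual_multiple = residual_multiple),
            class = "fit_config")
}

# complex model and its parameter Jacobian at angular frequencies w
.z_model <- function(p, w) {
  p["R1"] + 1 / (1i * w * p["C1"]) + p["R2"] / (1 + 1i * w * p["R2"] * p["C2"])
}

.z_jacobian <- function(p, w) {
  D <- 1 + 1i * w * p["R2"] * p["C2"]
  cbind(R1 = rep(1 + 0i, length(w)),
        C1 = 1i / (w * p["C1"]^2),
        R2 = 1 / D^2,
        C2 = -1i * w * p["R2"]^2 / D^2)
}

#' Heuristic initial parameter guess from a spectrum
#'
#' Reads approximate circuit parameters directly off the spectrum shape:
#' R1 from the high-frequency modulus plateau, R2 from the low-frequency real
#' part minus R1, C2 from the frequency of maximal reactive part of the barrier
#' branch (after removing the series-capacitor contribution), and C1 from the
#' low-frequency \eqn{-\mathrm{Im}\,Z \approx 1/(\omega C_1)} asymptote.
#' Outputs are clipped to the configured bounds.
#'
#' @param spectrum an [impedance_spectrum()] with at least 8 frequencies
#'   spanning at least 3 decades.
#' @param config a [fit_config()].
#' @return a [circuit_params()], with attribute \code{condition_warning} set
#'   when the barrier characteristic frequency falls at the edge of (or outside)
#'   the sweep window.
#' @export
initial_guess <- function(spectrum, config = fit_config()) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequency_hz
  z <- spectrum$z
  if (length(f) < 8L || log10(max(f) / min(f)) < 3)
    stop("initial_guess needs >= 8 frequencies spanning >= 3 decades", call. = FALSE)
  w <- 2 * pi * f
  clip <- function(v, nm) min(max(v, config$lower[[nm]]), config$upper[[nm]])

  top <- f >= max(f) / 10^0.5                     # top half-decade
  R1 <- clip(stats::median(Mod(z[top])), "R1")

  R2 <- clip(Re(z[1]) - R1, "R2")

  # series-capacitor estimate from the lowest frequency, then locate the
  # reactive peak of the barrier branch
  C1 <- clip(1 / (w[1] * max(-Im(z[1]), .Machine$double.eps)), "C1")
  im_barrier <- -Im(z) - 1 / (w * C1)
  istar <- which.max(im_barrier)
  fstar <- f[istar]
  C2 <- clip(1 / (2 * pi * fstar * R2), "C2")

  guess <- circuit_params(R1 = R1, C1 = C1, R2 = R2, C2 = C2)
  attr(guess, "condition_warning") <-
    istar <= 1L || istar >= length(f) ||
    characteristic_frequency(guess) < min(f) ||
    characteristic_frequency(guess) > max(f)
  guess
}

#' Fit the four-element circuit to an impedance spectrum
#'
#' Complex nonlinear least squares: minimizes
#' \deqn{\sum_f w_f \left[(\mathrm{Re}\,\hat Z_f - \mathrm{Re}\,Z_f)^2 +
#'   (\mathrm{Im}\,\hat Z_f - \mathrm{Im}\,Z_f)^2\right]}
#' over (R1, C1, R2, C2) by Levenberg-Marquardt with an analytic Jacobian,
#' by default in log-parameter space with \eqn{w_f = 1/|Z_f|^2}. Non-convergence
#' is a recorded outcome (\code{converged = FALSE} with the last iterate), never
#' an exception, so experiment pipelines can proceed with exclusion logging.
#'
#' @param spectrum an [impedance_spectrum()].
#' @param config a [fit_config()].
#' @param init optional [circuit_params()] starting point; defaults to
#'   [initial_guess()].
#' @return an object of class \code{fit_result}: \code{params}
#'   ([circuit_params()]), \code{standard_errors} (same units, from the
#'   covariance of the weighted problem), \code{residual_norm} (weighted sum of
#'   squares), \code{converged}, \code{n_frequencies},
#'   \code{condition_warning} (barrier plateau not resolved inside the sweep
#'   window), and the spectrum metadata.
#' @export
fit_spectrum <- function(spectrum, config = fit_config(), init = NULL) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  if (any(!is.finite(Re(spectrum$z))) || any(!is.finite(Im(spectrum$z))))
    stop("spectrum contains non-finite impedance values", call. = FALSE)
  auto_init <- is.null(init)
  if (auto_init) init <- initial_guess(spectrum, config)
  stopifnot(inherits(init, "circuit_params"))
  out <- .fit_spectrum_once(spectrum, config, init)
  if (auto_init && .looks_degenerate(out, config)) {
    # the heuristic start occasionally lands in a basin where the barrier
    # branch collapses onto its bounds; retry from a mid-sweep time constant
    # and keep whichever fit has the smaller weighted residual
    f <- spectrum$frequency_hz
    fgeo <- sqrt(min(f) * max(f))
    r2_alt <- max(Re(spectrum$z[1]) - init$R1, config$lower[["R2"]] * 10)
    alt <- circuit_params(init$R1, init$C1, r2_alt,
                          min(max(1 / (2 * pi * fgeo * r2_alt),
                                  config$lower[["C2"]]), config$upper[["C2"]]))
    out2 <- .fit_spectrum_once(spectrum, config, alt)
    if (out2$residual_norm < out$residual_norm) out <- out2
  }
  out
}

.looks_degenerate <- function(res, config) {
  p <- res$params
  # collapsed onto a bound, or time constant pushed outside the sweep: the
  # parallel branch has degenerated into a pure resistor/capacitor
  fstar <- characteristic_frequency(p)
  p$R2 <= config$lower[["R2"]] * 2 || p$R2 >= config$upper[["R2"]] / 2 ||
    p$C2 <= config$lower[["C2"]] * 2 || p$C2 >= config$upper[["C2"]] / 2 ||
    fstar < res$f_range[1] || fstar > res$f_range[2]
}

.fit_spectrum_once <- function(spectrum, config, init) {

  f <- spectrum$frequency_hz
  w <- 2 * pi * f
  z <- spectrum$z
  n <- length(f)
  sw_data <- switch(config$weighting,
                    modulus = 1 / Mod(z),
                    unit = rep(1, n),
                    proportional = NULL)  # computed from the model per iterate
  nm <- c("R1", "C1", "R2", "C2")
  p0 <- pmin(pmax(unlist(init[nm]), config$lower), config$upper)

  to_theta   <- if (config$log_transform) log else identity
  from_theta <- if (config$log_transform) exp else identity

  resid_fn <- function(theta) {
    p <- from_theta(theta); names(p) <- nm
    zm <- .z_model(p, w)
    sw <- if (is.null(sw_data)) 1 / pmax(Mod(zm), .Machine$double.xmin) else sw_data
    c(sw * (Re(zm) - Re(z)), sw * (Im(zm) - Im(z)))
  }
  jac_fn <- function(theta) {
    p <- from_theta(theta); names(p) <- nm
    J <- .z_jacobian(p, w)
    if (config$log_transform) J <- sweep(J, 2, p, "*")
    zm <- .z_model(p, w)
    sw <- if (is.null(sw_data)) 1 / pmax(Mod(zm), .Machine$double.xmin) else sw_data
    rbind(sw * Re(J), sw * Im(J))
  }

  # non-convergence is recorded in the result, so the optimizer's own
  # iteration-cap warning is redundant noise
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = to_theta(p0), fn = resid_fn, jac = jac_fn,
    lower = to_theta(config$lower), upper = to_theta(config$upper),
    control = minpack.lm::nls.lm.control(
      maxiter = config$max_iterations, ptol = config$tol,
      ftol = config$tol, gtol = 0, maxfev = 100L * config$max_iterations)))

  p_hat <- from_theta(fit$par); names(p_hat) <- nm
  params <- circuit_params(p_hat["R1"], p_hat["C1"], p_hat["R2"], p_hat["C2"])
  converged <- fit$info %in% c(1L, 2L, 3L, 4L)

  # covariance-derived standard errors (delta method back from log space)
  se <- rep(NA_real_, 4); names(se) <- nm
  dof <- 2L * n - 4L
  if (dof > 0) {
    J <- jac_fn(fit$par)
    sigma2 <- fit$deviance / dof
    cv <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(cv)) {
      se_theta <- sqrt(pmax(diag(cv), 0))
      se <- if (config$log_transform) p_hat * se_theta else se_theta
      names(se) <- nm
    }
  }

  fstar <- characteristic_frequency(params)
  cond_warn <- fstar < min(f) || fstar > max(f) ||
    p_hat["R2"] <= config$lower[["R2"]] * (1 + 1e-6) ||
    p_hat["R2"] < 0.05 * p_hat["R1"] ||   # barrier step lost under the series R
    !is.null(attr(init, "condition_warning")) && isTRUE(attr(init, "condition_warning"))

  structure(list(params = params, standard_errors = se,
                 residual_norm = fit$deviance, converged = converged,
                 n_frequencies = n, condition_warning = isTRUE(cond_warn),
                 f_range = range(f),
                 n_iterations = fit$niter, optimizer_info = fit$info,
                 well = spectrum$well, electrode = spectrum$electrode,
                 side = spectrum$side, timepoint = spectrum$timepoint),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("circuit fit (%s): R2 = %.4g +/- %.3g ohm%s\n",
              if (x$converged) "converged" else "NOT converged",
              x$params$R2, x$standard_errors[["R2"]],
              if (x$condition_warning) " [condition warning]" else ""))
  cat(sprintf("  R1 = %.4g, C1 = %.4g, C2 = %.4g; weighted SSR = %.3g over %d frequencies\n",
              x$params$R1, x$params$C1, x$params$C2, x$residual_norm,
              x$n_frequencies))
  invisible(x)
}

#' Aggregate electrode-replicate fits into a well-level barrier resistance
#'
#' Excludes non-converged fits and fits whose residual norm exceeds a
#' configurable multiple (default 5x) of the within-well median; the aggregate
#' R2 is the mean (or median) of the survivors with the SEM as dispersion. An
#' empty survivor set yields a flagged missing aggregate, never a fabricated
#' value.
#'
#' @param results list of [fit_spectrum()] results from one well/side/timepoint.
#' @param config a [fit_config()] (supplies the aggregate statistic and the
#'   residual-multiple exclusion rule).
#' @return an object of class \code{well_fit} with fields \code{r2}
#'   (aggregate, ohm; NA when missing), \code{r2_sem}, \code{n_used},
#'   \code{exclusions} (data.frame of electrode, reason) and the metadata of the
#'   first result.
#' @export
aggregate_well <- function(results, config = fit_config()) {
  if (inherits(results, "fit_result")) results <- list(results)
  if (length(results) == 0L) stop("aggregate_well needs >= 1 fit result", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "fit_result")))

  elec <- vapply(results, function(r) r$electrode, character(1))
  conv <- vapply(results, function(r) isTRUE(r$converged), logical(1))
  rn <- vapply(results, function(r) r$residual_norm, numeric(1))

  excl <- data.frame(electrode = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  keep <- conv
  if (any(!conv))
    excl <- rbind(excl, data.frame(electrode = elec[!conv],
                                   reason = "not converged"))
  if (any(keep)) {
    med <- stats::median(rn[keep])
    bad <- keep & rn > config$residual_multiple * med & med > 0
    if (any(bad)) {
      excl <- rbind(excl, data.frame(electrode = elec[bad],
                                     reason = "residual norm outlier"))
      keep <- keep & !bad
    }
  }

  r2s <- vapply(results[keep], function(r) r$params$R2, numeric(1))
  if (length(r2s) == 0L) {
    r2 <- NA_real_; sem <- NA_real_
    excl <- rbind(excl, data.frame(electrode = NA_character_,
                                   reason = "no surviving electrodes"))
  } else {
    r2 <- if (config$aggregate == "mean") mean(r2s) else stats::median(r2s)
    sem <- if (length(r2s) > 1L) stats::sd(r2s) / sqrt(length(r2s)) else NA_real_
  }

  structure(list(well = results[[1]]$well, side = results[[1]]$side,
                 timepoint = results[[1]]$timepoint,
                 r2 = r2, r2_sem = sem,
                 n_total = length(results), n_used = sum(keep),
                 condition_warning = any(vapply(results[keep],
                                                function(r) r$condition_warning,
                                                logical(1))),
                 results = results, exclusions = excl),
            class = "well_fit")
}

#' @export
print.well_fit <- function(x, ...) {
  cat(sprintf("well %s (%s, %s): R2 = %s ohm (SEM %s), %d/%d electrodes used\n",
              x$well, x$side, x$timepoint,
              if (is.na(x$r2)) "missing" else sprintf("%.4g", x$r2),
              if (is.na(x$r2_sem)) "NA" else sprintf("%.3g", x$r2_sem),
              x$n_used, x$n_total))
  invisible(x)
}

#' Classify a well as epithelial-like or endothelial-like
#'
#' Epithelial barriers (e.g. Caco2/HT29-MTX co-cultures) have a substantially
#' higher barrier resistance than endothelial (HUVEC-like) monolayers. The
#' default threshold is the geometric midpoint between the synthetic
#' population's epithelial and endothelial R2 medians; the boundary itself is
#' classified epithelial-like.
#'
#' @param wellfit a [aggregate_well()] result with a non-missing aggregate.
#' @param threshold decision threshold in ohm.
#' @return \code{"epithelial-like"} or \code{"endothelial-like"}.
#' @export
classify_barrier <- function(wellfit, threshold = default_r2_threshold()) {
  stopifnot(inherits(wellfit, "well_fit"))
  if (is.na(wellfit$r2))
    stop("classification refused: well aggregate is missing", call. = FALSE)
  if (wellfit$r2 >= threshold) "epithelial-like" else "endothelial-like"
}

#' Default epithelial/endothelial decision threshold
#'
#' Geometric midpoint between the configured epithelial and endothelial R2
#' population medians.
#'
#' @param population a [population_spec()].
#' @return threshold in ohm.
#' @export
default_r2_threshold <- function(population = population_spec()) {
  sqrt(population$epithelial$R2_median * population$endothelial$R2_median)
}
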