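.known_config_keys <- c("stages", "seed", "scenario", "grid_fmin_hz",
                        "grid_fmax_hz", "grid_n", "fit", "noise", "design",
                        "fem_refine", "verbose")

#' Validate and resolve a pipeline run configuration
#'
#' Strict parsing: unknown keys are rejected so that typos (e.g. a mis-suffixed
#' unit) fail loudly instead of silently using a default.
#'
#' @param config named list; recognized keys: \code{stages} (character vector,
#'   subset of synth/fem/fit/stats), \code{seed} (master seed),
#'   \code{scenario} (a [scenario_template()] name for synth, or a
#'   [build_device()] scenario for fem), \code{grid_fmin_hz},
#'   \code{grid_fmax_hz}, \code{grid_n}, \code{fit} (arguments to
#'   [fit_config()]), \code{noise} (arguments to [noise_spec()]),
#'   \code{design} (see [run_experiment()]), \code{fem_refine},
#'   \code{verbose}.
#' @return resolved config list with all defaults filled in.
#' @export
resolve_config <- function(config = list()) {
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  utils::modifyList(
    list(stages = c("synth", "fit", "stats"), seed = 1L,
         scenario = "butyrate", grid_fmin_hz = 0.1, grid_fmax_hz = 1e5,
         grid_n = 51L, fit = list(), noise = list(), design = list(),
         fem_refine = 1, verbose = TRUE),
    config)
}

.log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[multiteer] ", fmt), ...))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in order against one output directory:
#' \describe{
#'   \item{synth}{generate a synthetic treatment experiment
#'     ([gen_experiment()]) and write \code{spectra.csv} + \code{truth.csv}.}
#'   \item{fem}{sweep the forward model for the configured device scenario
#'     ([fem_sweep()]) and write its spectrum to \code{spectra.csv}.}
#'   \item{fit}{read \code{spectra.csv}, fit every electrode spectrum
#'     ([fit_experiment()]), write \code{fits.csv} (per electrode) and
#'     \code{wells.csv} (per-well aggregates).}
#'   \item{stats}{run the treatment statistics ([run_experiment()]) on
#'     \code{wells.csv}, write \code{report.csv} and \code{summary.txt}.}
#' }
#' Every run writes \code{resolved_config.yaml} (including the package version)
#' next to its outputs; a run is idempotent given identical config and seed.
#'
#' @param config see [resolve_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- resolve_config(config)
  stopifnot(all(cfg$stages %in% c("synth", "fem", "fit", "stats")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  resolved <- c(cfg, list(package_version =
                            as.character(utils::packageVersion("multiteer"))))
  cfg_path <- file.path(out_dir, "resolved_config.yaml")
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(resolved, cfg_path)
  } else {
    dput(resolved, file = cfg_path)
  }

  grid <- default_grid(cfg$grid_fmin_hz, cfg$grid_fmax_hz, cfg$grid_n)
  fitcfg <- do.call(fit_config, cfg$fit)
  artifacts <- list(resolved_config = cfg_path)
  spectra_path <- file.path(out_dir, "spectra.csv")

  for (stage in cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    if (stage == "synth") {
      scen <- scenario_template(cfg$scenario)
      exp_ <- gen_experiment(scen, noise = do.call(noise_spec, cfg$noise),
                             seed = cfg$seed, grid = grid)
      n <- write_spectra(exp_$spectra, spectra_path)
      truth_path <- file.path(out_dir, "truth.csv")
      utils::write.csv(exp_$truth, truth_path, row.names = FALSE, quote = FALSE)
      artifacts$spectra <- spectra_path
      artifacts$truth <- truth_path
      .log(cfg$verbose, "synth: %d spectra rows, %d truth rows written",
           n, nrow(exp_$truth))
    } else if (stage == "fem") {
      model <- build_device(cfg$scenario)
      mesh <- build_mesh(model, refine = cfg$fem_refine)
      sp <- fem_sweep(model, grid, mesh = mesh, electrode = "we",
                      side = "apical", timepoint = "simulated")
      n <- write_spectra(sp, spectra_path)
      artifacts$spectra <- spectra_path
      .log(cfg$verbose, "fem: scenario %s, %d nodes, %d spectrum rows written",
           cfg$scenario, mesh$n_nodes, n)
    } else if (stage == "fit") {
      if (!file.exists(spectra_path))
        stop("fit stage: no spectra.csv in the output directory (run synth or fem first)",
             call. = FALSE)
      spectra <- read_spectra(spectra_path)
      wells <- fit_experiment(spectra, fitcfg)
      fits_path <- file.path(out_dir, "fits.csv")
      write_fits(attr(wells, "fits"), fits_path)
      wells_path <- file.path(out_dir, "wells.csv")
      utils::write.csv(wells, wells_path, row.names = FALSE, quote = FALSE)
      artifacts$fits <- fits_path
      artifacts$wells <- wells_path
      .log(cfg$verbose, "fit: %d spectra fitted, %d well aggregates written",
           length(spectra), nrow(wells))
    } else if (stage == "stats") {
      wells_path <- file.path(out_dir, "wells.csv")
      if (!file.exists(wells_path))
        stop("stats stage: no wells.csv in the output directory (run fit first)",
             call. = FALSE)
      wells <- utils::read.csv(wells_path, stringsAsFactors = FALSE)
      report <- run_experiment(wells, cfg$design)
      report_path <- file.path(out_dir, "report.csv")
      utils::write.csv(report, report_path, row.names = FALSE, quote = FALSE)
      summary_path <- file.path(out_dir, "summary.txt")
      writeLines(format_report(report), summary_path)
      artifacts$report <- report_path
      artifacts$summary <- summary_path
      .log(cfg$verbose, "stats: %d comparisons written", nrow(report))
    }
    .log(cfg$verbose, "stage %s done in %.2f s", stage,
         proc.time()[["elapsed"]] - t0)
  }
  invisible(artifacts)
}

#' Human-readable text rendering of a statistics report
#'
#' @param report a [run_experiment()] report.
#' @return character vector of lines.
#' @export
format_report <- function(report) {
  header <- sprintf("%-7s %-5s %-28s %12s %12s %8s %5s",
                    "side", "time", "comparison", "mean_treated",
                    "mean_control", "p(adj)", "sig")
  lines <- vapply(seq_len(nrow(report)), function(k) {
    r <- report[k, ]
    p <- if (!is.na(r$p_adjusted)) r$p_adjusted else r$p
    sprintf("%-7s %-5s %-28s %11.2f%% %11.2f%% %8.3g %5s",
            r$side, r$timepoint, r$comparison, r$mean_treated,
            r$mean_control, p, r$stars)
  }, character(1))
  c(header, lines)
}
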