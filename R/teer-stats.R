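#' Significance stars
#'
#' Convention: \code{***} p < 0.001, \code{**} p < 0.01, \code{*} p < 0.05,
#' \code{ns} otherwise.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return character vector of star labels.
#' @export
p_stars <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "ns")))
  out[is.na(p)] <- NA_character_
  out
}

#' Convert an EVOM chopstick reading to TEER
#'
#' \deqn{\mathrm{TEER} = (\mathrm{measured} - \mathrm{blank}) \times
#'   \mathrm{growth\ area}} in ohm cm^2, with the 24-well insert growth area
#' (0.33 cm^2) as default. Negative values (blank exceeding the measurement)
#' are flagged with a warning but retained, never clamped, since clamping would
#' bias well means.
#'
#' @param measured_ohm measured resistance, ohm.
#' @param blank_ohm blank (cell-free) resistance, ohm.
#' @param area_cm2 insert growth area, cm^2 (default 0.33).
#' @return TEER in ohm cm^2 (vectorized).
#' @export
teer_from_evom <- function(measured_ohm, blank_ohm, area_cm2 = 0.33) {
  if (any(!is.finite(measured_ohm)) || any(!is.finite(blank_ohm)))
    stop("measured and blank resistances must be finite", call. = FALSE)
  if (any(area_cm2 <= 0)) stop("growth area must be > 0", call. = FALSE)
  teer <- (measured_ohm - blank_ohm) * area_cm2
  if (any(teer < 0))
    warning(sprintf("%d TEER value(s) negative (blank exceeds measurement); retained unclamped",
                    sum(teer < 0)), call. = FALSE)
  teer
}

#' Fit every spectrum of an experiment and aggregate per well
#'
#' Runs [fit_spectrum()] on each electrode spectrum and [aggregate_well()]
#' within each (condition-bearing) well/side/timepoint group, producing the
#' tidy experiment table consumed by [normalized_change()] and
#' [run_experiment()].
#'
#' @param spectra list of [impedance_spectrum()] (e.g. from
#'   [gen_experiment()]).
#' @param config a [fit_config()].
#' @param condition_by_well optional named character vector mapping well id to
#'   condition label; by default the condition is parsed from well ids of the
#'   form \code{"<condition>_w<number>"} as emitted by [gen_experiment()].
#' @return data.frame with columns \code{condition}, \code{well}, \code{side},
#'   \code{timepoint}, \code{r2}, \code{r2_sem}, \code{n_used},
#'   \code{n_total}, \code{condition_warning}; attribute \code{fits} carries
#'   the per-electrode [fit_spectrum()] results.
#' @export
fit_experiment <- function(spectra, config = fit_config(),
                           condition_by_well = NULL) {
  stopifnot(is.list(spectra), length(spectra) > 0L)
  key <- vapply(spectra, function(s)
    paste(s$well, s$side, s$timepoint, sep = "\r"), character(1))
  fits <- lapply(spectra, fit_spectrum, config = config)
  rows <- lapply(split(fits, key), function(group) {
    wf <- aggregate_well(group, config)
    cond <- if (!is.null(condition_by_well)) condition_by_well[[wf$well]]
            else sub("_w[0-9]+$", "", wf$well)
    data.frame(condition = cond, well = wf$well, side = wf$side,
               timepoint = wf$timepoint, r2 = wf$r2, r2_sem = wf$r2_sem,
               n_used = wf$n_used, n_total = wf$n_total,
               condition_warning = wf$condition_warning,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$well, out$side, out$timepoint), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Baseline-normalized barrier-resistance changes
#'
#' Per well and side, the percent change of the barrier resistance from each
#' well's own baseline measurement,
#' \eqn{100 (R_{2,t} - R_{2,0}) / R_{2,0}}. Wells without a baseline row (or
#' with a zero/missing baseline) yield missing changes and an entry in the
#' \code{log} attribute rather than a fabricated value.
#'
#' @param table experiment table as returned by [fit_experiment()] (columns
#'   \code{condition}, \code{well}, \code{side}, \code{timepoint} and a value
#'   column).
#' @param baseline_timepoint label of the baseline timepoint (default
#'   \code{"0h"}).
#' @param value_col name of the value column (default \code{"r2"}).
#' @return the table without baseline rows, with an added
#'   \code{change_pct} column; attribute \code{log} lists wells with missing
#'   or zero baselines.
#' @export
normalized_change <- function(table, baseline_timepoint = "0h",
                              value_col = "r2") {
  need <- c("well", "side", "timepoint", value_col)
  stopifnot(all(need %in% names(table)))
  key <- paste(table$well, table$side, sep = "\r")
  base_rows <- table$timepoint == baseline_timepoint
  baseline <- stats::setNames(table[[value_col]][base_rows], key[base_rows])

  out <- table[!base_rows, , drop = FALSE]
  okey <- key[!base_rows]
  b <- baseline[okey]
  log <- character(0)
  miss <- !(okey %in% names(baseline))
  if (any(miss))
    log <- c(log, sprintf("no baseline row for well %s (%s)",
                          out$well[miss], out$side[miss]))
  bad <- !miss & (is.na(b) | b == 0)
  if (any(bad))
    log <- c(log, sprintf("zero or missing baseline for well %s (%s)",
                          out$well[bad], out$side[bad]))
  change <- 100 * (out[[value_col]] - b) / b
  change[miss | bad] <- NA_real_
  out$change_pct <- as.numeric(change)
  rownames(out) <- NULL
  attr(out, "log") <- log
  out
}

#' Two-group comparison (t-test)
#'
#' Unpaired two-group comparisons default to the Welch variant (unequal
#' variances are common across inserts); \code{welch = FALSE} restores the
#' classical Student test. Groups that are element-wise identical constants
#' (degenerate zero variance with equal means) return p = 1 by convention with
#' a \code{degenerate} flag rather than an error.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @param paired paired test (requires equal lengths).
#' @param welch use the Welch-Satterthwaite correction (default TRUE).
#' @param comparison label for the output row.
#' @return one-row data.frame: \code{comparison}, \code{statistic}, \code{df},
#'   \code{p}, \code{p_adjusted} (NA for a single comparison), \code{stars},
#'   \code{degenerate}.
#' @export
t_test <- function(groupA, groupB, paired = FALSE, welch = TRUE,
                   comparison = "A vs B") {
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  if (paired && length(groupA) != length(groupB))
    stop("paired test requires equal group lengths", call. = FALSE)
  res <- tryCatch(
    stats::t.test(groupA, groupB, paired = paired, var.equal = !welch),
    error = function(e) NULL)
  if (is.null(res)) {
    # degenerate: essentially constant data; identical means are a clean null
    if (isTRUE(all.equal(mean(groupA), mean(groupB))))
      return(data.frame(comparison = comparison, statistic = 0, df = NA_real_,
                        p = 1, p_adjusted = NA_real_, stars = "ns",
                        degenerate = TRUE, stringsAsFactors = FALSE))
    stop("t-test failed: constant data with unequal means", call. = FALSE)
  }
  p <- unname(res$p.value)
  data.frame(comparison = comparison, statistic = unname(res$statistic),
             df = unname(res$parameter), p = p, p_adjusted = NA_real_,
             stars = p_stars(p), degenerate = FALSE, stringsAsFactors = FALSE)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param groups named list of >= 3 numeric vectors (each n >= 2); with fewer
#'   groups an error directs the caller to [t_test()].
#' @param alpha significance level used only for the significance flag
#'   (default 0.05).
#' @return list with \code{anova} (one-row data.frame: F statistic, df1, df2,
#'   p) and \code{pairs} (data.frame of all pairwise Tukey comparisons with
#'   studentized-range adjusted p-values and stars). All-constant input yields
#'   a flagged undefined F and non-significant pairs.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("anova_tukey needs >= 3 groups; use t_test() for two groups",
         call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  stopifnot(all(vapply(groups, length, integer(1)) >= 2L))

  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  pair_names <- utils::combn(names(groups), 2,
                             FUN = function(x) paste(x[2], x[1], sep = "-"))
  if (stats::var(values) == 0) {
    pairs <- data.frame(comparison = pair_names, diff = 0,
                        statistic = NA_real_, df = NA_real_, p = NA_real_,
                        p_adjusted = 1, stars = "ns", significant = FALSE,
                        stringsAsFactors = FALSE)
    return(list(anova = data.frame(statistic = NA_real_, df1 = NA_real_,
                                   df2 = NA_real_, p = NA_real_,
                                   degenerate = TRUE),
                pairs = pairs))
  }

  fit <- stats::aov(values ~ labels)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$labels
  p_adj <- tk[, "p adj"]
  pairs <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      statistic = NA_real_, df = an[2, "Df"],
                      p = NA_real_, p_adjusted = p_adj, stars = p_stars(p_adj),
                      significant = p_adj < alpha, stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(anova = data.frame(statistic = an[1, "F value"],
                          df1 = an[1, "Df"],
                          df2 = an[2, "Df"],
                          p = an[1, "Pr(>F)"], degenerate = FALSE),
       pairs = pairs)
}

#' Run the treatment-experiment statistics
#'
#' For each side and comparison timepoint, compares baseline-normalized barrier
#' resistance changes between conditions: two-condition designs route to
#' [t_test()] (control vs treatment), designs with three or more conditions to
#' [anova_tukey()] (all pairwise, control comparisons flagged). The report is
#' deterministic and invariant to the row order of the input table.
#'
#' @param table experiment table ([fit_experiment()] output or equivalent with
#'   columns condition, well, side, timepoint and a value column).
#' @param design list with \code{control} (control condition label),
#'   \code{baseline_timepoint} (default \code{"0h"}), \code{timepoints}
#'   (comparison timepoints; default all non-baseline timepoints),
#'   \code{welch} (default TRUE), \code{alpha} (default 0.05).
#' @param value_col value column name (default \code{"r2"}).
#' @return data.frame report: one row per side, timepoint and comparison with
#'   group means, SEMs, group sizes, test statistics, (adjusted) p-values,
#'   stars and a significance flag.
#' @export
run_experiment <- function(table, design = list(), value_col = "r2") {
  design <- utils::modifyList(
    list(control = "control", baseline_timepoint = "0h", timepoints = NULL,
         welch = TRUE, alpha = 0.05), design)
  conds <- sort(unique(table$condition))
  if (!design$control %in% conds)
    stop(sprintf("unknown control condition '%s'", design$control), call. = FALSE)
  if (is.null(design$timepoints))
    design$timepoints <- setdiff(sort(unique(table$timepoint)),
                                 design$baseline_timepoint)

  ch <- normalized_change(table, design$baseline_timepoint, value_col)
  ch <- ch[order(ch$condition, ch$well, ch$side, ch$timepoint), ]

  rows <- list()
  for (side in sort(unique(ch$side))) {
    for (tp in design$timepoints) {
      sub <- ch[ch$side == side & ch$timepoint == tp & !is.na(ch$change_pct), ]
      groups <- split(sub$change_pct, factor(sub$condition, levels = conds))
      groups <- groups[vapply(groups, length, integer(1)) >= 2L]
      if (length(groups) < 2L) next
      gm <- vapply(groups, mean, numeric(1))
      gsem <- vapply(groups, function(x) stats::sd(x) / sqrt(length(x)),
                     numeric(1))
      gn <- vapply(groups, length, integer(1))

      if (length(groups) == 2L) {
        other <- setdiff(names(groups), design$control)
        st <- t_test(groups[[other]], groups[[design$control]],
                     welch = design$welch,
                     comparison = paste(other, "vs", design$control))
        rows[[length(rows) + 1L]] <- data.frame(
          side = side, timepoint = tp, test = "t_test",
          comparison = st$comparison,
          mean_treated = gm[[other]], sem_treated = gsem[[other]],
          n_treated = gn[[other]],
          mean_control = gm[[design$control]],
          sem_control = gsem[[design$control]],
          n_control = gn[[design$control]],
          statistic = st$statistic, df = st$df, p = st$p,
          p_adjusted = NA_real_, stars = st$stars,
          significant = st$p < design$alpha, stringsAsFactors = FALSE)
      } else {
        at <- anova_tukey(groups, alpha = design$alpha)
        for (k in seq_len(nrow(at$pairs))) {
          pr <- at$pairs[k, ]
          members <- strsplit(pr$comparison, "-", fixed = TRUE)[[1]]
          treated <- setdiff(members, design$control)[1]
          control <- if (design$control %in% members) design$control
                     else members[2]
          rows[[length(rows) + 1L]] <- data.frame(
            side = side, timepoint = tp, test = "anova_tukey",
            comparison = pr$comparison,
            mean_treated = gm[[treated]], sem_treated = gsem[[treated]],
            n_treated = gn[[treated]],
            mean_control = gm[[control]], sem_control = gsem[[control]],
            n_control = gn[[control]],
            statistic = at$anova$statistic, df = at$anova$df2,
            p = at$anova$p, p_adjusted = pr$p_adjusted, stars = pr$stars,
            significant = isTRUE(pr$significant), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L)
    stop("no comparable groups found in the experiment table", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
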