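# canonical parameter sets used across tests (the synthetic population medians)
epi_params <- function() circuit_params(R1 = 120, C1 = 1e-5, R2 = 2000, C2 = 1e-6)
endo_params <- function() circuit_params(R1 = 120, C1 = 1e-5, R2 = 150, C2 = 1e-6)

unpack_params <- function(p) unlist(p[c("R1", "C1", "R2", "C2")])

# independent forward oracle: evaluate the three circuit terms separately and
# sum (plain complex arithmetic, no package code)
oracle_impedance <- function(R1, C1, R2, C2, f) {
  w <- 2 * pi * f
  term_series_r <- complex(real = rep(R1, length(f)))
  term_series_c <- complex(imaginary = -1 / (w * C1))
  denom <- complex(real = 1, imaginary = w * R2 * C2)
  term_parallel <- R2 / denom
  term_series_r + term_series_c + term_parallel
}

# exhaustive two-sample permutation p-value of the Student t statistic
perm_t_pvalue <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  t_of <- function(x, y) {
    sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
  }
  t_obs <- abs(t_of(a, b))
  idx <- utils::combn(length(pooled), na)
  ts <- apply(idx, 2, function(i) abs(t_of(pooled[i], pooled[-i])))
  mean(ts >= t_obs - 1e-12)
}

# butyrate/palmitic scenario restricted to the baseline and 48 h timepoints
# (the comparison the treatment criteria concern); effects are unchanged
two_timepoint_scenario <- function(name) {
  full <- scenario_template(name)
  scenario_spec(full$name, full$conditions, control = full$control,
                n_wells = full$n_wells,
                electrodes_per_well = full$electrodes_per_well,
                timepoints = c("0h", "48h"),
                well_fluctuation_cv = full$well_fluctuation_cv)
}
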