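# Shared fixtures: all built in code, no files.

# A changepoint set at given sentinel-free interior positions.
cpts_at <- function(interior, n, beta = 1) {
  toiseg:::new_changepoint_set(c(0L, sort(interior), n), n,
                               total_cost = NA_real_, beta = beta)
}

# Deterministic 30-sample record with three 10-sample marker blocks.
block_record <- function(values = NULL, subject_index = 1L) {
  markers <- rep(c("basal", "cold", "warm"), each = 10L)
  if (is.null(values)) values <- sin(seq_len(30)) + seq_len(30) / 10
  perfusion_record(subject_index = subject_index, code = "WT10D1",
                   group = "control", sex = "male",
                   times = seq_len(30), markers = markers, values = values)
}

# Random signal mixing piecewise-linear structure and noise, for oracle sweeps.
random_signal <- function(n) {
  kind <- sample(3L, 1L)
  if (kind == 1L) {
    b <- sample(3:(n - 3), 1L)
    y <- c(seq_len(b) * runif(1, -2, 2),
           seq_len(n - b) * runif(1, -2, 2) + runif(1, -5, 5)) +
      rnorm(n, 0, 0.5)
  } else if (kind == 2L) {
    y <- cumsum(rnorm(n)) + rnorm(n)
  } else {
    y <- rnorm(n)
  }
  y
}

# Small, fast cohort design for pipeline-level tests.
small_design <- function(seed = 11L) {
  simulation_design(
    n_per_group = c(control_female = 2L, control_male = 2L,
                    experimental_female = 2L, experimental_male = 2L),
    toi_lengths = c(basal = 60L, cold = 60L, warm = 60L),
    seed = seed)
}
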