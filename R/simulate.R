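#' Design of a synthetic perfusion cohort
#'
#' Describes a cohort emulating the statistical structure the analysis
#' assumes: per-group sample sizes over a control/experimental x female/male
#' layout, three marker blocks (basal, cold, warm) of fixed lengths,
#' piecewise-constant group response profiles, AR(1) measurement noise, and
#' a large transient artifact burst centered at every marker boundary (the
#' instrumentation noise of a manual intervention).
#'
#' Defaults mirror the cohort the method was designed around: 33 subjects
#' (16 control responders, 17 experimental non-responders), a baseline of
#' 250 perfusion units, a cold-induced drop of 40 PU with full warm recovery
#' in controls, a flat profile in the experimental group, AR(1) noise of
#' marginal sd 10 PU with coefficient 0.3, and bursts of amplitude 80 PU and
#' half-width 3 samples. Block lengths default to 120 samples each.
#'
#' @param n_per_group Named integer vector with entries `control_female`,
#'   `control_male`, `experimental_female`, `experimental_male`.
#' @param toi_lengths Integer vector of samples per marker block, named by
#'   TOI label (basal first).
#' @param baseline_mean Baseline perfusion level (perfusion units).
#' @param effects Numeric matrix (rows `control`, `experimental`; one column
#'   per TOI) of mean offsets relative to baseline, in perfusion units.
#' @param noise_sd Marginal standard deviation of the AR(1) noise (PU).
#' @param ar_coef AR(1) coefficient in `[0, 1)`; 0 gives white noise.
#' @param artifact_amp Amplitude of the boundary artifact burst (PU).
#' @param artifact_halfwidth Half-width of the burst in samples; must be
#'   smaller than half the shortest block.
#' @param artifact_shape `"square"` (default), `"triangle"` or `"exp"`.
#' @param seed Integer master seed; per-subject seeds are derived from it.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(
    n_per_group = c(control_female = 8L, control_male = 8L,
                    experimental_female = 9L, experimental_male = 8L),
    toi_lengths = c(basal = 120L, cold = 120L, warm = 120L),
    baseline_mean = 250,
    effects = rbind(control = c(0, -40, 0),
                    experimental = c(0, 0, 0)),
    noise_sd = 10,
    ar_coef = 0.3,
    artifact_amp = 80,
    artifact_halfwidth = 3L,
    artifact_shape = c("square", "triangle", "exp"),
    seed = 1L) {
  artifact_shape <- match.arg(artifact_shape)
  toi_lengths <- stats::setNames(as.integer(toi_lengths), names(toi_lengths))
  if (is.null(names(toi_lengths)) || any(!nzchar(names(toi_lengths))))
    stop("toi_lengths must be named by TOI label", call. = FALSE)
  if (ncol(effects) != length(toi_lengths))
    stop("effects needs one column per TOI", call. = FALSE)
  if (!all(rownames(effects) == c("control", "experimental")))
    stop("effects rows must be 'control' then 'experimental'", call. = FALSE)
  if (abs(ar_coef) >= 1) stop("|ar_coef| must be < 1", call. = FALSE)
  if (any(toi_lengths < 9L))
    stop("each TOI needs at least 9 samples (3 * min_len)", call. = FALSE)
  if (artifact_halfwidth >= min(toi_lengths) / 2)
    stop("artifact_halfwidth must be < min(toi_lengths)/2", call. = FALSE)
  if (noise_sd < 0 || artifact_amp < 0)
    stop("noise_sd and artifact_amp must be >= 0", call. = FALSE)
  structure(list(n_per_group = n_per_group, toi_lengths = toi_lengths,
                 baseline_mean = baseline_mean, effects = effects,
                 noise_sd = noise_sd, ar_coef = ar_coef,
                 artifact_amp = artifact_amp,
                 artifact_halfwidth = as.integer(artifact_halfwidth),
                 artifact_shape = artifact_shape,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("<simulation_design> N = %d (%s), blocks %s, seed %d\n",
              sum(x$n_per_group),
              paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                    collapse = " "),
              paste(sprintf("%s:%d", names(x$toi_lengths), x$toi_lengths),
                    collapse = " "),
              x$seed))
  invisible(x)
}

artifact_weights <- function(halfwidth, shape) {
  d <- abs(seq.int(-halfwidth, halfwidth))
  switch(shape,
         square = rep(1, length(d)),
         triangle = 1 - d / (halfwidth + 1),
         exp = exp(-2 * d / max(1, halfwidth)))
}

#' Simulate one subject's perfusion record
#'
#' The signal is a piecewise-constant mean profile
#' (`baseline_mean + effect(group, TOI)`) plus stationary AR(1) noise of
#' marginal sd `noise_sd`, plus an additive artifact burst of amplitude
#' `artifact_amp` centered on the first sample of every post-basal marker
#' block. Markers follow the designed block lengths; times are the sample
#' indices. Setting `subject_seed` makes the record fully reproducible.
#'
#' @param design A [simulation_design()].
#' @param group `"control"` or `"experimental"`.
#' @param sex `"female"` or `"male"`.
#' @param subject_index Subject number used in the record and its code.
#' @param subject_seed Integer seed, or `NULL` to use the current RNG state.
#' @return A [perfusion_record()].
#' @export
simulate_subject <- function(design, group, sex, subject_index,
                             subject_seed = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  group <- match.arg(group, c("control", "experimental"))
  sex <- match.arg(sex, c("female", "male"))
  if (!is.null(subject_seed)) set.seed(as.integer(subject_seed))
  len <- design$toi_lengths
  ni <- sum(len)
  markers <- rep(names(len), len)
  mu <- design$baseline_mean + rep(design$effects[group, ], len)
  noise <- if (design$noise_sd > 0) {
    innov_sd <- design$noise_sd * sqrt(1 - design$ar_coef^2)
    if (design$ar_coef != 0) {
      as.numeric(stats::arima.sim(list(ar = design$ar_coef), ni, sd = innov_sd))
    } else {
      stats::rnorm(ni, 0, design$noise_sd)
    }
  } else rep(0, ni)
  values <- mu + noise
  h <- design$artifact_halfwidth
  if (design$artifact_amp > 0) {
    w <- artifact_weights(h, design$artifact_shape)
    starts <- cumsum(len) + 1L
    for (b in starts[-length(starts)]) {       # first sample of blocks 2..nT
      idx <- seq.int(b - h, b + h)
      values[idx] <- values[idx] + design$artifact_amp * w
    }
  }
  prefix <- if (group == "control") "WT" else "L"
  code <- sprintf("%s%dD%d", prefix, 10L + ((subject_index - 1L) %/% 5L),
                  ((subject_index - 1L) %% 5L) + 1L)
  perfusion_record(subject_index = subject_index, code = code,
                   group = group, sex = sex,
                   times = seq_len(ni), markers = markers, values = values)
}

#' Simulate a full cohort
#'
#' Draws every subject of the design with a distinct derived seed (the master
#' seed determines all of them), giving byte-identical cohorts across runs.
#'
#' @param design A [simulation_design()].
#' @return A [cohort()] of `sum(n_per_group)` records, controls first.
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  roster <- data.frame(
    group = rep(c("control", "control", "experimental", "experimental"),
                design$n_per_group[c("control_female", "control_male",
                                     "experimental_female", "experimental_male")]),
    sex = rep(c("female", "male", "female", "male"),
              design$n_per_group[c("control_female", "control_male",
                                   "experimental_female", "experimental_male")]),
    stringsAsFactors = FALSE)
  N <- nrow(roster)
  set.seed(design$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, N)
  records <- lapply(seq_len(N), function(i)
    simulate_subject(design, roster$group[i], roster$sex[i],
                     subject_index = i, subject_seed = seeds[i]))
  cohort(records, toi_labels = names(design$toi_lengths))
}
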