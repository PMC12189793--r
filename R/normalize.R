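#' Piecewise-linear approximation over a changepoint partition
#'
#' Fits an independent ordinary-least-squares line on every inter-changepoint
#' segment (no continuity constraint: the approximation is step-like at the
#' changepoints, matching the segment costs used by the search). The total
#' RSS of the fit equals the unpenalized part of the segmentation objective
#' at the same changepoints.
#'
#' @param values Numeric signal.
#' @param cpts A `changepoint_set` valid for `values`.
#' @return An object of class `pla_model` with `breakpoints`, per-segment
#'   `coefficients` (intercept at the segment's first sample, slope per
#'   sample), `fitted` (length `ni`) and `rss`.
#' @export
fit_pla <- function(values, cpts) {
  stopifnot(inherits(cpts, "changepoint_set"))
  if (cpts$n != length(values))
    stop("changepoint set and signal have different lengths", call. = FALSE)
  pos <- cpts$positions
  nseg <- length(pos) - 1L
  fitted <- numeric(length(values))
  coef <- matrix(NA_real_, nseg, 2L,
                 dimnames = list(NULL, c("intercept", "slope")))
  rss <- 0
  for (s in seq_len(nseg)) {
    a <- pos[s] + 1L
    b <- pos[s + 1L]
    if (b - a + 1L < 2L)
      stop("segment shorter than 2 samples cannot carry a line", call. = FALSE)
    x <- seq.int(a, b)
    y <- values[a:b]
    xc <- x - mean(x)
    slope <- sum(xc * y) / sum(xc^2)
    intercept <- mean(y) - slope * mean(x)
    f <- intercept + slope * x
    fitted[a:b] <- f
    coef[s, ] <- c(intercept, slope)
    rss <- rss + sum((y - f)^2)
  }
  structure(list(breakpoints = cpts, coefficients = coef,
                 fitted = fitted, rss = rss),
            class = "pla_model")
}

#' @export
print.pla_model <- function(x, ...) {
  cat(sprintf("<pla_model> %d segments, total RSS %.6g\n",
              nrow(x$coefficients), x$rss))
  invisible(x)
}

#' Reference-state z-normalization
#'
#' Centers and scales a subject's perfusion signal by the mean and sample
#' standard deviation of its own reference TOI (usually the basal state),
#' `z(t) = (y(t) - mean_ref) / sd_ref`, and likewise for the piecewise-linear
#' approximation with its own reference statistics. Reference statistics are
#' computed over the *optimal* reference TOI only — transition-window samples
#' never enter them — but the normalization itself is applied to every sample
#' so the full record can be plotted on the normalized scale.
#'
#' @param record A [perfusion_record()].
#' @param pla A [fit_pla()] model for the record (or `NULL` to skip `z_pla`).
#' @param seg A `toi_segmentation` for the record.
#' @param ref Reference TOI index (default 1, the basal state).
#' @return An object of class `normalized_signal` with `ref_label`,
#'   `ref_mean`, `ref_sd`, `z`, and (when a PLA is given) `pla_ref_mean`,
#'   `pla_ref_sd`, `z_pla`.
#' @export
znormalize <- function(record, pla, seg, ref = 1L) {
  stopifnot(inherits(record, "perfusion_record"),
            inherits(seg, "toi_segmentation"))
  if (seg$ni != record_length(record))
    stop("segmentation and record have different lengths", call. = FALSE)
  idx <- otoi_indices(seg, ref)
  if (length(idx) < 2L)
    stop("reference TOI has fewer than 2 samples", call. = FALSE)
  m <- mean(record$values[idx])
  s <- stats::sd(record$values[idx])
  if (!is.finite(s) || s == 0)
    stop("degenerate reference: reference TOI has zero standard deviation",
         call. = FALSE)
  out <- list(ref_label = seg$toi_labels[ref], ref_toi = as.integer(ref),
              ref_mean = m, ref_sd = s,
              z = (record$values - m) / s)
  if (!is.null(pla)) {
    stopifnot(inherits(pla, "pla_model"))
    mp <- mean(pla$fitted[idx])
    sp <- stats::sd(pla$fitted[idx])
    if (!is.finite(sp) || sp == 0)
      stop("degenerate reference: PLA is constant over the reference TOI",
           call. = FALSE)
    out$pla_ref_mean <- mp
    out$pla_ref_sd <- sp
    out$z_pla <- (pla$fitted - mp) / sp
  }
  structure(out, class = "normalized_signal")
}

#' @export
print.normalized_signal <- function(x, ...) {
  cat(sprintf("<normalized_signal> ref = '%s' (mean %.4g, sd %.4g), ni = %d%s\n",
              x$ref_label, x$ref_mean, x$ref_sd, length(x$z),
              if (is.null(x$z_pla)) "" else ", with PLA"))
  invisible(x)
}

#' Aligned difference of two normalized TOI segments
#'
#' Subtracts the normalized signal of TOI `l` from that of TOI `k`, sample by
#' sample in within-TOI order, truncated to the shorter TOI. Because both
#' segments share the reference statistics, the difference equals
#' `(y_k - y_l) / sd_ref` at every aligned index, so it measures the raw
#' between-state response in units of basal variability.
#'
#' @param norm A [znormalize()] result.
#' @param seg The matching `toi_segmentation`.
#' @param k,l Distinct TOI indices, both nonempty.
#' @param source `"z"` (raw signal, default) or `"z_pla"`.
#' @return An object of class `toi_difference` with `toi_k`, `toi_l`,
#'   `diff` and `alignment_len`.
#' @export
toi_difference <- function(norm, seg, k, l, source = c("z", "z_pla")) {
  source <- match.arg(source)
  stopifnot(inherits(norm, "normalized_signal"),
            inherits(seg, "toi_segmentation"))
  if (k == l) stop("TOI indices k and l must differ", call. = FALSE)
  z <- norm[[source]]
  if (is.null(z)) stop("normalized signal has no ", source, " component",
                       call. = FALSE)
  ik <- otoi_indices(seg, k)
  il <- otoi_indices(seg, l)
  if (length(ik) == 0L || length(il) == 0L)
    stop("empty optimal TOI", call. = FALSE)
  L <- min(length(ik), length(il))
  structure(list(toi_k = as.integer(k), toi_l = as.integer(l),
                 source = source,
                 diff = z[ik[seq_len(L)]] - z[il[seq_len(L)]],
                 alignment_len = as.integer(L)),
            class = "toi_difference")
}
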