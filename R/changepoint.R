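#' Least-squares cost of a single segment
#'
#' Residual sum of squares of the ordinary-least-squares line fitted to
#' `values[a:b]` against the sample indices `a..b`. This is the per-segment
#' cost used by the penalized segmentation: a segmentation is scored as the
#' sum of its segments' RSS plus a penalty per changepoint. With
#' `cost = "constant"` the line is replaced by the segment mean (classical
#' mean-change cost).
#'
#' @param values Numeric vector (the full signal).
#' @param a,b 1-based segment bounds, inclusive; `b - a + 1 >= 2`.
#' @param cost `"linear"` (OLS line, default) or `"constant"` (mean).
#' @return Non-negative RSS; 0 iff the samples are exactly collinear
#'   (respectively constant).
#' @examples
#' linear_segment_cost(c(0, 1, 0), 1, 3)  # 2/3
#' @export
linear_segment_cost <- function(values, a, b, cost = c("linear", "constant")) {
  cost <- match.arg(cost)
  a <- as.integer(a); b <- as.integer(b)
  if (a < 1L || b > length(values) || b - a + 1L < 2L)
    stop("segment must contain at least 2 samples and lie within the signal",
         call. = FALSE)
  y <- values[a:b]
  n <- length(y)
  syy <- sum((y - mean(y))^2)
  if (cost == "constant") return(syy)
  x <- seq_len(n) - (n + 1) / 2          # centered index
  sxy <- sum(x * y)
  sxx <- n * (n^2 - 1) / 12
  max(0, syy - sxy^2 / sxx)
}

#' Penalty configuration for penalized changepoint search
#'
#' @param beta Non-negative penalty added per changepoint.
#' @param min_len Minimum segment length (>= 2; default 3, because any
#'   2-point segment has zero linear RSS and would be degenerately favored).
#' @param sigma_hat Noise-scale estimate the penalty was derived from
#'   (informational; `NA` when beta was set by hand).
#' @param cost Segment cost family, `"linear"` or `"constant"`.
#' @return An object of class `penalty_config`.
#' @seealso [default_penalty()]
#' @export
penalty_config <- function(beta, min_len = 3L, sigma_hat = NA_real_,
                           cost = c("linear", "constant")) {
  cost <- match.arg(cost)
  beta <- as.numeric(beta); min_len <- as.integer(min_len)
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (min_len < 2L) stop("min_len must be >= 2", call. = FALSE)
  structure(list(beta = beta, min_len = min_len, sigma_hat = sigma_hat,
                 cost = cost),
            class = "penalty_config")
}

#' Data-driven default penalty
#'
#' Estimates the noise scale robustly from first differences,
#' `sigma_hat = 1.4826 * MAD(diff(values)) / sqrt(2)` (first differencing
#' removes slowly varying structure; the sqrt(2) undoes the variance doubling
#' of differencing), and sets a BIC-flavored penalty
#' `beta = 2 * sigma_hat^2 * log(n)` with `min_len = 3`. A noise-free input
#' (`sigma_hat = 0`) raises a degenerate-noise warning and a small positive
#' floor is applied to beta so the search still prefers parsimony.
#'
#' @param values Numeric vector, length >= 4.
#' @param cost Segment cost family passed through to the config.
#' @return A [penalty_config()].
#' @export
default_penalty <- function(values, cost = c("linear", "constant")) {
  cost <- match.arg(cost)
  n <- length(values)
  if (n < 4L) stop("need at least 4 samples to estimate a penalty", call. = FALSE)
  sigma_hat <- stats::mad(diff(values)) / sqrt(2)
  beta <- 2 * sigma_hat^2 * log(n)
  if (sigma_hat == 0) {
    warning("degenerate noise estimate (sigma_hat = 0); applying beta floor",
            call. = FALSE)
    beta <- 1e-8
  }
  penalty_config(beta = beta, min_len = 3L, sigma_hat = sigma_hat, cost = cost)
}

new_changepoint_set <- function(positions, n, total_cost, beta) {
  structure(list(positions = as.integer(positions),
                 interior = as.integer(positions[positions != 0L & positions != n]),
                 interior_count = sum(positions != 0L & positions != n),
                 total_cost = total_cost,
                 beta = beta,
                 n = as.integer(n)),
            class = "changepoint_set")
}

#' @export
print.changepoint_set <- function(x, ...) {
  cat(sprintf("<changepoint_set> n = %d, m = %d interior changepoints, penalized cost %.6g\n",
              x$n, x$interior_count, x$total_cost))
  cat("  positions:", paste(x$positions, collapse = " "), "\n")
  invisible(x)
}

# Vectorized segment RSS for segments (s+1)..t, s in `starts0` (0-based ends of
# the previous segment), shared cumulative sums. Index shift to the segment
# start keeps the centered sums well conditioned for long signals.
segment_costs_to <- function(cum, t, starts0, cost) {
  a <- starts0 + 1
  m <- t - starts0
  sy <- cum$cy[t + 1L] - cum$cy[a]
  syy <- cum$cyy[t + 1L] - cum$cyy[a]
  syyc <- syy - sy^2 / m
  if (cost == "constant") return(pmax(0, syyc))
  sty <- cum$cty[t + 1L] - cum$cty[a]
  sxy <- (sty - a * sy) - (m - 1) / 2 * sy   # x centered at segment mean index
  sxx <- m * (m^2 - 1) / 12
  pmax(0, syyc - sxy^2 / sxx)
}

make_cumsums <- function(values) {
  t <- seq_along(values)
  list(cy = c(0, cumsum(values)),
       cyy = c(0, cumsum(values^2)),
       cty = c(0, cumsum(t * values)))
}

#' Exact penalized segmentation by PELT
#'
#' Minimizes `sum of segment costs + beta * (number of changepoints)` over all
#' segmentations whose segments are at least `min_len` samples long, by the
#' Pruned Exact Linear Time dynamic program. Pruning is exact here because the
#' per-segment RSS cost is subadditive under splitting (a single line is an
#' admissible fit on each half), so discarded candidates can never re-enter
#' the optimum. Ties are broken toward the fewest changepoints, then the
#' leftmost last changepoint, so results are deterministic.
#'
#' A changepoint at position `p` is a boundary after sample `p`: segments are
#' the closed index ranges between consecutive positions, and the returned
#' positions carry sentinels `0` and `n`.
#'
#' @param values Numeric signal, length >= `2 * min_len`.
#' @param cfg A [penalty_config()]; defaults to [default_penalty()].
#' @return A `changepoint_set` with elements `positions` (with sentinels),
#'   `interior`, `interior_count`, `total_cost` (penalized objective) and
#'   `beta`.
#' @seealso [exhaustive_segment()] for the enumeration oracle.
#' @export
pelt_segment <- function(values, cfg = default_penalty(values)) {
  stopifnot(inherits(cfg, "penalty_config"))
  n <- length(values)
  L <- cfg$min_len
  if (n < 2L * L)
    stop(sprintf("signal too short: need at least 2*min_len = %d samples", 2L * L),
         call. = FALSE)
  beta <- cfg$beta
  cum <- make_cumsums(values)

  F <- rep(Inf, n + 1L)   # F[s+1] = optimal penalized cost of 1..s
  F[1L] <- -beta
  ncp <- integer(n + 1L)
  back <- integer(n + 1L)
  cand <- 0L              # candidate last-changepoint positions (0-based)
  expire <- Inf           # last time each candidate may still be used:
                          # a candidate dominated at time t is provably
                          # useless only from t + min_len on (paths through t
                          # need a segment of at least min_len), so pruning
                          # is delayed by min_len - 1 steps
  for (t in seq.int(L, n)) {
    alive <- expire >= t
    cand <- cand[alive]
    expire <- expire[alive]
    adm <- t - cand >= L
    ok <- cand[adm]
    C <- segment_costs_to(cum, t, ok, cfg$cost)
    G <- F[ok + 1L] + C + beta
    # min with ties broken by fewest changepoints then leftmost position
    v <- min(G)
    tie <- which(G == v)
    if (length(tie) > 1L) {
      nc <- ncp[ok[tie] + 1L]
      tie <- tie[order(nc, ok[tie])]
    }
    s <- ok[tie[1L]]
    F[t + 1L] <- v
    back[t + 1L] <- s
    ncp[t + 1L] <- if (s == 0L) 0L else ncp[s + 1L] + 1L
    dominated <- adm
    dominated[adm] <- F[ok + 1L] + C > v
    expire[dominated] <- pmin(expire[dominated], t + L - 1)
    cand <- c(cand, t)
    expire <- c(expire, Inf)
  }
  pos <- n
  p <- n
  while (p > 0L) {
    p <- back[p + 1L]
    pos <- c(p, pos)
  }
  new_changepoint_set(pos, n, F[n + 1L], beta)
}

#' Global-optimum segmentation by exhaustive enumeration
#'
#' Enumerates every admissible partition (all segments >= `min_len`) and
#' returns the one minimizing the penalized objective; serves as an
#' independent oracle for [pelt_segment()] on short signals. Refuses inputs
#' longer than `guard` samples.
#'
#' @inheritParams pelt_segment
#' @param guard Maximum signal length accepted (default 25).
#' @return A `changepoint_set`.
#' @export
exhaustive_segment <- function(values, cfg = default_penalty(values), guard = 25L) {
  stopifnot(inherits(cfg, "penalty_config"))
  n <- length(values)
  if (n > guard)
    stop(sprintf("exhaustive search refused for n = %d > guard = %d", n, guard),
         call. = FALSE)
  L <- cfg$min_len
  if (n < max(L, 2L))
    stop("signal too short", call. = FALSE)
  partitions <- enumerate_partitions(n, L)
  best <- NULL
  best_cost <- Inf
  best_m <- NA_integer_
  for (bounds in partitions) {
    segcost <- 0
    prev <- 0L
    for (p in bounds) {
      segcost <- segcost + linear_segment_cost(values, prev + 1L, p, cfg$cost)
      prev <- p
    }
    m <- length(bounds) - 1L
    total <- segcost + cfg$beta * m
    if (total < best_cost ||
        (total == best_cost && (m < best_m ||
          (m == best_m && bounds[1L] < best[1L])))) {
      best <- bounds; best_cost <- total; best_m <- m
    }
  }
  new_changepoint_set(c(0L, best), n, best_cost, cfg$beta)
}

# All vectors of segment end positions (ending at n) with gaps >= min_len.
enumerate_partitions <- function(n, min_len) {
  recurse <- function(start) {
    out <- list()
    if (n - start + 1L >= min_len) out[[1L]] <- n
    lo <- start + min_len - 1L
    hi <- n - min_len
    ends <- if (lo <= hi) seq.int(lo, hi) else integer()
    for (e in ends) {
      for (tail in recurse(e + 1L)) out[[length(out) + 1L]] <- c(e, tail)
    }
    out
  }
  if (n < 2L * min_len) return(list(n))
  recurse(1L)
}
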