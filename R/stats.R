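#' Kruskal-Wallis omnibus test over a list of samples
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' `groups - 1` degrees of freedom (delegating to [stats::kruskal.test()]).
#' When every value in every group is identical the statistic is defined as
#' `H = 0`, `p = 1`.
#'
#' @param samples List (optionally named) of >= 2 nonempty numeric vectors.
#' @return List with elements `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("need a list of at least 2 samples", call. = FALSE)
  if (any(lengths(samples) == 0L))
    stop("every sample must be nonempty", call. = FALSE)
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), lengths(samples)))
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(samples) - 1L))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Pairwise rank-based multiple comparison (Dunn's test)
#'
#' Dunn's z statistics on the pooled ranking with tie correction,
#' `z_ab = (Rbar_a - Rbar_b) / sqrt((N(N+1)/12 - T) (1/n_a + 1/n_b))` with
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups, two-sided normal
#' p-values, and a family-wise correction over all pairs (Holm by default).
#' Returns the significance matrix at level `alpha` together with the
#' adjusted p-values, so the sensitivity of downstream counts to the
#' correction choice can be reported.
#'
#' @param samples List of >= 2 nonempty numeric vectors (>= 3 for the
#'   family-wise correction to matter).
#' @param alpha Family-wise significance level (default 0.05).
#' @param method Correction passed to [stats::p.adjust()]: `"holm"`
#'   (default), `"bonferroni"`, or any other supported method.
#' @return An object of class `pairwise_comparison`: `sig` (symmetric logical
#'   matrix, `FALSE` diagonal), `p_adj`, `z`, `alpha`, `method`.
#' @export
pairwise_multicompare <- function(samples, alpha = 0.05, method = "holm") {
  ng <- length(samples)
  if (ng < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(lengths(samples) == 0L))
    stop("every sample must be nonempty", call. = FALSE)
  nm <- names(samples) %||% as.character(seq_len(ng))
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_len(ng), lengths(samples))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- lengths(samples)
  ties <- tabulate(match(x, unique(x)))  # exact-equality tie groups
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr

  z <- matrix(0, ng, ng, dimnames = list(nm, nm))
  p <- matrix(NA_real_, ng, ng, dimnames = list(nm, nm))
  pairs <- utils::combn(ng, 2L)
  praw <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    a <- pairs[1L, c]; b <- pairs[2L, c]
    se <- sqrt(v0 * (1 / n[a] + 1 / n[b]))
    zz <- if (se > 0) (rbar[a] - rbar[b]) / se else 0
    z[a, b] <- z[b, a] <- zz
    praw[c] <- 2 * stats::pnorm(-abs(zz))
  }
  padj <- stats::p.adjust(praw, method = method)
  for (c in seq_len(ncol(pairs))) {
    a <- pairs[1L, c]; b <- pairs[2L, c]
    p[a, b] <- p[b, a] <- padj[c]
  }
  diag(p) <- 1
  sig <- p < alpha
  diag(sig) <- FALSE
  structure(list(sig = sig, p_adj = p, z = z, alpha = alpha, method = method),
            class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf("<pairwise_comparison> Dunn/%s at alpha = %g: %d of %d pairs significant\n",
              x$method, x$alpha, sum(x$sig[upper.tri(x$sig)]),
              sum(upper.tri(x$sig))))
  invisible(x)
}

#' Per-subject counts of significant pairwise differences
#'
#' Summarizes a pairwise significance matrix subject by subject: how many
#' other subjects each one differs from, split by the *other* subject's
#' group, with a formatted label in the style `"32: 15 WT and 17 LNAME"`.
#'
#' @param sig Symmetric logical matrix (e.g. `$sig` of
#'   [pairwise_multicompare()]).
#' @param group_labels Character vector of group names, one per subject
#'   (row of `sig`); exactly 2 distinct values expected for the formatted
#'   label, more are allowed (label then lists every group).
#' @return A data frame with columns `subject`, `group`, `total`, one count
#'   column per group level (`vs_<level>`), and `label`; `total` always
#'   equals the sum of the per-group counts.
#' @export
difference_counts <- function(sig, group_labels) {
  stopifnot(is.matrix(sig), nrow(sig) == ncol(sig))
  ns <- nrow(sig)
  if (length(group_labels) != ns)
    stop("group_labels must cover every subject", call. = FALSE)
  levels <- unique(group_labels)
  out <- data.frame(subject = seq_len(ns), group = group_labels,
                    total = as.integer(rowSums(sig)),
                    stringsAsFactors = FALSE)
  for (lv in levels) {
    out[[paste0("vs_", lv)]] <-
      as.integer(rowSums(sig[, group_labels == lv, drop = FALSE]))
  }
  out$label <- vapply(seq_len(ns), function(i) {
    parts <- vapply(levels, function(lv)
      sprintf("%d %s", out[[paste0("vs_", lv)]][i], lv), character(1))
    sprintf("%d: %s", out$total[i], paste(parts, collapse = " and "))
  }, character(1))
  out
}

#' Tukey box-and-whisker summary
#'
#' Five-number summary using linearly interpolated quartiles (quantile
#' type 6, the (n+1)p plotting position), whiskers at the most extreme
#' observations within `1.5 * IQR` of the quartiles, and everything beyond
#' flagged as outliers.
#'
#' @param series Nonempty numeric vector.
#' @return List with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
box_stats <- function(series) {
  series <- series[is.finite(series)]
  if (length(series) == 0L) stop("series must be nonempty", call. = FALSE)
  q <- stats::quantile(series, c(0.25, 0.5, 0.75), names = FALSE, type = 6)
  iqr <- q[3L] - q[1L]
  lo <- q[1L] - 1.5 * iqr
  hi <- q[3L] + 1.5 * iqr
  inside <- series[series >= lo & series <= hi]
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(series[series < lo | series > hi]))
}
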