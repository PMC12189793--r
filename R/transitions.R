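#' Split detected changepoints by the experimenter's TOI markers
#'
#' Assigns every interior changepoint to exactly one TOI by the marker of the
#' sample at its position (sentinels 0 and `ni` are excluded). A changepoint
#' sitting on the first sample of a marker block therefore belongs to that
#' block's TOI.
#'
#' @param cpts A `changepoint_set` from [pelt_segment()] on `record$values`.
#' @param record The [perfusion_record()] the changepoints were detected on.
#' @return Named list of `nT` integer vectors (possibly empty), one per TOI
#'   label in recording order.
#' @export
split_by_marker <- function(cpts, record) {
  stopifnot(inherits(cpts, "changepoint_set"),
            inherits(record, "perfusion_record"))
  if (cpts$n != record_length(record))
    stop("changepoint set and record have different lengths", call. = FALSE)
  labels <- unique(record$markers)
  out <- stats::setNames(rep(list(integer()), length(labels)), labels)
  for (p in cpts$interior) {
    lab <- record$markers[p]
    out[[lab]] <- c(out[[lab]], p)
  }
  out
}

#' Intervention times from per-TOI changepoint subsets
#'
#' The intervention time of TOI `j` is the earliest detected-changepoint
#' position inside that TOI's marker block. When a post-basal TOI holds no
#' changepoint, the experimenter's marker boundary (the block's first sample)
#' is used as a fallback, with a warning: markers are error-prone but are the
#' only information left. The basal entry is computed when available and
#' reported as `NA` (unused) otherwise.
#'
#' @param subsets Output of [split_by_marker()].
#' @param record The corresponding [perfusion_record()].
#' @return Numeric vector `IT` of length `nT` (sample indices; entry 1 may be
#'   `NA`).
#' @export
intervention_times <- function(subsets, record) {
  blk <- marker_blocks(record$markers)
  if (!identical(blk$label, names(subsets)))
    stop("changepoint subsets do not match the record's marker blocks",
         call. = FALSE)
  nT <- nrow(blk)
  it <- rep(NA_real_, nT)
  for (j in seq_len(nT)) {
    if (length(subsets[[j]]) > 0L) {
      it[j] <- min(subsets[[j]])
    } else if (j >= 2L) {
      it[j] <- blk$start[j]
      warning(sprintf(
        "no changepoint detected in TOI %d ('%s'); falling back to the marker boundary at sample %d",
        j, blk$label[j], blk$start[j]), call. = FALSE)
    }
  }
  it
}

#' Optimal TOIs and transition windows
#'
#' Converts detected changepoints plus experimenter markers into the record's
#' optimal times of interest (OTOI) and the transition windows (OTT) that
#' isolate intervention artifacts. The window half-width `k` is the total
#' number of interior changepoints detected after the basal TOI; each
#' transition window is the symmetric range `[IT_(j+1) - k, IT_(j+1) + k]`
#' around the intervention time, and the optimal TOIs are what remains, so
#' that OTOI and OTT together partition `1..ni` exactly:
#' \itemize{
#'   \item `otoi[1] = [1, IT_2 - k - 1]`
#'   \item `ott[j] = [IT_(j+1) - k, IT_(j+1) + k]`, `j = 1..nT-1`
#'   \item `otoi[j] = [IT_j + k + 1, IT_(j+1) - k - 1]` for `1 < j < nT`
#'   \item `otoi[nT] = [IT_nT + k + 1, ni]`
#' }
#'
#' When the windows would overlap or leave an empty TOI, the default is an
#' inadmissible-window error naming the offending TOI; with `clamp = TRUE`
#' the half-width is instead reduced to the largest admissible value (with a
#' warning), which preserves window symmetry and the exact-cover property.
#'
#' @param cpts A `changepoint_set` for the record's values.
#' @param record A [perfusion_record()] with at least 2 marker blocks.
#' @param clamp Reduce `k` instead of failing on inadmissible windows.
#' @return An object of class `toi_segmentation` with elements `k`,
#'   `it_times`, `otoi`, `ott` (lists of closed index ranges `c(a, b)`),
#'   `toi_subsets`, `toi_labels` and `ni`.
#' @export
optimal_tois <- function(cpts, record, clamp = FALSE) {
  blk <- marker_blocks(record$markers)
  nT <- nrow(blk)
  if (nT < 2L)
    stop("need at least 2 TOIs (marker blocks) to define transitions",
         call. = FALSE)
  subsets <- split_by_marker(cpts, record)
  it <- intervention_times(subsets, record)
  ni <- record_length(record)
  k <- sum(lengths(subsets[-1L]))

  build <- function(k) {
    otoi <- vector("list", nT)
    ott <- vector("list", nT - 1L)
    otoi[[1L]] <- c(1L, it[2L] - k - 1L)
    for (j in seq_len(nT - 1L)) ott[[j]] <- c(it[j + 1L] - k, it[j + 1L] + k)
    if (nT > 2L) {
      for (j in 2:(nT - 1L)) otoi[[j]] <- c(it[j] + k + 1L, it[j + 1L] - k - 1L)
    }
    otoi[[nT]] <- c(it[nT] + k + 1L, ni)
    list(otoi = otoi, ott = ott)
  }
  offending <- function(k) {
    if (it[2L] - k <= 1L) return(1L)
    if (nT > 2L) for (j in 2:(nT - 1L)) {
      if (it[j] + k + 1L > it[j + 1L] - k - 1L) return(j)
    }
    if (it[nT] + k >= ni) return(nT)
    NA_integer_
  }
  bad <- offending(k)
  if (!is.na(bad)) {
    if (!clamp)
      stop(sprintf(
        "inadmissible window: transition half-width k = %d empties or overlaps TOI %d; use a smaller k (larger penalty) or clamp = TRUE",
        k, bad), call. = FALSE)
    k_adm <- k
    while (k_adm > 0L && !is.na(offending(k_adm))) k_adm <- k_adm - 1L
    if (!is.na(offending(k_adm)))
      stop("inadmissible window: no admissible half-width exists for this record",
           call. = FALSE)
    warning(sprintf("transition half-width clamped from %d to %d", k, k_adm),
            call. = FALSE)
    k <- k_adm
  }
  rng <- build(k)
  structure(list(k = as.integer(k), it_times = it,
                 otoi = rng$otoi, ott = rng$ott,
                 toi_subsets = subsets, toi_labels = blk$label,
                 ni = as.integer(ni)),
            class = "toi_segmentation")
}

#' @export
print.toi_segmentation <- function(x, ...) {
  fmt <- function(r) sprintf("[%d-%d]", r[1L], r[2L])
  cat(sprintf("<toi_segmentation> ni = %d, k = %d, IT = (%s)\n",
              x$ni, x$k, paste(round(x$it_times), collapse = ", ")))
  cat("  OTOI:", paste(vapply(x$otoi, fmt, character(1)), collapse = " "), "\n")
  cat("  OTT: ", paste(vapply(x$ott, fmt, character(1)), collapse = " "), "\n")
  invisible(x)
}

#' Sample indices of one optimal TOI
#' @param seg A `toi_segmentation`.
#' @param j TOI index.
#' @return Integer vector of sample indices.
#' @export
otoi_indices <- function(seg, j) {
  r <- seg$otoi[[j]]
  seq.int(r[1L], r[2L])
}

#' Sample indices of all transition windows
#' @param seg A `toi_segmentation`.
#' @return Integer vector of all samples inside any transition window.
#' @export
ott_indices <- function(seg) {
  unlist(lapply(seg$ott, function(r) seq.int(r[1L], r[2L])))
}

#' Serialize a segmentation to JSON
#' @param seg A `toi_segmentation`.
#' @return JSON string with fields `k`, `IT`, `otoi`, `ott`.
#' @export
segmentation_json <- function(seg) {
  jsonlite::toJSON(list(k = seg$k, IT = seg$it_times,
                        otoi = lapply(seg$otoi, as.integer),
                        ott = lapply(seg$ott, as.integer)),
                   auto_unbox = FALSE, digits = NA)
}
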