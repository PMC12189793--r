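#' Perfusion recording for one experimental subject
#'
#' Container for a single subject's perfusion time series together with the
#' experimenter's TOI markers (basal plus post-intervention states) and the
#' subject's metadata. Times, markers and values must have a common length
#' `ni`; times must be strictly increasing and uniformly sampled (all segment
#' arithmetic downstream is carried out in 1-based sample-index space, which
#' requires a constant sampling interval); markers must form contiguous,
#' non-repeating blocks in recording order, one block per TOI.
#'
#' @param subject_index Integer subject number `i` (1-based within a cohort).
#' @param code Internal text label for the subject (e.g. `"WT14D4"`).
#' @param group `"control"` or `"experimental"`.
#' @param sex `"female"` or `"male"`.
#' @param times Numeric vector of time stamps, length `ni`.
#' @param markers Character vector of TOI labels per sample, length `ni`.
#' @param values Numeric perfusion measurements (arbitrary perfusion units),
#'   length `ni`.
#' @param uniform_tol Relative tolerance on the sampling interval when
#'   checking uniformity (fraction of the median interval).
#'
#' @return An object of class `perfusion_record`.
#' @seealso [cohort()], [simulate_subject()]
#' @export
perfusion_record <- function(subject_index, code, group, sex,
                             times, markers, values,
                             uniform_tol = 1e-6) {
  group <- match.arg(group, c("control", "experimental"))
  sex <- match.arg(sex, c("female", "male"))
  subject_index <- as.integer(subject_index)
  times <- as.numeric(times)
  markers <- as.character(markers)
  values <- as.numeric(values)
  ni <- length(values)
  if (length(times) != ni || length(markers) != ni)
    stop("times, markers and values must have identical length", call. = FALSE)
  if (ni < 2L)
    stop("a perfusion record needs at least two samples", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0))
    stop("time order error: times must be strictly increasing", call. = FALSE)
  step <- stats::median(dt)
  if (any(abs(dt - step) > uniform_tol * step))
    stop("time order error: sampling must be uniform (within tolerance)",
         call. = FALSE)
  labels <- marker_blocks(markers)$label
  if (anyDuplicated(labels))
    stop("marker error: markers must form contiguous non-repeating blocks",
         call. = FALSE)
  structure(
    list(subject_index = subject_index, code = as.character(code),
         group = group, sex = sex,
         times = times, markers = markers, values = values),
    class = "perfusion_record")
}

#' @export
print.perfusion_record <- function(x, ...) {
  blk <- marker_blocks(x$markers)
  cat(sprintf("<perfusion_record> #%d %s (%s %s), ni = %d\n",
              x$subject_index, x$code, x$group, x$sex, length(x$values)))
  cat("  TOIs:", paste(sprintf("%s[%d-%d]", blk$label, blk$start, blk$end),
                       collapse = " "), "\n")
  invisible(x)
}

# Run-length view of the marker column: one row per contiguous block.
marker_blocks <- function(markers) {
  r <- rle(markers)
  end <- cumsum(r$lengths)
  data.frame(label = r$values,
             start = end - r$lengths + 1L,
             end = end,
             stringsAsFactors = FALSE)
}

#' Number of samples in a record
#' @param record A [perfusion_record()].
#' @return Integer `ni`.
#' @export
record_length <- function(record) length(record$values)

#' Cohort of perfusion records
#'
#' Bundles subject records with the ordered list of TOI labels (basal first).
#' Subject indices must be unique and dense `1..N`, and every record must
#' carry exactly the cohort's marker labels in the cohort's order.
#'
#' @param records List of [perfusion_record()] objects.
#' @param toi_labels Ordered character vector of the `nT` TOI labels. Defaults
#'   to the marker order of the first record (first appearance = basal).
#' @return An object of class `perfusion_cohort`.
#' @export
cohort <- function(records, toi_labels = NULL) {
  if (length(records) == 0L) {
    return(structure(list(records = list(),
                          toi_labels = as.character(toi_labels %||% character())),
                     class = "perfusion_cohort"))
  }
  ok <- vapply(records, inherits, logical(1), "perfusion_record")
  if (!all(ok)) stop("all records must be perfusion_record objects", call. = FALSE)
  if (is.null(toi_labels)) toi_labels <- unique(records[[1L]]$markers)
  idx <- vapply(records, `[[`, integer(1), "subject_index")
  if (!identical(sort(idx), seq_along(records)))
    stop("subject_index values must be unique and dense 1..N", call. = FALSE)
  records <- records[order(idx)]
  for (r in records) {
    if (!identical(unique(r$markers), toi_labels))
      stop(sprintf("marker error: subject %d has marker blocks (%s) not matching cohort TOI labels (%s)",
                   r$subject_index,
                   paste(unique(r$markers), collapse = ","),
                   paste(toi_labels, collapse = ",")), call. = FALSE)
  }
  structure(list(records = records, toi_labels = as.character(toi_labels)),
            class = "perfusion_cohort")
}

#' @export
print.perfusion_cohort <- function(x, ...) {
  cat(sprintf("<perfusion_cohort> N = %d subjects, TOIs: %s\n",
              length(x$records), paste(x$toi_labels, collapse = " > ")))
  invisible(x)
}

#' @export
length.perfusion_cohort <- function(x) length(x$records)

`%||%` <- function(a, b) if (is.null(a)) b else a
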