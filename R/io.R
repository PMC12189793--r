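#' Layout configuration for block-format input files
#'
#' Input workbooks hold one 4-column block per subject, laid side by side on
#' one sheet: a within-subject row index, the time stamps, the TOI markers,
#' and the perfusion values. The first row is a header whose four cells carry
#' the subject's internal code, group and sex (fourth cell unused). Column
#' roles can be remapped for files that deviate from this arrangement.
#'
#' @param index_col,time_col,marker_col,value_col 1-based column roles within
#'   each 4-column block.
#' @param header Logical; does the first row carry code/group/sex metadata?
#' @param toi_order Optional character vector fixing the TOI label order;
#'   default is first-appearance order (basal assumed first).
#' @return An object of class `layout_config`.
#' @export
layout_config <- function(index_col = 1L, time_col = 2L, marker_col = 3L,
                          value_col = 4L, header = TRUE, toi_order = NULL) {
  cols <- c(index_col, time_col, marker_col, value_col)
  if (!identical(sort(as.integer(cols)), 1:4))
    stop("column roles must be a permutation of 1:4", call. = FALSE)
  structure(list(index_col = as.integer(index_col),
                 time_col = as.integer(time_col),
                 marker_col = as.integer(marker_col),
                 value_col = as.integer(value_col),
                 header = isTRUE(header),
                 toi_order = toi_order),
            class = "layout_config")
}

#' Read a block-format cohort workbook
#'
#' Reads a cohort from a single sheet holding one 4-column block per subject
#' (see [layout_config()]). `.xlsx` files are read through the readxl
#' package; `.csv`/`.tsv` files holding the same side-by-side layout are read
#' directly. Trailing empty cells in a block are trimmed, and marker labels
#' are mapped to TOI order by first appearance (or by `layout$toi_order`).
#'
#' @param path Path to the workbook or delimited file.
#' @param layout A [layout_config()].
#' @return A [cohort()].
#' @export
read_workbook <- function(path, layout = layout_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading xlsx requires the readxl package", call. = FALSE)
    as.data.frame(readxl::read_excel(path, col_names = FALSE,
                                     col_types = "text"),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = if (ext == "tsv") "\t" else ",",
                      header = FALSE, colClasses = "character",
                      stringsAsFactors = FALSE, fill = TRUE,
                      na.strings = c("", "NA"))
  }
  if (ncol(raw) %% 4L != 0L)
    stop("layout error: sheet width ", ncol(raw),
         " is not a multiple of 4 columns", call. = FALSE)
  nblocks <- ncol(raw) %/% 4L
  records <- vector("list", nblocks)
  toi_order <- layout$toi_order
  for (s in seq_len(nblocks)) {
    block <- raw[, (4L * (s - 1L) + 1L):(4L * s), drop = FALSE]
    meta <- c(code = sprintf("S%02d", s), group = "control", sex = "female")
    body <- block
    if (layout$header) {
      hd <- as.character(unlist(block[1L, ]))
      meta["code"] <- hd[1L] %|NA|% meta["code"]
      meta["group"] <- hd[2L] %|NA|% meta["group"]
      meta["sex"] <- hd[3L] %|NA|% meta["sex"]
      body <- block[-1L, , drop = FALSE]
    }
    # trim trailing all-empty rows (ragged blocks on a shared sheet)
    nonempty <- rowSums(!is.na(body)) > 0L
    keep <- if (any(nonempty)) seq_len(max(which(nonempty))) else integer()
    body <- body[keep, , drop = FALSE]
    if (nrow(body) == 0L)
      stop(sprintf("layout error: subject block %d is empty", s), call. = FALSE)
    tm <- suppressWarnings(as.numeric(body[[layout$time_col]]))
    vv <- suppressWarnings(as.numeric(body[[layout$value_col]]))
    mk <- as.character(body[[layout$marker_col]])
    if (anyNA(tm))
      stop(sprintf("layout error: subject block %d, time column holds non-numeric cells", s),
           call. = FALSE)
    if (anyNA(vv))
      stop(sprintf("layout error: subject block %d, value column holds non-numeric cells", s),
           call. = FALSE)
    if (anyNA(mk) || any(!nzchar(mk)))
      stop(sprintf("layout error: subject block %d, marker column holds empty cells", s),
           call. = FALSE)
    if (any(diff(tm) <= 0))
      stop(sprintf("time order error: subject block %d", s), call. = FALSE)
    if (!is.null(toi_order) && !all(mk %in% toi_order))
      stop(sprintf("marker error: subject block %d holds labels outside (%s)",
                   s, paste(toi_order, collapse = ",")), call. = FALSE)
    records[[s]] <- perfusion_record(
      subject_index = s, code = meta[["code"]],
      group = meta[["group"]], sex = meta[["sex"]],
      times = tm, markers = mk, values = vv)
  }
  cohort(records, toi_labels = toi_order %||% unique(records[[1L]]$markers))
}

`%|NA|%` <- function(a, b) if (is.na(a) || !nzchar(a)) b else a

#' Write a cohort as a long-format table
#'
#' One UTF-8 tab-separated file with columns `subject_index`, `code`,
#' `group`, `sex`, `time`, `marker`, `value`; the round trip through
#' [read_cohort_table()] is lossless.
#'
#' @param cohort_obj A [cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort_obj, path) {
  stopifnot(inherits(cohort_obj, "perfusion_cohort"))
  rows <- lapply(cohort_obj$records, function(r)
    data.frame(subject_index = r$subject_index, code = r$code,
               group = r$group, sex = r$sex,
               time = r$times, marker = r$markers, value = r$values,
               stringsAsFactors = FALSE))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_index = integer(), code = character(),
               group = character(), sex = character(), time = numeric(),
               marker = character(), value = numeric())
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format cohort table
#'
#' Inverse of [write_cohort_table()].
#'
#' @param path Path to a tab-separated long-format cohort file.
#' @param toi_order Optional TOI label order override.
#' @return A [cohort()].
#' @export
read_cohort_table <- function(path, toi_order = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("subject_index", "code", "group", "sex", "time", "marker", "value")
  if (!all(need %in% names(tab)))
    stop("layout error: missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L) return(cohort(list(), toi_labels = toi_order))
  records <- lapply(split(tab, tab$subject_index), function(d) {
    d <- d[order(d$time), ]
    perfusion_record(subject_index = d$subject_index[1L], code = d$code[1L],
                     group = d$group[1L], sex = d$sex[1L],
                     times = d$time, markers = d$marker, values = d$value)
  })
  cohort(unname(records), toi_labels = toi_order)
}

#' Write a cohort in the block workbook layout
#'
#' Side-by-side 4-column blocks (CSV), the same arrangement
#' [read_workbook()] consumes — handy for building fixtures and for
#' round-tripping simulated cohorts through the ingestion path.
#'
#' @param cohort_obj A [cohort()].
#' @param path Output `.csv` path.
#' @param layout A [layout_config()] (header must be `TRUE`).
#' @return `path`, invisibly.
#' @export
write_workbook_csv <- function(cohort_obj, path, layout = layout_config()) {
  stopifnot(inherits(cohort_obj, "perfusion_cohort"))
  recs <- cohort_obj$records
  if (length(recs) == 0L) stop("cannot write an empty cohort workbook",
                               call. = FALSE)
  nmax <- max(vapply(recs, record_length, integer(1)))
  cols <- list()
  for (r in recs) {
    blk <- matrix("", nrow = nmax + 1L, ncol = 4L)
    blk[1L, ] <- c(r$code, r$group, r$sex, "")
    ni <- record_length(r)
    fill <- function(col, x) blk[1L + seq_len(ni), col] <<- as.character(x)
    fill(layout$index_col, seq_len(ni))
    fill(layout$time_col, r$times)
    fill(layout$marker_col, r$markers)
    fill(layout$value_col, r$values)
    cols[[length(cols) + 1L]] <- blk
  }
  full <- do.call(cbind, cols)
  utils::write.table(full, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-TOI matrix of a record's segmented series
#'
#' Restricts the chosen series to each optimal TOI and formats the (ragged)
#' columns both as a list and as a rectangular matrix padded with `NA` (a
#' true missing-value marker, never a numeric code). Transition-window
#' samples appear in no column.
#'
#' @param record A [perfusion_record()].
#' @param seg The record's `toi_segmentation`.
#' @param source `"values"`, `"z"`, or `"pla_z"`.
#' @param norm A [znormalize()] result; required for `"z"`/`"pla_z"`.
#' @return An object of class `toi_matrix`: `subject_index`, `columns`
#'   (named list of numeric vectors) and `padded` (matrix, `NA`-padded).
#' @export
toi_matrix <- function(record, seg, source = c("values", "z", "pla_z"),
                       norm = NULL) {
  source <- match.arg(source)
  stopifnot(inherits(record, "perfusion_record"),
            inherits(seg, "toi_segmentation"))
  if (seg$ni != record_length(record))
    stop("segmentation and record have different lengths", call. = FALSE)
  series <- switch(source,
    values = record$values,
    z = { if (is.null(norm)) stop("source 'z' needs a normalized signal",
                                  call. = FALSE); norm$z },
    pla_z = { if (is.null(norm) || is.null(norm$z_pla))
                stop("source 'pla_z' needs a normalized signal with a PLA",
                     call. = FALSE); norm$z_pla })
  nT <- length(seg$otoi)
  columns <- stats::setNames(
    lapply(seq_len(nT), function(j) series[otoi_indices(seg, j)]),
    seg$toi_labels)
  nmax <- max(lengths(columns))
  padded <- vapply(columns, function(col) c(col, rep(NA_real_, nmax - length(col))),
                   numeric(nmax))
  if (is.null(dim(padded))) padded <- matrix(padded, nrow = nmax,
                                             dimnames = list(NULL, names(columns)))
  structure(list(subject_index = record$subject_index,
                 source = source, columns = columns, padded = padded),
            class = "toi_matrix")
}

#' Export a padded TOI matrix as CSV
#'
#' `NA` sentinels become empty cells.
#'
#' @param tm A [toi_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toi_matrix <- function(tm, path) {
  stopifnot(inherits(tm, "toi_matrix"))
  utils::write.table(tm$padded, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE, na = "")
  invisible(path)
}
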