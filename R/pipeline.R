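#' Pipeline configuration
#'
#' Exactly one of `input` (a long-format table or block workbook on disk) or
#' `design` (a [simulation_design()]) must be given.
#'
#' @param input Path to an input cohort file, or `NULL`.
#' @param design A [simulation_design()], or `NULL`.
#' @param layout A [layout_config()] for block-format inputs.
#' @param penalty A [penalty_config()], or `NULL` for the per-subject
#'   [default_penalty()].
#' @param ref Reference TOI index for the normalization (default 1, basal).
#' @param posthoc Family-wise correction for the pairwise comparison
#'   (`"holm"` or `"bonferroni"`).
#' @param alpha Significance level for the pairwise comparison.
#' @param clamp Clamp inadmissible transition windows (see [optimal_tois()]).
#' @param out_dir Output directory for the report bundle, or `NULL` to skip
#'   writing.
#' @param plots Write per-subject segmented-signal and group box plots
#'   (PDF) into the bundle.
#' @param seed Integer seed applied before any stochastic step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, design = NULL,
                            layout = layout_config(), penalty = NULL,
                            ref = 1L, posthoc = c("holm", "bonferroni"),
                            alpha = 0.05, clamp = FALSE,
                            out_dir = NULL, plots = FALSE, seed = 1L) {
  posthoc <- match.arg(posthoc)
  if (is.null(input) == is.null(design))
    stop("exactly one of input / design must be given", call. = FALSE)
  structure(list(input = input, design = design, layout = layout,
                 penalty = penalty, ref = as.integer(ref), posthoc = posthoc,
                 alpha = alpha, clamp = isTRUE(clamp), out_dir = out_dir,
                 plots = isTRUE(plots), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `input`, `design` (a named list of
#' [simulation_design()] arguments; `effects` as a 2-row list), `penalty`
#' (`beta`, `min_len`, `cost`), `ref`, `posthoc`, `alpha`, `clamp`,
#' `out_dir`, `plots`, `seed`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- NULL
  if (!is.null(y$design)) {
    args <- y$design
    if (!is.null(args$effects))
      args$effects <- do.call(rbind, args$effects)
    if (!is.null(args$n_per_group)) args$n_per_group <- unlist(args$n_per_group)
    if (!is.null(args$toi_lengths)) args$toi_lengths <- unlist(args$toi_lengths)
    design <- do.call(simulation_design, args)
  }
  penalty <- if (!is.null(y$penalty))
    do.call(penalty_config, y$penalty) else NULL
  pipeline_config(input = y$input, design = design, penalty = penalty,
                  ref = y$ref %||% 1L, posthoc = y$posthoc %||% "holm",
                  alpha = y$alpha %||% 0.05, clamp = y$clamp %||% FALSE,
                  out_dir = y$out_dir, plots = y$plots %||% FALSE,
                  seed = y$seed %||% 1L)
}

#' Segment, approximate and normalize one record
#'
#' The per-subject stage of the pipeline: penalized changepoint detection,
#' optimal TOI/transition computation, piecewise-linear approximation, and
#' reference-state normalization.
#'
#' @param record A [perfusion_record()].
#' @param penalty A [penalty_config()] or `NULL` for [default_penalty()].
#' @param ref Reference TOI index.
#' @param clamp Passed to [optimal_tois()].
#' @return List with `record`, `cpts`, `seg`, `pla`, `norm`.
#' @export
analyze_record <- function(record, penalty = NULL, ref = 1L, clamp = FALSE) {
  cfg <- penalty %||% default_penalty(record$values)
  cpts <- pelt_segment(record$values, cfg)
  seg <- optimal_tois(cpts, record, clamp = clamp)
  pla <- fit_pla(record$values, cpts)
  norm <- znormalize(record, pla, seg, ref = ref)
  list(record = record, cpts = cpts, seg = seg, pla = pla, norm = norm)
}

#' Run the full analysis pipeline
#'
#' Executes, for every subject: penalized segmentation, optimal
#' TOI/transition computation, PLA fitting and reference-state
#' normalization; then the cohort-level comparative statistics of the
#' method: Kruskal-Wallis tests on the basal state (raw per individual,
#' normalized per interest group), on cold-to-basal and warm-to-cold
#' normalized differences (per individual and per interest group, raw and
#' PLA), the pairwise multiple comparison across individuals with
#' per-subject difference counts, and box summaries. Only optimal-TOI
#' samples enter any statistic; transition windows are excluded throughout.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `perfusion_report` (see Details), invisibly
#'   written to `cfg$out_dir` when given.
#' @details The report holds `cohort`, `subjects` (per-subject stage
#'   results), `stats` (named test results), `counts` (difference-count
#'   tables for both TOI contrasts), and `config` echoes.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  set.seed(cfg$seed)
  cohort_obj <- if (!is.null(cfg$design)) {
    simulate_cohort(cfg$design)
  } else {
    ext <- tolower(tools::file_ext(cfg$input))
    if (ext %in% c("tsv", "txt")) read_cohort_table(cfg$input)
    else read_workbook(cfg$input, cfg$layout)
  }
  subjects <- lapply(cohort_obj$records, function(r) {
    tryCatch(analyze_record(r, cfg$penalty, cfg$ref, cfg$clamp),
             error = function(e) stop(sprintf("subject %d (%s): %s",
                                              r$subject_index, r$code,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
  nT <- length(cohort_obj$toi_labels)
  groups4 <- vapply(cohort_obj$records, function(r)
    paste(r$group, r$sex, sep = "_"), character(1))
  groups2 <- vapply(cohort_obj$records, `[[`, character(1), "group")

  series_by_subject <- function(f) lapply(subjects, f)
  pool_by <- function(series, labels) {
    lv <- unique(labels)
    stats::setNames(lapply(lv, function(g)
      unlist(series[labels == g], use.names = FALSE)), lv)
  }
  basal_raw <- series_by_subject(function(s)
    s$record$values[otoi_indices(s$seg, cfg$ref)])
  basal_z <- series_by_subject(function(s) s$norm$z[otoi_indices(s$seg, cfg$ref)])
  diffs <- function(k, l, source) series_by_subject(function(s)
    toi_difference(s$norm, s$seg, k, l, source)$diff)

  stats_out <- list(
    basal_raw_individuals = kruskal_wallis(basal_raw),
    basal_z_groups = kruskal_wallis(pool_by(basal_z, groups4)))
  counts <- list()
  contrasts <- list()
  if (nT >= 2L) contrasts$cold_to_basal <- c(2L, 1L)
  if (nT >= 3L) contrasts$warm_to_cold <- c(3L, 2L)
  for (nmc in names(contrasts)) {
    kl <- contrasts[[nmc]]
    for (src in c("z", "z_pla")) {
      d <- diffs(kl[1L], kl[2L], src)
      tag <- if (src == "z") nmc else paste0(nmc, "_pla")
      stats_out[[paste0(tag, "_individuals")]] <- kruskal_wallis(d)
      stats_out[[paste0(tag, "_groups")]] <- kruskal_wallis(pool_by(d, groups4))
      if (src == "z") {
        pw <- pairwise_multicompare(d, alpha = cfg$alpha, method = cfg$posthoc)
        cnt <- difference_counts(pw$sig, groups2)
        cnt$code <- vapply(cohort_obj$records, `[[`, character(1), "code")
        counts[[nmc]] <- list(pairwise = pw, counts = cnt)
      }
    }
  }
  report <- structure(
    list(cohort = cohort_obj, subjects = subjects, stats = stats_out,
         counts = counts,
         k_values = vapply(subjects, function(s) s$seg$k, integer(1)),
         it_times = lapply(subjects, function(s) s$seg$it_times),
         config = cfg),
    class = "perfusion_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.perfusion_report <- function(x, ...) {
  cat(sprintf("<perfusion_report> N = %d subjects, %d TOIs\n",
              length(x$cohort$records), length(x$cohort$toi_labels)))
  cat(sprintf("  median transition half-width k = %g\n",
              stats::median(x$k_values)))
  for (nm in names(x$stats))
    cat(sprintf("  K-W %-32s H = %8.3f  p = %.4g\n",
                nm, x$stats[[nm]]$H, x$stats[[nm]]$p))
  invisible(x)
}

#' Write a report bundle
#'
#' Writes `summary.json` (test statistics, per-subject k and intervention
#' times, configuration echo), `counts_<contrast>.tsv` difference-count
#' tables, the long-format cohort table, and, when `report$config$plots` is
#' set, per-subject segmented-signal plots and group box plots as PDFs.
#'
#' @param report A `perfusion_report`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  summary <- list(
    n_subjects = length(report$cohort$records),
    toi_labels = report$cohort$toi_labels,
    posthoc = cfg$posthoc, alpha = cfg$alpha, seed = cfg$seed,
    k = report$k_values,
    it_times = report$it_times,
    tests = lapply(report$stats, function(s) s[c("H", "p", "df")]))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(report$counts)) {
    utils::write.table(report$counts[[nm]]$counts,
                       file.path(out_dir, sprintf("counts_%s.tsv", nm)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_cohort_table(report$cohort, file.path(out_dir, "cohort.tsv"))
  if (isTRUE(cfg$plots)) {
    grDevices::pdf(file.path(out_dir, "subjects.pdf"), width = 9, height = 4)
    on.exit(grDevices::dev.off(), add = TRUE)
    for (s in report$subjects) plot_segmented(s)
    plot_group_boxes(report)
  }
  invisible(out_dir)
}
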