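#' Plot a subject's normalized, segmented signal
#'
#' Normalized signal and its normalized PLA over the full record, with the
#' optimal TOIs shaded and the transition-window bounds drawn as dashed
#' vertical lines.
#'
#' @param subject One element of a report's `subjects` list (the result of
#'   [analyze_record()]).
#' @param shade Background colors recycled over the optimal TOIs.
#' @return Invisibly, `NULL`.
#' @export
plot_segmented <- function(subject,
                           shade = c("#DDDDDD", "#CCE5FF", "#FFD6D6")) {
  norm <- subject$norm
  seg <- subject$seg
  rec <- subject$record
  z <- norm$z
  graphics::plot(seq_along(z), z, type = "n",
                 xlab = "sample", ylab = "z (ref-normalized)",
                 main = sprintf("#%d %s (%s %s), k = %d",
                                rec$subject_index, rec$code, rec$group,
                                rec$sex, seg$k))
  usr <- graphics::par("usr")
  for (j in seq_along(seg$otoi)) {
    r <- seg$otoi[[j]]
    graphics::rect(r[1L], usr[3L], r[2L], usr[4L],
                   col = shade[(j - 1L) %% length(shade) + 1L], border = NA)
  }
  graphics::lines(seq_along(z), z, col = "grey30")
  if (!is.null(norm$z_pla))
    graphics::lines(seq_along(norm$z_pla), norm$z_pla, col = "red", lwd = 2)
  for (r in seg$ott)
    graphics::abline(v = r, lty = 2, col = "blue")
  invisible(NULL)
}

#' Group-level box plots of normalized basal values and TOI differences
#'
#' One panel per comparison (normalized basal state, cold-to-basal,
#' warm-to-cold), each showing the four interest groups
#' (group x sex) with Tukey whiskers.
#'
#' @param report A `perfusion_report`.
#' @return Invisibly, `NULL`.
#' @export
plot_group_boxes <- function(report) {
  cfg <- report$config
  groups4 <- vapply(report$cohort$records, function(r)
    paste(r$group, r$sex, sep = "\n"), character(1))
  panels <- list(
    "normalized basal" = lapply(report$subjects, function(s)
      s$norm$z[otoi_indices(s$seg, cfg$ref)]))
  nT <- length(report$cohort$toi_labels)
  if (nT >= 2L)
    panels[["cold - basal"]] <- lapply(report$subjects, function(s)
      toi_difference(s$norm, s$seg, 2L, 1L)$diff)
  if (nT >= 3L)
    panels[["warm - cold"]] <- lapply(report$subjects, function(s)
      toi_difference(s$norm, s$seg, 3L, 2L)$diff)
  old <- graphics::par(mfrow = c(1, length(panels)))
  on.exit(graphics::par(old), add = TRUE)
  for (nm in names(panels)) {
    pooled <- split(unlist(panels[[nm]], use.names = FALSE),
                    rep(groups4, lengths(panels[[nm]])))
    graphics::boxplot(pooled, main = nm, ylab = "z difference",
                      range = 1.5, las = 2, cex.axis = 0.7)
  }
  invisible(NULL)
}
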