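#' Assemble a report bundle from upstream results
#'
#' Writes, into \code{outDir}: a violin plot of SP-selected corrected
#' reporter band power per condition (when a reporter table is given),
#' bar-with-error plots for velocity groups and bin fractions, a summary
#' CSV with one row per requested group comparison, and a
#' machine-readable JSON run log (seed, configuration, package and R
#' versions; no timestamps, so regeneration from the same inputs is
#' byte-identical).  No multiple-testing correction is applied — the
#' summary counts the comparisons so users can correct externally.
#'
#' @param reporter optional long-format table from
#'   \code{\link{quantifyReporter}} (multiple conditions row-bound).
#' @param velocityGroups optional named list of per-condition velocity
#'   vectors (two groups).
#' @param composition optional output of \code{\link{mpBpComposition}}.
#' @param binTables optional named list of \code{\link{binDistribution}}
#'   tables per condition.
#' @param config configuration list, see \code{\link{defaultConfig}}.
#' @param outDir output directory (created if needed).
#' @return invisibly, list with \code{summary} (the comparisons
#'   data.frame) and \code{files} (paths written).
#' @export
makeReport <- function(reporter = NULL, velocityGroups = NULL,
                       composition = NULL, binTables = NULL,
                       config = defaultConfig(), outDir) {
  if (is.null(reporter) && is.null(velocityGroups) && is.null(composition) &&
      is.null(binTables)) {
    stop("no inputs: at least one upstream table is required")
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  rows <- list()

  if (!is.null(reporter)) {
    f <- file.path(outDir, "reporter_violin.png")
    grDevices::png(f, width = 700, height = 500)
    print(plotReporterViolin(reporter))
    grDevices::dev.off()
    files <- c(files, f)
    conds <- unique(reporter$condition)
    sp <- reporter[reporter$in_sp_selection, , drop = FALSE]
    if (length(conds) == 2L) {
      gs <- tTestUnpaired(sp$B_star[sp$condition == conds[1]],
                          sp$B_star[sp$condition == conds[2]],
                          variant = config$t_test_variant, names = conds)
      rows[[length(rows) + 1L]] <- groupStatsRow(gs, "reporter_B_star_SP")
    }
    # per-slice aggregation alongside the per-grid values: which of the
    # two is "n" in a given experiment is a design choice, so both are
    # emitted
    agg <- stats::aggregate(B_star ~ condition + slice_id, data = sp, median)
    names(agg)[3] <- "median_B_star_SP"
    fsl <- file.path(outDir, "reporter_slice_medians.csv")
    writeResults(agg, fsl)
    files <- c(files, fsl)
  }

  if (!is.null(velocityGroups)) {
    stopifnot(length(velocityGroups) == 2L)
    gs <- compareVelocity(velocityGroups, variant = config$t_test_variant)
    rows[[length(rows) + 1L]] <- groupStatsRow(gs, "radial_velocity")
    bar <- do.call(rbind, lapply(names(velocityGroups), function(nm) {
      ms <- meanSem(velocityGroups[[nm]])
      data.frame(condition = nm, mean = ms$mean, sem = ms$sem, n = ms$n)
    }))
    f <- file.path(outDir, "velocity_bar.png")
    grDevices::png(f, width = 500, height = 500)
    print(
      ggplot2::ggplot(bar, ggplot2::aes(x = .data$condition, y = .data$mean)) +
        ggplot2::geom_col(fill = "grey70") +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                            ymax = .data$mean + .data$sem),
                               width = 0.2) +
        ggplot2::labs(x = NULL, y = "radial velocity (um/h)") +
        ggplot2::theme_classic())
    grDevices::dev.off()
    files <- c(files, f)
  }

  if (!is.null(composition)) {
    f <- file.path(outDir, "mp_bp_composition.csv")
    writeResults(composition, f)
    files <- c(files, f)
  }

  if (!is.null(binTables)) {
    tab <- do.call(rbind, lapply(names(binTables), function(nm) {
      cbind(condition = nm, binTables[[nm]])
    }))
    f <- file.path(outDir, "bin_fractions.png")
    grDevices::png(f, width = 600, height = 500)
    print(
      ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$bin),
                                        y = .data$fraction,
                                        fill = .data$condition)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::labs(x = "BIN (1 = pial-most)", y = "fraction of cells") +
        ggplot2::theme_classic())
    grDevices::dev.off()
    files <- c(files, file.path(outDir, "bin_fractions.csv"), f)
    writeResults(tab, file.path(outDir, "bin_fractions.csv"))
  }

  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(comparison = character(0))
  sf <- file.path(outDir, "summary.csv")
  writeResults(summary, sf)
  lf <- file.path(outDir, "runlog.json")
  jsonlite::write_json(
    list(seed = config$seed, config = config,
         package_version = as.character(utils::packageVersion("radmig")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    lf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, sf, lf)
  invisible(list(summary = summary, files = files))
}
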