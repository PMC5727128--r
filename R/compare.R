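## Two-species comparisons of absolute and relative (proportion) brain
## measurements: pooled-variance t-tests from summaries or specimens,
## per-specimen proportions, and headline ratio summaries.

#' Two-sample t-test from group summaries
#'
#' Computes the two-tailed two-sample t-test directly from per-group mean,
#' SD and n. The default is the pooled-variance (Student) test with
#' `df = n1 + n2 - 2`; `var_equal = FALSE` gives the Welch test. When both
#' SDs are zero the test degenerates: equal means give `t = 0, p = 1`;
#' different means give an infinite statistic with `p` reported at the
#' smallest representable positive double.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param var_equal Pooled variance if `TRUE` (default), Welch otherwise.
#' @param measure Optional measure label carried into the result.
#' @param mode Optional label for what was compared: `"absolute"`,
#'   `"proportion_of_brain"` or `"proportion_of_telencephalon"`.
#' @return A `group_comparison` list: the inputs plus `t`, `df`, `p`.
#' @examples
#' pooled_t_from_summary(224.87, 34.92, 3, 54.28, 7.04, 3)$p
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                  var_equal = TRUE, measure = NA_character_,
                                  mode = "absolute") {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative", call. = FALSE)
  diff <- mean1 - mean2
  if (sd1 == 0 && sd2 == 0) {
    t_stat <- if (diff == 0) 0 else sign(diff) * Inf
    df <- n1 + n2 - 2
    p <- if (diff == 0) 1 else .Machine$double.xmin
  } else if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t_stat <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    p <- max(2 * stats::pt(-abs(t_stat), df), .Machine$double.xmin)
  } else {
    a <- sd1^2 / n1
    b <- sd2^2 / n2
    t_stat <- diff / sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
    p <- max(2 * stats::pt(-abs(t_stat), df), .Machine$double.xmin)
  }
  structure(list(measure = measure, mode = mode,
                 mean1 = mean1, sd1 = sd1, n1 = n1,
                 mean2 = mean2, sd2 = sd2, n2 = n2,
                 t = t_stat, df = df, p = p,
                 var_equal = var_equal),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s t-test%s: t = %.3f, df = %.4g, p = %.4g\n",
              if (x$var_equal) "Pooled" else "Welch",
              if (is.na(x$measure)) "" else paste0(" [", x$measure, "]"),
              x$t, x$df, x$p))
  invisible(x)
}

#' Per-specimen relative brain-region sizes
#'
#' Divides each region volume by the specimen's whole-brain volume, and
#' additionally expresses the olfactory-bulb volume as a proportion of
#' telencephalon volume. Proportions are computed per specimen (not as
#' ratios of group means), so they can feed proportion-mode t-tests.
#'
#' @param specimens Data frame with one row per specimen: a species
#'   column, a brain-volume column, and numeric region-volume columns.
#' @param species_col,brain_col,telencephalon_col,ob_col Column names
#'   (defaults `"species"`, `"brain"`, `"telencephalon"`,
#'   `"olfactory_bulb"`).
#' @param exclude Numeric columns that are not volumes and must not enter
#'   the part-of-whole computation (default `"mitral_cells"`, a cell
#'   count).
#' @return A data frame with the species column and one proportion column
#'   per region (named `<region>_vs_brain`), plus
#'   `olfactory_bulb_vs_telencephalon` when both columns are present.
#' @export
relative_measures <- function(specimens, species_col = "species",
                              brain_col = "brain",
                              telencephalon_col = "telencephalon",
                              ob_col = "olfactory_bulb",
                              exclude = "mitral_cells") {
  stopifnot(is.data.frame(specimens))
  if (!brain_col %in% names(specimens)) {
    stop("no '", brain_col, "' column", call. = FALSE)
  }
  brain <- specimens[[brain_col]]
  if (any(!is.finite(brain)) || any(brain <= 0)) {
    stop("brain volume must be positive for every specimen", call. = FALSE)
  }
  regions <- setdiff(names(specimens)[vapply(specimens, is.numeric, logical(1))],
                     c(brain_col, exclude))
  out <- specimens[, intersect(c(species_col), names(specimens)), drop = FALSE]
  for (r in regions) {
    v <- specimens[[r]]
    if (any(v > brain, na.rm = TRUE)) {
      stop("region '", r, "' exceeds brain volume for some specimen",
           call. = FALSE)
    }
    out[[paste0(r, "_vs_brain")]] <- v / brain
  }
  if (all(c(ob_col, telencephalon_col) %in% names(specimens))) {
    out[["olfactory_bulb_vs_telencephalon"]] <-
      specimens[[ob_col]] / specimens[[telencephalon_col]]
  }
  out
}

#' Per-measure two-species comparison table
#'
#' Summarises a per-specimen table into group means/SDs and runs one
#' pooled t-test per numeric measure between the two species present.
#' With `mode = "proportion"` the specimens are first converted with
#' [relative_measures()].
#'
#' @param specimens Per-specimen data frame (see [relative_measures()]).
#' @param mode `"absolute"` (raw volumes/counts) or `"proportion"`.
#' @param species_col Species column name.
#' @param ... Passed to [relative_measures()] in proportion mode.
#' @return Data frame with one row per measure: group means, SDs, ns, `t`,
#'   `df`, `p`.
#' @export
group_compare_table <- function(specimens, mode = c("absolute", "proportion"),
                                species_col = "species", ...) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(specimens))
  spp <- unique(specimens[[species_col]])
  if (length(spp) != 2L) {
    stop("expected exactly 2 species, got ", length(spp), call. = FALSE)
  }
  if (mode == "proportion") {
    specimens <- relative_measures(specimens, species_col = species_col, ...)
  }
  measures <- names(specimens)[vapply(specimens, is.numeric, logical(1))]
  rows <- lapply(measures, function(m) {
    v1 <- specimens[[m]][specimens[[species_col]] == spp[1]]
    v2 <- specimens[[m]][specimens[[species_col]] == spp[2]]
    cmp <- pooled_t_from_summary(mean(v1), stats::sd(v1), length(v1),
                                 mean(v2), stats::sd(v2), length(v2),
                                 measure = m, mode = mode)
    data.frame(measure = m, species1 = spp[1], mean1 = cmp$mean1,
               sd1 = cmp$sd1, n1 = cmp$n1, species2 = spp[2],
               mean2 = cmp$mean2, sd2 = cmp$sd2, n2 = cmp$n2,
               t = cmp$t, df = cmp$df, p = cmp$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Headline ratios between two species
#'
#' From a summary table of group means, reports the mean ratio (species 1
#' over species 2) per measure and the percent difference
#' `100 * (mean2 - mean1) / mean2` (positive when species 1 is smaller).
#'
#' @param summary_table Data frame with columns `measure`, `mean1`,
#'   `mean2` (as produced by [group_compare_table()]).
#' @return Data frame with `measure`, `ratio`, `percent_difference`.
#' @export
ratio_report <- function(summary_table) {
  stopifnot(is.data.frame(summary_table))
  need <- c("measure", "mean1", "mean2")
  if (!all(need %in% names(summary_table))) {
    stop("summary table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(summary_table$mean2 == 0)) {
    stop("zero denominator mean in measure(s): ",
         paste(summary_table$measure[summary_table$mean2 == 0], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    measure = summary_table$measure,
    ratio = summary_table$mean1 / summary_table$mean2,
    percent_difference = 100 * (summary_table$mean2 - summary_table$mean1) /
      summary_table$mean2
  )
}
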