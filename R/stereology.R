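## Optical-fractionator population estimation, Gundersen-Jensen
## coefficients of error, and Cavalieri serial-section volumes.

#' Optical fractionator sampling design
#'
#' Encodes the three sampling fractions of the optical fractionator. The
#' areal sampling fraction is derived from the counting-frame and grid
#' dimensions: `asf = (frame_x * frame_y) / (grid_x * grid_y)`.
#'
#' @param ssf Section sampling fraction, e.g. `1/10` for every 10th
#'   section.
#' @param frame Counting-frame dimensions in micrometres, length-2 (e.g.
#'   `c(70, 70)`).
#' @param grid Sampling-grid dimensions in micrometres, length-2 (e.g.
#'   `c(250, 250)`).
#' @param tsf Thickness sampling fraction (disector height / section
#'   thickness); defaults to 1, i.e. the full mounted thickness is
#'   counted.
#' @return A `fractionator_design` list with `ssf`, `asf`, `tsf`, `frame`,
#'   `grid`.
#' @export
fractionator_design <- function(ssf, frame = c(70, 70), grid = c(250, 250),
                                tsf = 1) {
  stopifnot(length(frame) == 2L, length(grid) == 2L)
  if (any(frame <= 0) || any(grid <= 0)) {
    stop("frame and grid dimensions must be positive", call. = FALSE)
  }
  asf <- prod(frame) / prod(grid)
  for (f in c(ssf = ssf, asf = asf, tsf = tsf)) {
    if (!is.finite(f) || f <= 0 || f > 1) {
      stop("sampling fractions must lie in (0, 1]; got ssf=", ssf,
           ", asf=", signif(asf, 4), ", tsf=", tsf, call. = FALSE)
    }
  }
  structure(list(ssf = ssf, asf = asf, tsf = tsf, frame = frame, grid = grid),
            class = "fractionator_design")
}

#' Optical-fractionator population estimate
#'
#' The unbiased fractionator estimator: total tally divided by the product
#' of the sampling fractions,
#' `N_hat = sum(Q) * (1/ssf) * (1/asf) * (1/tsf)`.
#'
#' @param tallies Non-negative integer vector of per-section counts (Q-).
#' @param design A [fractionator_design()].
#' @return A `stereology_sample` list: `tallies`, `design`, `total_q`,
#'   `N_hat`, and the Gundersen-Jensen `ce` (NA when fewer than 3
#'   sections).
#' @export
fractionator_estimate <- function(tallies, design) {
  stopifnot(inherits(design, "fractionator_design"))
  if (!length(tallies)) stop("need at least one section", call. = FALSE)
  if (any(!is.finite(tallies)) || any(tallies < 0)) {
    stop("tallies must be non-negative", call. = FALSE)
  }
  total_q <- sum(tallies)
  n_hat <- total_q / (design$ssf * design$asf * design$tsf)
  ce <- if (length(tallies) >= 3L && total_q > 0) gundersen_ce(tallies)
        else NA_real_
  structure(list(tallies = tallies, design = design, total_q = total_q,
                 N_hat = n_hat, ce = ce),
            class = "stereology_sample")
}

#' @export
print.stereology_sample <- function(x, ...) {
  cat(sprintf("Fractionator estimate: N_hat = %.0f from %d sections (sum Q = %d)\n",
              x$N_hat, length(x$tallies), as.integer(x$total_q)))
  cat(sprintf("  ssf %.4g, asf %.4g, tsf %.4g; CE %s\n", x$design$ssf,
              x$design$asf, x$design$tsf,
              if (is.na(x$ce)) "n/a" else sprintf("%.3f", x$ce)))
  invisible(x)
}

#' Gundersen-Jensen coefficient of error
#'
#' CE of a systematic-uniform-random fractionator count, combining the
#' Poisson counting ("nugget") variance `sum(Q)` with the
#' systematic-sampling variance of the section series estimated from
#' lag-0/1/2 products of the tallies. The default smoothness class
#' `m = 1` suits smooth biological section profiles; `m = 0` is the
#' conservative alternative. In the Poisson-dominated limit (many cells,
#' flat profile) the CE approaches `1/sqrt(sum(Q))`.
#'
#' @param tallies Per-section counts, in section order; at least 3.
#' @param m Smoothness class, 0 or 1 (default 1).
#' @return The CE (a non-negative scalar) with attributes `noise` (Poisson
#'   component, `sum(Q)`) and `var_srs` (systematic-sampling component);
#'   `NA` with a warning when all tallies are zero.
#' @export
gundersen_ce <- function(tallies, m = 1) {
  if (length(tallies) < 3L) stop("need at least 3 sections", call. = FALSE)
  if (!m %in% c(0, 1)) stop("smoothness class m must be 0 or 1", call. = FALSE)
  q <- as.numeric(tallies)
  total <- sum(q)
  if (total == 0) {
    warning("all tallies are zero; CE undefined")
    return(NA_real_)
  }
  A <- sum(q * q)
  B <- sum(q[-length(q)] * q[-1])
  C <- if (length(q) > 2L) sum(q[seq_len(length(q) - 2L)] * q[-(1:2)]) else 0
  noise <- total
  var_srs <- if (m == 1) {
    (3 * (A - noise) - 4 * B + C) / 240
  } else {
    (3 * A - 4 * B + C) / 12
  }
  var_srs <- max(var_srs, 0)
  ce <- sqrt(noise + var_srs) / total
  attr(ce, "noise") <- noise
  attr(ce, "var_srs") <- var_srs
  ce
}

#' Cavalieri volume from serial profile areas
#'
#' Estimates a solid's volume from an ordered stack of section profile
#' areas as `sum(areas) * spacing`, the Cavalieri estimator. `spacing` is
#' the distance between consecutive *measured* sections — mounting
#' interval times cut thickness (see [section_spacing()]); e.g. every 4th
#' section cut at 40 micrometres gives 0.16 mm and a volume in mm^3 when
#' areas are in mm^2.
#'
#' @param areas Ordered profile areas (mm^2), non-negative.
#' @param spacing Distance between measured sections (mm), positive.
#' @return Estimated volume (mm^3).
#' @export
volume_from_sections <- function(areas, spacing) {
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stop("spacing must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop("profile areas must be non-negative and finite", call. = FALSE)
  }
  sum(areas) * spacing
}

#' Distance between measured serial sections
#'
#' @param interval Mounting interval in sections (e.g. 4 for every 4th
#'   section).
#' @param thickness Cut thickness of one section, in mm (e.g. 0.04 for 40
#'   micrometres).
#' @return Spacing in mm.
#' @export
section_spacing <- function(interval, thickness) {
  if (interval < 1 || thickness <= 0) {
    stop("interval must be >= 1 and thickness > 0", call. = FALSE)
  }
  interval * thickness
}
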