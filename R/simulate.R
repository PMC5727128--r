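## Seeded synthetic-data generators: birth-death trees, allometric traits
## evolving under lambda-attenuated Brownian motion, two-species specimen
## tables, and sectioned 3-D cell fields for the stereology estimators.

#' Simulate a birth-death tree
#'
#' Draws a rooted ultrametric birth-death tree conditioned on the tip
#' count (so lineage extinction can never leave an empty tree) and labels
#' the tips `sp001`, `sp002`, ...
#'
#' @param n_tips Number of extant tips (>= 3).
#' @param birth,death Speciation and extinction rates (default 1 and 0, a
#'   pure-birth tree).
#' @param seed Optional integer seed.
#' @return A `phylo`.
#' @export
sim_bd_tree <- function(n_tips, birth = 1, death = 0, seed = NULL) {
  if (n_tips < 3) stop("need at least 3 tips", call. = FALSE)
  if (birth <= death) stop("birth rate must exceed death rate", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = death)
  tr$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tr
}

#' Simulate a set of birth-death trees on one tip set
#'
#' Independent draws from the same birth-death process, sharing tip
#' labels — a stand-in for a posterior sample of candidate phylogenies.
#'
#' @param n_trees Number of trees.
#' @inheritParams sim_bd_tree
#' @return A `multiPhylo`.
#' @export
sim_tree_set <- function(n_trees, n_tips, birth = 1, death = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(i) {
    sim_bd_tree(n_tips, birth = birth, death = death, seed = NULL)
  })
  class(trees) <- "multiPhylo"
  trees
}

#' Simulate allometric traits on a tree
#'
#' Generates a predictor by Brownian motion on the tree and a response
#' `intercept + slope * predictor + e` with residuals drawn jointly
#' multivariate normal with covariance `sigma2 * V(lambda)` — exactly the
#' error structure the PGLS model assumes, so that lambda recovery is a
#' meaningful test. An optional planted species receives an additive
#' log10-scale offset. Traits are exported on the raw (antilog) scale so a
#' downstream log10 step is exercised.
#'
#' Defaults emulate a strong brain-structure allometry: slope 0.9,
#' intercept -2.2 (log10 units), lambda 0.9, residual variance 0.05 on the
#' log10 scale, with the predictor spanning a few decades around 10^3.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param slope,intercept True regression parameters (log10 scale).
#' @param sigma2 Residual variance on the log10 scale (> 0).
#' @param lambda Phylogenetic signal of the residuals, in `[0, 1]`.
#' @param x_root Predictor root state (log10 scale; default 3).
#' @param x_sigma2 Brownian rate of the predictor per unit branch length.
#' @param outlier Optional tip label to plant as exceptional.
#' @param offset Additive log10 offset for the planted species (e.g.
#'   `5 * sqrt(sigma2)` for a +5-residual-SD outlier).
#' @param response,predictor Output column names.
#' @param seed Optional integer seed.
#' @return A data frame with columns `species`, predictor, response (raw
#'   scale), suitable for [fit_pgls()].
#' @export
sim_allometric_traits <- function(tree, slope = 0.9, intercept = -2.2,
                                  sigma2 = 0.05, lambda = 0.9,
                                  x_root = 3, x_sigma2 = 0.5,
                                  outlier = NULL, offset = 0,
                                  response = "response",
                                  predictor = "predictor", seed = NULL) {
  validate_phylo(tree)
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  if (!is.null(outlier) && !outlier %in% tree$tip.label) {
    stop("outlier species '", outlier, "' is not a tip", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  V1 <- ape::vcv.phylo(tree)
  x <- x_root + drop(MASS::mvrnorm(1, rep(0, n), x_sigma2 * V1))
  Vl <- V1 * lambda
  diag(Vl) <- diag(V1)
  e <- drop(MASS::mvrnorm(1, rep(0, n), sigma2 * Vl))
  y <- intercept + slope * x + e
  if (!is.null(outlier)) {
    y[match(outlier, rownames(V1))] <- y[match(outlier, rownames(V1))] + offset
  }
  out <- data.frame(species = rownames(V1))
  out[[predictor]] <- 10^x
  out[[response]] <- 10^y
  out
}

#' Simulate a two-species specimen table
#'
#' Draws per-specimen region volumes (and a cell count) around
#' species-level means with lognormal noise. The default means emulate a
#' published two-vulture contrast: the focal scent-foraging species has a
#' roughly 4-fold larger olfactory bulb, twice the mitral cells and a
#' ~20% smaller brain than its visually foraging relative. `ob_factor`
#' overrides the focal species' olfactory-bulb mean as a multiple of the
#' comparison species'.
#'
#' @param n_per_species Specimens per species (>= 2; default 3).
#' @param means_a,means_b Named numeric vectors of region means for the
#'   focal (`species_a`) and comparison (`species_b`) species.
#' @param cv Log-scale noise SD per region (default 0.06, comparable to
#'   within-species variation in small museum series).
#' @param ob_factor Optional olfactory-bulb enlargement factor for the
#'   focal species relative to the comparison species.
#' @param seed Optional integer seed.
#' @return A data frame: `specimen`, `species`, one column per region.
#' @export
sim_two_species_specimens <- function(n_per_species = 3,
                                      means_a = NULL, means_b = NULL,
                                      cv = 0.06, ob_factor = NULL,
                                      seed = NULL) {
  if (n_per_species < 2) stop("need at least 2 specimens per species", call. = FALSE)
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  if (is.null(means_a)) {
    means_a <- c(brain = 9212, telencephalon = 6154, optic_tectum = 223,
                 nucleus_rotundus = 14, entopallium = 100,
                 olfactory_bulb = 225, mitral_cells = 162565)
  }
  if (is.null(means_b)) {
    means_b <- c(brain = 11579, telencephalon = 8113, optic_tectum = 219,
                 nucleus_rotundus = 15.8, entopallium = 129,
                 olfactory_bulb = 54.3, mitral_cells = 86550)
  }
  if (!identical(sort(names(means_a)), sort(names(means_b)))) {
    stop("means_a and means_b must name the same regions", call. = FALSE)
  }
  if (!is.null(ob_factor)) {
    means_a["olfactory_bulb"] <- ob_factor * means_b["olfactory_bulb"]
  }
  if (!is.null(seed)) set.seed(seed)
  one_species <- function(label, means) {
    rows <- lapply(seq_len(n_per_species), function(i) {
      # lognormal noise with mean preserved: E[exp(N(-s^2/2, s))] = 1
      noise <- exp(stats::rnorm(length(means), -cv^2 / 2, cv))
      v <- as.list(means * noise)
      c(list(specimen = paste0(label, "_", i), species = label), v)
    })
    do.call(rbind, lapply(rows, as.data.frame))
  }
  out <- rbind(one_species("species_a", means_a),
               one_species("species_b", means_b[names(means_a)]))
  rownames(out) <- NULL
  out
}

#' Simulate a sectioned 3-D cell field
#'
#' Places `n_cells` points uniformly in a solid (a box, or the sphere
#' inscribed in it), cuts it into serial sections of the given thickness,
#' samples every `round(1/ssf)`-th section starting at a uniformly random
#' offset, and tallies the cells falling inside a systematically placed
#' grid of counting frames with a uniformly random phase — the
#' systematic-uniform-random design under which the fractionator
#' estimator is unbiased. The thickness sampling fraction, when below 1,
#' keeps only a random sub-slab of each section.
#'
#' @param n_cells True population size (>= 1).
#' @param design A [fractionator_design()].
#' @param box Field dimensions in micrometres, length 3 (x, y, z).
#' @param thickness Section thickness in micrometres (default 40).
#' @param shape `"box"` (default) or `"sphere"` (inscribed; gives a
#'   unimodal per-section profile).
#' @param seed Optional integer seed.
#' @return A list: `tallies` (per sampled section), `sections` (their
#'   indices), `n_sections`, `design`, `n_cells`. Feed `tallies` and
#'   `design` to [fractionator_estimate()].
#' @export
sim_cell_field <- function(n_cells, design, box = c(2000, 2000, 1600),
                           thickness = 40, shape = c("box", "sphere"),
                           seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(inherits(design, "fractionator_design"), length(box) == 3L)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (shape == "sphere") {
    r <- min(box) / 2
    ctr <- box / 2
    pts <- matrix(NA_real_, 0, 3)
    while (nrow(pts) < n_cells) {
      cand <- matrix(stats::runif(3 * n_cells, -r, r), ncol = 3)
      cand <- cand[rowSums(cand^2) <= r^2, , drop = FALSE]
      pts <- rbind(pts, cand)
    }
    pts <- sweep(pts[seq_len(n_cells), , drop = FALSE], 2, ctr, `+`)
  } else {
    pts <- cbind(stats::runif(n_cells, 0, box[1]),
                 stats::runif(n_cells, 0, box[2]),
                 stats::runif(n_cells, 0, box[3]))
  }
  n_sections <- ceiling(box[3] / thickness)
  k <- max(1L, as.integer(round(1 / design$ssf)))
  start <- if (k > 1L) sample.int(k, 1L) else 1L
  sampled <- seq.int(start, n_sections, by = k)
  h <- design$tsf * thickness
  # fresh grid phase on every sampled section, as fractionator software does
  tallies <- vapply(sampled, function(s) {
    z0 <- (s - 1) * thickness
    u <- stats::runif(1, 0, design$grid[1])
    v <- stats::runif(1, 0, design$grid[2])
    zoff <- if (design$tsf < 1) stats::runif(1, 0, thickness - h) else 0
    in_frame <- ((pts[, 1] - u) %% design$grid[1]) < design$frame[1] &
      ((pts[, 2] - v) %% design$grid[2]) < design$frame[2]
    sum(in_frame & pts[, 3] >= z0 + zoff & pts[, 3] < z0 + zoff + h)
  }, numeric(1))
  list(tallies = as.integer(tallies), sections = sampled,
       n_sections = n_sections, design = design, n_cells = n_cells)
}

#' Simulate serial profile areas of a known solid
#'
#' Sections a sphere or ellipsoid with planes a fixed distance apart at a
#' uniformly random offset (the condition for the Cavalieri estimator's
#' unbiasedness) and returns the exact profile areas.
#'
#' @param spacing Distance between section planes (mm).
#' @param semiaxes Ellipsoid semi-axes in mm, length 3; equal values give
#'   a sphere (default `c(2, 2, 2)`, true volume `(4/3)*pi*8`).
#' @param seed Optional integer seed.
#' @return A list: `areas` (mm^2), `spacing`, `true_volume` (mm^3).
#' @export
sim_profile_stack <- function(spacing, semiaxes = c(2, 2, 2), seed = NULL) {
  stopifnot(length(semiaxes) == 3L, all(semiaxes > 0), spacing > 0)
  if (!is.null(seed)) set.seed(seed)
  a <- semiaxes[1]; b <- semiaxes[2]; c_ <- semiaxes[3]
  off <- stats::runif(1, 0, spacing)
  z <- seq(-c_ - spacing + off, c_, by = spacing)
  areas <- pi * a * b * pmax(1 - z^2 / c_^2, 0)
  list(areas = areas, spacing = spacing,
       true_volume = 4 / 3 * pi * a * b * c_)
}
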