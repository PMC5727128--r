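small_setup <- function(seed = 1, n_tips = 15, n_trees = 4, ...) {
  trees <- sim_tree_set(n_trees, n_tips, seed = seed)
  traits <- sim_allometric_traits(trees[[1]], seed = seed + 1000, ...)
  list(trees = trees, traits = traits)
}

test_that("retained draw count is floor((iterations - burn_in) / thinning)", {
  s <- small_setup(2)
  cases <- list(c(1100, 100, 100), c(1100, 100, 37), c(505, 5, 50))
  for (cs in cases) {
    pp <- posterior_predict_phylo(s$trees, s$traits, "sp001", "response",
                                  "predictor", iterations = cs[1],
                                  burn_in = cs[2], thinning = cs[3], seed = 4)
    expect_length(pp$draws, floor((cs[1] - cs[2]) / cs[3]))
    expect_equal(pp$settings$retained, length(pp$draws))
  }
  expect_error(posterior_predict_phylo(s$trees, s$traits, "sp001", "response",
                                       "predictor", iterations = 50,
                                       burn_in = 100), "exceed")
})

test_that("identical inputs and seed give bit-identical draws", {
  s <- small_setup(3)
  run <- function() posterior_predict_phylo(
    s$trees, s$traits, "sp002", "response", "predictor",
    iterations = 600, burn_in = 100, thinning = 10, seed = 99)
  expect_identical(run()$draws, run()$draws)
})

test_that("zero residual variance with fixed lambda collapses draws onto the conditioned line", {
  s <- small_setup(4, n_trees = 1)
  pp <- posterior_predict_phylo(s$trees, s$traits, "sp003", "response",
                                "predictor", iterations = 300, burn_in = 100,
                                thinning = 10, seed = 5,
                                fixed = list(sigma2 = 0, lambda = 1))
  expect_lt(max(pp$draws) - min(pp$draws), 1e-12)
  # the collapsed value is the position-aware GLS prediction for the target
  nt <- s$traits[s$traits$species != "sp003", ]
  tr <- s$trees[[1]]
  f <- fit_pgls(ape::drop.tip(tr, "sp003"), nt, "response", "predictor",
                lambda = 1)
  V <- ape::vcv.phylo(tr)
  b <- prediction_band(f, x_grid = log10(
    s$traits$predictor[s$traits$species == "sp003"]),
    target_covariance = V["sp003", f$species],
    target_variance = V["sp003", "sp003"])
  expect_equal(unname(pp$draws[1]), b$fit, tolerance = 1e-8)
  expect_error(
    posterior_predict_phylo(s$trees, s$traits, "sp003", "response",
                            "predictor", fixed = list(sigma2 = 0)),
    "fixed lambda")
})

test_that("posterior slope mean matches the PGLS point estimate within MC error", {
  tr <- sim_bd_tree(40, seed = 17)
  tt <- sim_allometric_traits(tr, slope = 0.85, lambda = 0.9, seed = 18)
  pp <- posterior_predict_phylo(list(tr), tt, "sp001", "response", "predictor",
                                iterations = 8100, burn_in = 100,
                                thinning = 8, seed = 19)
  nt <- tt[tt$species != "sp001", ]
  f <- fit_pgls(ape::drop.tip(tr, "sp001"), nt, "response", "predictor")
  sl <- pp$param_draws[, "slope"]
  n_eff <- max(10, length(sl) / 10)  # conservative for autocorrelation
  expect_lt(abs(mean(sl) - f$slope), 2 * stats::sd(sl) / sqrt(n_eff) +
              2 * stats::sd(sl) / sqrt(length(sl)))
  expect_lt(abs(mean(sl) - f$slope), 3 * stats::sd(sl))
})

test_that("target absent from a tree or table is a validation error", {
  s <- small_setup(6)
  expect_error(posterior_predict_phylo(s$trees, s$traits, "nope", "response",
                                       "predictor"), "not in trait table")
  tr2 <- s$trees
  tr2[[2]] <- ape::drop.tip(tr2[[2]], "sp001")
  expect_error(posterior_predict_phylo(tr2, s$traits, "sp001", "response",
                                       "predictor", iterations = 200,
                                       burn_in = 10, thinning = 10),
               "tree 2")
})

test_that("removing the target's closest relatives does not shrink the predictive interval", {
  # target sp001 nested in a tight clade; dropping that clade loses the
  # strongest conditioning information
  tr <- ape::read.tree(text = paste0(
    "(((sp001:0.05,sp002:0.05):0.05,(sp003:0.05,sp004:0.05):0.05):0.9,",
    "((sp005:0.4,sp006:0.4):0.3,(sp007:0.4,(sp008:0.2,sp009:0.2):0.2):0.3):0.3);"))
  width <- function(traits, trees, seed) diff(posterior_predict_phylo(
    trees, traits, "sp001", "response", "predictor",
    iterations = 4100, burn_in = 100, thinning = 8, seed = seed)$ci)
  pruned_tree <- ape::drop.tip(tr, c("sp002", "sp003", "sp004"))
  w_full <- w_pruned <- numeric(5)
  for (s in 1:5) {
    tt <- sim_allometric_traits(tr, lambda = 1, sigma2 = 0.05, seed = 76 + s)
    w_full[s] <- width(tt, list(tr), 780 + s)
    w_pruned[s] <- width(tt[!tt$species %in% c("sp002", "sp003", "sp004"), ],
                         list(pruned_tree), 880 + s)
  }
  # averaged over replicates, losing the conditioning information cannot
  # tighten the predictive interval (small allowance for MC noise)
  expect_gte(mean(w_pruned), mean(w_full) * 0.97)
})

test_that("exceptionality verdicts follow the credible interval", {
  set.seed(30)
  draws <- stats::rnorm(1001)
  pp <- fake_pp(draws, observed = stats::median(draws))
  rep <- exceptionality_report(pp)
  expect_equal(rep$verdict, "within")
  expect_equal(rep$percentile, 50, tolerance = 0.2)

  pp2 <- fake_pp(draws, observed = max(draws) + 1)
  rep2 <- exceptionality_report(pp2)
  expect_equal(rep2$verdict, "above")
  expect_equal(rep2$percentile, 100)

  pp3 <- fake_pp(draws, observed = min(draws) - 1)
  expect_equal(exceptionality_report(pp3)$verdict, "below")

  expect_error(exceptionality_report(fake_pp(stats::rnorm(50), 0)),
               "100 retained draws")
})

test_that("a planted +4 SD outlier is called above its credible interval", {
  set.seed(40)
  hits <- 0
  for (rep in 1:10) {
    trees <- sim_tree_set(3, 15)
    h <- max(diag(ape::vcv.phylo(trees[[1]])))
    tt <- sim_allometric_traits(trees[[1]], sigma2 = 0.05, lambda = 0.5,
                                outlier = "sp007",
                                offset = 4 * sqrt(0.05 * h))
    pp <- posterior_predict_phylo(trees, tt, "sp007", "response", "predictor",
                                  iterations = 1100, burn_in = 100,
                                  thinning = 10, seed = 40 + rep)
    if (exceptionality_report(pp)$verdict == "above") hits <- hits + 1
  }
  expect_gte(hits, 9)
})
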