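# Shared fixtures and small oracles used across test files.

# three-tip tree with hand-computable shared path lengths
tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# star phylogeny: no shared internal paths, all tips equidistant
star_tree <- function(n = 8, depth = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(depth, n)
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  tr
}

# brute-force GLS by explicit covariance inversion (independent oracle)
brute_gls <- function(V, x, y) {
  X <- cbind(1, x)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  drop(beta)
}

# textbook OLS prediction interval (closed-form oracle)
ols_pi <- function(x, y, x0, level = 0.95) {
  n <- length(x)
  fit <- stats::lm(y ~ x)
  s2 <- sum(stats::residuals(fit)^2) / (n - 2)
  xb <- mean(x)
  sxx <- sum((x - xb)^2)
  se <- sqrt(s2 * (1 + 1 / n + (x0 - xb)^2 / sxx))
  yh <- stats::coef(fit)[1] + stats::coef(fit)[2] * x0
  tq <- stats::qt(1 - (1 - level) / 2, n - 2)
  cbind(fit = yh, lwr = yh - tq * se, upr = yh + tq * se)
}

# trait table with species exactly on a given line (log10 scale)
traits_on_line <- function(tree, slope = 0.8, intercept = -1, x = NULL) {
  n <- ape::Ntip(tree)
  if (is.null(x)) x <- seq(1, 4, length.out = n)
  data.frame(species = tree$tip.label,
             predictor = 10^x,
             response = 10^(intercept + slope * x))
}

# minimal posterior_predictive object for report-level tests
fake_pp <- function(draws, observed) {
  phyloallometry:::new_posterior_predictive(
    draws, observed, target_x = 0, level = 0.95, target = "sp001",
    response = "response", predictor = "predictor",
    iterations = length(draws), burn_in = 0, thinning = 1, seed = 1,
    n_trees = 1, acceptance = NA_real_)
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_path <- function() {
  system.file("cli", "phyloallometry.R", package = "phyloallometry")
}

run_cli <- function(args, dir = tempdir()) {
  out <- tempfile()
  err <- tempfile()
  status <- suppressWarnings(
    system2(rscript_bin(), c(cli_path(), args), stdout = out, stderr = err)
  )
  list(status = status, stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}
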