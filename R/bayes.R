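## Bayesian posterior-predictive test for one focal species, excluded from
## the regression: Metropolis-Hastings over (intercept, slope, sigma2,
## lambda) with each iteration conditioning on a tree drawn at random from
## a supplied set, and one conditional-normal predictive draw of the focal
## species' trait per retained iteration.

#' Posterior-predictive distribution for a left-out focal species
#'
#' Fits the log10-scale allometric regression to all species except
#' `target` by MCMC and, at every retained iteration, draws the target's
#' response from the conditional normal implied by its phylogenetic
#' position (mean and variance conditioned on the non-target species under
#' that iteration's parameters and tree). Each iteration uses a tree drawn
#' uniformly at random (seeded) from `trees`, so topological uncertainty
#' propagates into the predictive distribution.
#'
#' Priors are flat on the regression coefficients and on `log(sigma2)`,
#' and uniform on `lambda` over `[0, 1]`. Proposals are Gaussian random
#' walks (reflected at the `lambda` bounds) whose scales are adapted
#' during burn-in toward a 20-45% acceptance rate; the realised rate is
#' reported in the result. The number of retained draws is
#' `floor((iterations - burn_in) / thinning)`; the defaults retain exactly
#' 1,000.
#'
#' @param trees A `multiPhylo` or list of rooted trees, every one
#'   containing `target` and all non-target species.
#' @param traits Trait data frame (raw scale; log10 applied internally).
#' @param target Focal species label, excluded from the regression.
#' @param response,predictor Trait column names.
#' @param iterations,burn_in,thinning MCMC schedule (defaults 100100, 100,
#'   100).
#' @param seed Integer seed fixing all randomness (tree choice, proposals,
#'   predictive draws).
#' @param species_col Species column name.
#' @param fixed Optional named list pinning `lambda` and/or `sigma2` to a
#'   constant instead of sampling it. `sigma2 = 0` (with a fixed `lambda`)
#'   collapses every draw to the phylogenetically conditioned regression
#'   value — a degenerate, noise-free predictive.
#' @param level Credible level for the reported interval (default 0.95).
#' @return A `posterior_predictive` object: `draws` (log10 scale),
#'   `observed`, `percentile`, `ci`, `settings`, `acceptance`, `n_trees`,
#'   and `param_draws` (retained intercept/slope/sigma2/lambda values).
#' @seealso [exceptionality_report()]
#' @export
posterior_predict_phylo <- function(trees, traits, target, response, predictor,
                                    iterations = 100100L, burn_in = 100L,
                                    thinning = 100L, seed = 1L,
                                    species_col = "species",
                                    fixed = list(), level = 0.95) {
  trees <- as_tree_set(trees)
  if (iterations <= burn_in) stop("iterations must exceed burn_in", call. = FALSE)
  if (thinning < 1L) stop("thinning must be >= 1", call. = FALSE)
  if (!is.data.frame(traits) || !species_col %in% names(traits)) {
    stop("traits must be a data frame with a '", species_col, "' column",
         call. = FALSE)
  }
  traits[[species_col]] <- trimws(traits[[species_col]])
  if (!target %in% traits[[species_col]]) {
    stop("target species '", target, "' not in trait table", call. = FALSE)
  }
  nt <- traits[traits[[species_col]] != target, , drop = FALSE]
  sp <- nt[[species_col]]
  if (length(sp) < 4L) stop("need at least 4 non-target species", call. = FALSE)
  x <- log_trait(nt[[predictor]], sp, predictor)
  y <- log_trait(nt[[response]], sp, response)
  trow <- traits[traits[[species_col]] == target, , drop = FALSE]
  xt <- log_trait(trow[[predictor]], target, predictor)
  yt <- log_trait(trow[[response]], target, response)
  n <- length(y)
  X <- cbind(1, x)

  # per-tree covariance blocks in a fixed species order
  pre <- lapply(seq_along(trees), function(k) {
    tr <- trees[[k]]
    tr$tip.label <- trimws(tr$tip.label)
    if (!target %in% tr$tip.label) {
      stop("target species '", target, "' absent from tree ", k, call. = FALSE)
    }
    missing <- setdiff(sp, tr$tip.label)
    if (length(missing)) {
      stop("tree ", k, " is missing species: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    tr <- ape::keep.tip(tr, c(sp, target))
    V <- ape::vcv.phylo(tr)
    ord <- match(sp, rownames(V))
    list(V = V[ord, ord, drop = FALSE],
         ct = V[ord, match(target, rownames(V))],
         vtt = V[match(target, rownames(V)), match(target, rownames(V))])
  })
  K <- length(pre)

  fix_lam <- fixed$lambda
  fix_s2 <- fixed$sigma2
  if (!is.null(fix_s2) && fix_s2 == 0 && is.null(fix_lam)) {
    stop("sigma2 = 0 requires a fixed lambda", call. = FALSE)
  }

  n_keep <- as.integer(floor((iterations - burn_in) / thinning))
  set.seed(seed)

  ## degenerate noise-free case: draws collapse to the conditioned line
  if (!is.null(fix_s2) && fix_s2 == 0) {
    draws <- vapply(seq_len(n_keep), function(j) {
      p <- pre[[sample.int(K, 1L)]]
      Vl <- lam_scale(p$V, fix_lam)
      R <- chol(Vl)
      beta <- gls_core(Vl, X, y, fix_lam)$beta
      wv <- backsolve(R, fix_lam * p$ct, transpose = TRUE)
      wr <- backsolve(R, y - drop(X %*% beta), transpose = TRUE)
      beta[1] + beta[2] * xt + sum(wv * wr)
    }, numeric(1))
    return(new_posterior_predictive(draws, yt, xt, level, target, response,
                                    predictor, iterations, burn_in, thinning,
                                    seed, K, acceptance = NA_real_))
  }

  ## initial state from OLS on the non-target species
  ols <- stats::lm.fit(X, y)
  theta <- c(b0 = unname(ols$coefficients[1]), b1 = unname(ols$coefficients[2]),
             logs2 = log(max(sum(ols$residuals^2) / (n - 2), 1e-8)),
             lam = if (is.null(fix_lam)) 0.5 else fix_lam)
  ols_se <- sqrt(diag(chol2inv(chol(crossprod(X))) *
                        sum(ols$residuals^2) / (n - 2)))
  scales <- c(ols_se[1], ols_se[2], 0.4, 0.15)
  sample_lam <- is.null(fix_lam)
  if (!is.null(fix_s2)) theta["logs2"] <- log(fix_s2)

  loglik <- function(th, p) {
    Vl <- lam_scale(p$V, th[4])
    R <- tryCatch(chol(Vl), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    r <- y - th[1] - th[2] * x
    wr <- backsolve(R, r, transpose = TRUE)
    s2 <- exp(th[3])
    -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(R))) + sum(wr^2) / s2)
  }

  draws <- numeric(n_keep)
  params <- matrix(NA_real_, n_keep, 4L,
                   dimnames = list(NULL, c("intercept", "slope", "sigma2", "lambda")))
  kept <- 0L
  acc <- 0L
  acc_win <- 0L
  win <- 0L
  for (i in seq_len(iterations)) {
    p <- pre[[if (K > 1L) sample.int(K, 1L) else 1L]]
    ll_cur <- loglik(theta, p)
    prop <- theta
    prop[1] <- prop[1] + stats::rnorm(1, 0, scales[1])
    prop[2] <- prop[2] + stats::rnorm(1, 0, scales[2])
    if (is.null(fix_s2)) prop[3] <- prop[3] + stats::rnorm(1, 0, scales[3])
    if (sample_lam) {
      prop[4] <- reflect01(prop[4] + stats::rnorm(1, 0, scales[4]))
    }
    ll_prop <- loglik(prop, p)
    if (log(stats::runif(1)) < ll_prop - ll_cur) {
      theta <- prop
      acc <- acc + 1L
      acc_win <- acc_win + 1L
    }
    win <- win + 1L
    if (i <= burn_in && win == 25L) {
      rate <- acc_win / win
      if (rate > 0.45) scales <- scales * 1.4
      if (rate < 0.20) scales <- scales * 0.7
      acc_win <- 0L
      win <- 0L
    }
    if (i > burn_in && (i - burn_in) %% thinning == 0L && kept < n_keep) {
      kept <- kept + 1L
      lam <- theta[4]
      s2 <- exp(theta[3])
      Vl <- lam_scale(p$V, lam)
      R <- chol(Vl)
      wv <- backsolve(R, lam * p$ct, transpose = TRUE)
      wr <- backsolve(R, y - theta[1] - theta[2] * x, transpose = TRUE)
      mu <- theta[1] + theta[2] * xt + sum(wv * wr)
      v <- s2 * max(p$vtt - sum(wv^2), 0)
      draws[kept] <- stats::rnorm(1, mu, sqrt(v))
      params[kept, ] <- c(theta[1], theta[2], s2, lam)
    }
  }
  out <- new_posterior_predictive(draws, yt, xt, level, target, response,
                                  predictor, iterations, burn_in, thinning,
                                  seed, K, acceptance = acc / iterations)
  out$param_draws <- params
  out
}

lam_scale <- function(V, lam) {
  Vl <- V * lam
  diag(Vl) <- diag(V)
  Vl
}

reflect01 <- function(v) {
  v <- v %% 2
  if (v > 1) 2 - v else v
}

new_posterior_predictive <- function(draws, observed, target_x, level, target,
                                     response, predictor, iterations, burn_in,
                                     thinning, seed, n_trees, acceptance) {
  a <- (1 - level) / 2
  structure(list(
    draws = draws,
    observed = observed,
    target_x = target_x,
    percentile = draw_percentile(draws, observed),
    ci = stats::quantile(draws, c(a, 1 - a), names = FALSE, type = 7),
    level = level,
    target = target,
    response = response,
    predictor = predictor,
    settings = list(iterations = iterations, burn_in = burn_in,
                    thinning = thinning, seed = seed,
                    retained = length(draws)),
    acceptance = acceptance,
    n_trees = n_trees
  ), class = "posterior_predictive")
}

## empirical percentile of the observed value within the draws, in [0, 100]
draw_percentile <- function(draws, observed) {
  100 * (mean(draws < observed) + 0.5 * mean(draws == observed))
}

#' Exceptionality verdict from a posterior predictive
#'
#' Compares the observed trait value against the central credible interval
#' of the predictive draws: `"above"` if it exceeds the upper bound,
#' `"below"` if under the lower bound, `"within"` otherwise, together with
#' the observed value's empirical percentile among the draws.
#'
#' @param pp A [posterior_predict_phylo()] result.
#' @param level Credible level (default 0.95).
#' @return A list (class `exceptionality_report`) with `verdict`,
#'   `percentile`, `ci`, `observed`, `level` and the MCMC settings.
#' @export
exceptionality_report <- function(pp, level = 0.95) {
  stopifnot(inherits(pp, "posterior_predictive"))
  if (length(pp$draws) < 100L) {
    stop("need at least 100 retained draws for a stable verdict", call. = FALSE)
  }
  a <- (1 - level) / 2
  ci <- stats::quantile(pp$draws, c(a, 1 - a), names = FALSE, type = 7)
  verdict <- if (pp$observed > ci[2]) "above"
             else if (pp$observed < ci[1]) "below"
             else "within"
  structure(list(
    target = pp$target,
    verdict = verdict,
    percentile = draw_percentile(pp$draws, pp$observed),
    ci = ci,
    level = level,
    observed = pp$observed,
    settings = pp$settings
  ), class = "exceptionality_report")
}

#' @export
print.posterior_predictive <- function(x, ...) {
  cat("Posterior predictive for '", x$target, "' (log10 ", x$response,
      " | ", x$predictor, ")\n", sep = "")
  cat(sprintf("  %d retained draws over %d trees; observed %.4f at percentile %.1f\n",
              length(x$draws), x$n_trees, x$observed, x$percentile))
  cat(sprintf("  %.0f%% credible interval: [%.4f, %.4f]\n",
              100 * x$level, x$ci[1], x$ci[2]))
  invisible(x)
}

#' @export
print.exceptionality_report <- function(x, ...) {
  cat(sprintf("'%s' is %s the %.0f%% credible interval [%.4f, %.4f]; observed %.4f (percentile %.1f)\n",
              x$target, x$verdict, 100 * x$level, x$ci[1], x$ci[2],
              x$observed, x$percentile))
  invisible(x)
}
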