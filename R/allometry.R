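## Phylogenetic generalized least squares on log10-transformed traits, with
## Pagel's lambda profiled out by maximum likelihood.

#' Fit a log-log allometric regression by PGLS
#'
#' Regresses `log10(response)` on `log10(predictor)` under a Gaussian model
#' whose error covariance is the phylogenetic covariance of `tree` with
#' off-diagonals scaled by Pagel's lambda. With `lambda = "ML"` (default)
#' lambda is estimated by maximising the profile log-likelihood over
#' `[0, 1]` (coarse grid scan followed by bounded optimisation, tolerance
#' 1e-6). At `lambda = 0`, or on a star phylogeny, the fit coincides with
#' ordinary least squares.
#'
#' The reported `sigma2` is the GLS residual quadratic form divided by the
#' residual degrees of freedom (n - 2). `r_squared` is
#' `1 - RSS_GLS / TSS_GLS`, where TSS is taken about the GLS-estimated
#' phylogenetic mean, so it is comparable across lambda values.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param traits A data frame with a species column and numeric trait
#'   columns; trait values entering the log10 transform must be strictly
#'   positive. Species labels are matched to tip labels exactly
#'   (case-sensitive) after trimming surrounding whitespace.
#' @param response,predictor Names of the response and predictor trait
#'   columns (raw scale; the log10 transform is applied internally).
#' @param lambda `"ML"` or a fixed value in `[0, 1]`.
#' @param method Likelihood flavour used for the lambda search: `"ML"`
#'   (default) or `"REML"`.
#' @param species_col Name of the species column (default `"species"`).
#' @param match `"error"` (default) fails if the tree and table disagree on
#'   species; `"intersect"` drops the difference with a message.
#' @return An object of class `pgls_fit`; see [coef.pgls_fit()],
#'   [summary.pgls_fit()].
#' @examples
#' tr <- sim_bd_tree(30, seed = 1)
#' tt <- sim_allometric_traits(tr, slope = 0.7, seed = 2)
#' fit <- fit_pgls(tr, tt, "response", "predictor")
#' coef(fit)
#' @export
fit_pgls <- function(tree, traits, response, predictor,
                     lambda = "ML", method = c("ML", "REML"),
                     species_col = "species", match = c("error", "intersect")) {
  method <- match.arg(method)
  match <- match.arg(match)
  d <- align_traits(tree, traits, c(response, predictor), species_col, match)
  x <- log_trait(d$data[[predictor]], d$data[[species_col]], predictor)
  y <- log_trait(d$data[[response]], d$data[[species_col]], response)
  n <- length(y)
  if (n < 4L) stop("need at least 4 species shared by tree and table", call. = FALSE)
  X <- cbind(intercept = 1, slope = x)
  V1 <- ape::vcv.phylo(d$tree)

  est_lambda <- identical(lambda, "ML")
  if (est_lambda) {
    lam <- optimize_lambda(V1, X, y, method)
  } else {
    if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1) {
      stop("lambda must be \"ML\" or a single value in [0, 1]", call. = FALSE)
    }
    lam <- lambda
  }

  Vl <- V1 * lam
  diag(Vl) <- diag(V1)
  core <- gls_core(Vl, X, y, lam)

  # TSS about the GLS phylogenetic mean (intercept-only GLS fit)
  null <- gls_core(Vl, matrix(1, n, 1), y, lam)
  r2 <- if (null$rss > 0) max(0, min(1, 1 - core$rss / null$rss)) else NA_real_

  structure(list(
    slope = unname(core$beta[2]),
    intercept = unname(core$beta[1]),
    lambda = lam,
    lambda_estimated = est_lambda,
    method = method,
    r_squared = r2,
    sigma2 = core$rss / (n - 2L),
    n = n,
    residual_df = n - 2L,
    logLik = profile_loglik(V1, X, y, lam, "ML"),
    response = response,
    predictor = predictor,
    species = d$data[[species_col]],
    x = x, y = y,
    fitted = drop(X %*% core$beta),
    V = Vl,
    chol_V = core$R,
    coef_vcov = core$rss / (n - 2L) * core$XtViX_inv,
    tree_height = max(diag(V1)),
    dropped = d$dropped
  ), class = "pgls_fit")
}

## Weighted (GLS) regression through a Cholesky whitening of V.
gls_core <- function(V, X, y, lam) {
  R <- tryCatch(chol(V), error = function(e) {
    stop(sprintf("phylogenetic covariance is singular at lambda = %.6g", lam),
         call. = FALSE)
  })
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  xtx <- crossprod(Xw)
  beta <- drop(solve(xtx, crossprod(Xw, yw)))
  resid <- yw - Xw %*% beta
  list(beta = beta, rss = drop(crossprod(resid)), R = R,
       XtViX_inv = solve(xtx), logdetV = 2 * sum(log(diag(R))))
}

## Profile log-likelihood in lambda (beta, sigma2 profiled out).
profile_loglik <- function(V1, X, y, lam, method) {
  Vl <- V1 * lam
  diag(Vl) <- diag(V1)
  core <- gls_core(Vl, X, y, lam)
  n <- length(y)
  p <- ncol(X)
  if (method == "REML") {
    s2 <- core$rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + core$logdetV +
              determinant(crossprod(backsolve(core$R, X, transpose = TRUE)),
                          logarithm = TRUE)$modulus[1])
  } else {
    s2 <- core$rss / n
    -0.5 * (n * (log(2 * pi * s2) + 1) + core$logdetV)
  }
}

## Grid scan + bounded local optimisation; the profile can be multimodal.
optimize_lambda <- function(V1, X, y, method, grid_by = 0.05, tol = 1e-6) {
  grid <- seq(0, 1, by = grid_by)
  ll <- vapply(grid, function(l) profile_loglik(V1, X, y, l, method), numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(l) profile_loglik(V1, X, y, l, method),
                         lower = lo, upper = hi, maximum = TRUE, tol = tol)
  # keep the better of the grid point and the local optimum
  if (opt$objective >= ll[i]) opt$maximum else grid[i]
}

#' Profile log-likelihood of Pagel's lambda on a grid
#'
#' @inheritParams fit_pgls
#' @param grid Numeric vector of lambda values in `[0, 1]`.
#' @return A data frame with columns `lambda` and `logLik`.
#' @export
profile_lambda <- function(tree, traits, response, predictor,
                           grid = seq(0, 1, by = 0.05),
                           method = c("ML", "REML"),
                           species_col = "species") {
  method <- match.arg(method)
  if (!length(grid)) stop("lambda grid is empty", call. = FALSE)
  if (any(grid < 0 | grid > 1)) stop("grid values must lie in [0, 1]", call. = FALSE)
  d <- align_traits(tree, traits, c(response, predictor), species_col, "error")
  x <- log_trait(d$data[[predictor]], d$data[[species_col]], predictor)
  y <- log_trait(d$data[[response]], d$data[[species_col]], response)
  X <- cbind(1, x)
  V1 <- ape::vcv.phylo(d$tree)
  data.frame(
    lambda = grid,
    logLik = vapply(grid, function(l) profile_loglik(V1, X, y, l, method),
                    numeric(1))
  )
}

#' Table of allometric fits for several trait pairs
#'
#' Fits one PGLS per (response, predictor) pair. When `subtract_response`
#' is set for a pair, the response volume is subtracted from the predictor
#' on the raw scale before the log transform (e.g. regressing a part
#' against "whole minus part" to avoid part-whole correlation). A pair that
#' fails to fit yields an `NA` row with a warning; remaining pairs are
#' still fitted.
#'
#' @inheritParams fit_pgls
#' @param pairs A data frame with character columns `response` and
#'   `predictor`, and optionally a logical `subtract_response`.
#' @return A data frame with one row per pair (columns `response`,
#'   `predictor`, `slope`, `intercept`, `lambda`, `r_squared`, `n`); the
#'   full `pgls_fit` objects are attached as attribute `"fits"`.
#' @export
allometry_table <- function(tree, traits, pairs, lambda = "ML",
                            method = c("ML", "REML"), species_col = "species") {
  method <- match.arg(method)
  stopifnot(is.data.frame(pairs))
  if (!all(c("response", "predictor") %in% names(pairs))) {
    stop("pairs must have 'response' and 'predictor' columns", call. = FALSE)
  }
  if (is.null(pairs$subtract_response)) pairs$subtract_response <- FALSE
  out <- data.frame(
    response = character(0), predictor = character(0), slope = numeric(0),
    intercept = numeric(0), lambda = numeric(0), r_squared = numeric(0),
    n = integer(0)
  )
  fits <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    resp <- pairs$response[i]
    pred <- pairs$predictor[i]
    tt <- traits
    pred_name <- pred
    if (isTRUE(pairs$subtract_response[i])) {
      pred_name <- paste0(pred, "_minus_", resp)
      tt[[pred_name]] <- tt[[pred]] - tt[[resp]]
    }
    row <- tryCatch({
      f <- fit_pgls(tree, tt, resp, pred_name, lambda = lambda,
                    method = method, species_col = species_col)
      fits[[i]] <- f
      data.frame(response = resp, predictor = pred_name, slope = f$slope,
                 intercept = f$intercept, lambda = f$lambda,
                 r_squared = f$r_squared, n = f$n)
    }, error = function(e) {
      warning("fit for ", resp, " ~ ", pred_name, " failed: ",
              conditionMessage(e), call. = FALSE)
      data.frame(response = resp, predictor = pred_name, slope = NA_real_,
                 intercept = NA_real_, lambda = NA_real_,
                 r_squared = NA_real_, n = NA_integer_)
    })
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

## -- alignment helpers -------------------------------------------------

## Match trait rows to tree tips (exact, case-sensitive, whitespace-trimmed)
## and return both pruned/reordered to a common species order.
align_traits <- function(tree, traits, needed, species_col, match) {
  validate_phylo(tree)
  if (!is.data.frame(traits)) stop("traits must be a data frame", call. = FALSE)
  if (!species_col %in% names(traits)) {
    stop("traits has no '", species_col, "' column", call. = FALSE)
  }
  miss <- setdiff(needed, names(traits))
  if (length(miss)) {
    stop("trait column(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  traits[[species_col]] <- trimws(traits[[species_col]])
  tree$tip.label <- trimws(tree$tip.label)
  dup <- unique(traits[[species_col]][duplicated(traits[[species_col]])])
  if (length(dup)) {
    stop("duplicate species row(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  in_tree <- tree$tip.label
  in_tab <- traits[[species_col]]
  only_tree <- setdiff(in_tree, in_tab)
  only_tab <- setdiff(in_tab, in_tree)
  dropped <- c(only_tree, only_tab)
  if (length(dropped)) {
    if (match == "error") {
      stop("species mismatch between tree and table; only in tree: [",
           paste(only_tree, collapse = ", "), "]; only in table: [",
           paste(only_tab, collapse = ", "), "]", call. = FALSE)
    }
    keep <- intersect(in_tree, in_tab)
    if (length(keep) < 3L) stop("fewer than 3 species in common", call. = FALSE)
    message("dropping ", length(dropped), " unmatched species")
    tree <- ape::keep.tip(tree, keep)
    traits <- traits[in_tab %in% keep, , drop = FALSE]
  }
  traits <- traits[match(tree$tip.label, traits[[species_col]]), , drop = FALSE]
  list(tree = tree, data = traits, dropped = dropped)
}

## log10 with a validation error naming offending species.
log_trait <- function(v, species, name) {
  if (!is.numeric(v)) stop("trait '", name, "' is not numeric", call. = FALSE)
  bad <- species[!is.finite(v) | v <= 0]
  if (length(bad)) {
    stop("trait '", name, "' must be positive and finite; offending species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  log10(v)
}

## -- S3 methods --------------------------------------------------------

#' @export
coef.pgls_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS allometric fit: log10(", x$response, ") ~ log10(", x$predictor,
      ")\n", sep = "")
  cat(sprintf("  slope %.4f, intercept %.4f, lambda %.3f%s, r^2 %.4f, n %d\n",
              x$slope, x$intercept, x$lambda,
              if (x$lambda_estimated) " (ML)" else " (fixed)",
              x$r_squared, x$n))
  invisible(x)
}

#' @export
summary.pgls_fit <- function(object, ...) {
  se <- sqrt(diag(object$coef_vcov))
  tval <- c(object$intercept, object$slope) / se
  out <- data.frame(
    estimate = c(object$intercept, object$slope),
    std_error = se,
    t_value = tval,
    p_value = 2 * stats::pt(-abs(tval), object$residual_df),
    row.names = c("intercept", "slope")
  )
  structure(list(coefficients = out, lambda = object$lambda,
                 r_squared = object$r_squared, sigma2 = object$sigma2,
                 n = object$n, logLik = object$logLik, fit = object),
            class = "summary.pgls_fit")
}

#' @export
print.summary.pgls_fit <- function(x, ...) {
  print(x$fit)
  print(x$coefficients, digits = 4)
  cat(sprintf("residual sigma^2 (log10 scale): %.5f; logLik %.3f\n",
              x$sigma2, x$logLik))
  invisible(x)
}
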