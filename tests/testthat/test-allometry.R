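test_that("fit_pgls equals brute-force GLS by explicit inversion", {
  set.seed(11)
  for (rep in 1:8) {
    tr <- sim_bd_tree(sample(5:10, 1))
    tt <- sim_allometric_traits(tr, slope = 0.9, lambda = 1, sigma2 = 0.05)
    f <- fit_pgls(tr, tt, "response", "predictor", lambda = 1)
    V <- ape::vcv.phylo(tr)[tt$species, tt$species]
    beta <- brute_gls(V, log10(tt$predictor), log10(tt$response))
    expect_lt(abs(f$intercept - beta[1]), 1e-8)
    expect_lt(abs(f$slope - beta[2]), 1e-8)
  }
})

test_that("lambda = 0 and star phylogenies reduce to ordinary least squares", {
  set.seed(12)
  tr <- sim_bd_tree(15)
  tt <- sim_allometric_traits(tr)
  f0 <- fit_pgls(tr, tt, "response", "predictor", lambda = 0)
  ols <- stats::lm(log10(tt$response) ~ log10(tt$predictor))
  expect_equal(unname(coef(f0)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(f0$r_squared, summary(ols)$r.squared, tolerance = 1e-10)
  # sigma2 is defined against V = height * I on an ultrametric tree at
  # lambda 0, so it is the OLS residual variance divided by tree height
  h <- max(diag(ape::vcv.phylo(tr)))
  expect_equal(f0$sigma2, sum(residuals(ols)^2) / (f0$n - 2) / h,
               tolerance = 1e-10)

  st <- star_tree(12)
  ts <- sim_allometric_traits(st, lambda = 0)
  for (lam in c(0.3, 1)) {
    fs <- fit_pgls(st, ts, "response", "predictor", lambda = lam)
    olss <- stats::lm(log10(ts$response) ~ log10(ts$predictor))
    expect_equal(unname(coef(fs)), unname(coef(olss)), tolerance = 1e-8)
  }
})

test_that("ML lambda and coefficients agree with an independent GLS oracle", {
  tr <- sim_bd_tree(60, seed = 21)
  tt <- sim_allometric_traits(tr, slope = 0.7, lambda = 0.7, seed = 22)
  f <- fit_pgls(tr, tt, "response", "predictor")
  d <- data.frame(x = log10(tt$predictor), y = log10(tt$response),
                  row.names = tt$species)
  g <- suppressWarnings(nlme::gls(
    y ~ x, data = d, method = "ML",
    correlation = ape::corPagel(0.5, tr, form = ~1)))
  lam_nlme <- coef(g$modelStruct$corStruct, unconstrained = FALSE)
  expect_equal(f$lambda, unname(lam_nlme), tolerance = 1e-3)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-5)
})

test_that("PGLS at lambda 1 matches independent-contrasts regression through the origin", {
  set.seed(31)
  for (rep in 1:5) {
    tr <- sim_bd_tree(20)
    tt <- sim_allometric_traits(tr, slope = 0.6, lambda = 1)
    f <- fit_pgls(tr, tt, "response", "predictor", lambda = 1)
    px <- ape::pic(log10(tt$predictor)[match(tr$tip.label, tt$species)], tr)
    py <- ape::pic(log10(tt$response)[match(tr$tip.label, tt$species)], tr)
    slope_pic <- unname(coef(stats::lm(py ~ px - 1)))
    expect_lt(abs(f$slope - slope_pic), 1e-6)
  }
})

test_that("rescaling raw traits by 10 shifts only the intercept", {
  tr <- sim_bd_tree(25, seed = 41)
  tt <- sim_allometric_traits(tr, seed = 42)
  f1 <- fit_pgls(tr, tt, "response", "predictor")
  tt2 <- tt
  tt2$response <- tt$response * 10
  tt2$predictor <- tt$predictor * 10
  f2 <- fit_pgls(tr, tt2, "response", "predictor")
  expect_equal(f2$slope, f1$slope, tolerance = 1e-6)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-4)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-6)
  expect_equal(f2$intercept, f1$intercept + 1 - f1$slope, tolerance = 1e-6)
})

test_that("profile_lambda brackets the ML estimate and is maximal there", {
  tr <- sim_bd_tree(40, seed = 51)
  tt <- sim_allometric_traits(tr, lambda = 0.8, seed = 52)
  f <- fit_pgls(tr, tt, "response", "predictor")
  prof <- profile_lambda(tr, tt, "response", "predictor",
                         grid = seq(0, 1, by = 0.05))
  best <- prof$lambda[which.max(prof$logLik)]
  expect_lte(abs(best - f$lambda), 0.05 + 1e-9)
  expect_true(all(f$logLik >= prof$logLik - 1e-6))
  expect_error(profile_lambda(tr, tt, "response", "predictor",
                              grid = numeric(0)), "empty")
})

test_that("simulated strong and destroyed phylogenetic signal push lambda to the bounds", {
  set.seed(61)
  hi <- 0
  lo <- 0
  for (rep in 1:10) {
    tr <- sim_bd_tree(64)
    tt <- sim_allometric_traits(tr, lambda = 1, sigma2 = 0.1)
    prof <- profile_lambda(tr, tt, "response", "predictor",
                           grid = seq(0, 1, by = 0.1))
    if (prof$lambda[which.max(prof$logLik)] >= 0.9) hi <- hi + 1
    shuf <- tt
    shuf$species <- sample(shuf$species)
    prof2 <- profile_lambda(tr, shuf, "response", "predictor",
                            grid = seq(0, 1, by = 0.1))
    if (prof2$lambda[which.max(prof2$logLik)] <= 0.3) lo <- lo + 1
  }
  expect_gte(hi, 7)
  expect_gte(lo, 7)
})

test_that("allometry_table is row-consistent with fit_pgls and handles edge cases", {
  tr <- sim_bd_tree(20, seed = 71)
  tt <- sim_allometric_traits(tr, seed = 72, response = "part",
                              predictor = "whole")
  tt$other <- tt$part * 2
  pairs <- data.frame(response = c("part", "other"),
                      predictor = c("whole", "whole"),
                      subtract_response = c(FALSE, FALSE))
  tab <- allometry_table(tr, tt, pairs)
  expect_equal(nrow(tab), 2)
  f1 <- fit_pgls(tr, tt, "part", "whole")
  expect_equal(tab$slope[1], f1$slope)
  expect_equal(tab$lambda[1], f1$lambda)

  empty <- allometry_table(tr, tt, pairs[0, ])
  expect_equal(nrow(empty), 0)

  # part-whole adjustment happens on the raw scale before the log
  pairs2 <- data.frame(response = "part", predictor = "whole",
                       subtract_response = TRUE)
  tab2 <- allometry_table(tr, tt, pairs2)
  tt$whole_minus_part <- tt$whole - tt$part
  f2 <- fit_pgls(tr, tt, "part", "whole_minus_part")
  expect_equal(tab2$slope, f2$slope)
  expect_equal(tab2$predictor, "whole_minus_part")

  # a failing row yields NA but the remaining rows still fit
  bad <- rbind(pairs, data.frame(response = "missing", predictor = "whole",
                                 subtract_response = FALSE))
  expect_warning(tab3 <- allometry_table(tr, tt, bad), "failed")
  expect_true(is.na(tab3$slope[3]))
  expect_false(anyNA(tab3$slope[1:2]))
})

test_that("validation errors name the offending species and columns", {
  tr <- sim_bd_tree(10, seed = 81)
  tt <- sim_allometric_traits(tr, seed = 82)
  tt$response[3] <- -1
  expect_error(fit_pgls(tr, tt, "response", "predictor"), tt$species[3])
  tt2 <- sim_allometric_traits(tr, seed = 83)
  tt2$species[1] <- "not_a_tip"
  expect_error(fit_pgls(tr, tt2, "response", "predictor"),
               "mismatch.*not_a_tip")
  expect_message(
    f <- fit_pgls(tr, tt2, "response", "predictor", match = "intersect"),
    "dropping")
  expect_equal(f$n, 9)
  tt3 <- rbind(tt2, tt2[2, ])
  expect_error(fit_pgls(tr, tt3, "response", "predictor"), "duplicate")
})

test_that("summary and print expose slope inference", {
  tr <- sim_bd_tree(20, seed = 91)
  tt <- sim_allometric_traits(tr, seed = 92)
  f <- fit_pgls(tr, tt, "response", "predictor")
  s <- summary(f)
  expect_named(s$coefficients,
               c("estimate", "std_error", "t_value", "p_value"))
  expect_equal(s$coefficients["slope", "estimate"], f$slope)
  expect_output(print(f), "slope")
})
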