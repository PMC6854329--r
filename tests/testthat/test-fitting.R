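# GLS/REML engine: exact reductions (OLS, noise-free interpolation),
# agreement with an independent GLS implementation, likelihood ordering,
# random-pairwise boundary behavior.

test_that("noise-free data are interpolated exactly", {
  set.seed(21)
  spec <- di_spec("M2", "P11")
  theta <- c(default_beta(the_pool), 30, 93.6, 2347.6)  # one block contrast
  ex <- exact_response(design2, spec, theta)
  g <- variance_groups(ex$data, "mono_vs_mixture", the_pool)
  fit <- fit_gls(ex$data$y, ex$mm, g)
  expect_lt(max(abs(fit$coefficients - theta)), 1e-8)
})

test_that("homoscedastic GLS equals an independent OLS solve", {
  set.seed(22)
  dat <- planted_frame(design2)
  mm <- build_design_matrix(dat, di_spec("M3"), the_pool)
  y <- drop(mm$X %*% rnorm(ncol(mm$X), 100, 50)) + rnorm(nrow(mm$X), 0, 40)
  fit <- fit_gls(y, mm, factor(rep("all", length(y))))
  # oracle: direct normal-equations solve
  ols <- solve(crossprod(mm$X), crossprod(mm$X, y))
  expect_lt(max(abs(fit$coefficients - drop(ols))), 1e-10)
  # closed-form Gaussian loglik at the ML variance
  n <- length(y); rss <- sum((y - mm$X %*% ols)^2)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  expect_equal(fit$loglik_ML, ll, tolerance = 1e-10)
})

test_that("grouped-variance fits agree with nlme::gls varIdent", {
  library(nlme)
  truth <- di_truth(the_pool)
  sim <- simulate_experiment(design5, truth, the_pool, years = 1, seed = 23)
  md <- model_data(sim, 1, "planted", the_pool)
  mm <- build_design_matrix(md, di_spec("M2", "P11"), the_pool)
  for (vsname in c("mono_vs_mixture", "mono_vs_focalmix_vs_othermix")) {
    g <- variance_groups(md, vsname, the_pool)
    fit <- fit_gls(md$y, mm, g)
    df <- data.frame(y = md$y, mm$X, g = g, check.names = TRUE)
    fml <- stats::as.formula(paste("y ~ 0 +",
      paste(make.names(colnames(mm$X)), collapse = "+")))
    ref_reml <- nlme::gls(fml, df, weights = nlme::varIdent(form = ~1 | g),
                          method = "REML")
    ref_ml <- nlme::gls(fml, df, weights = nlme::varIdent(form = ~1 | g),
                        method = "ML")
    expect_equal(fit$loglik_REML, as.numeric(logLik(ref_reml)),
                 tolerance = 1e-6)
    expect_equal(fit$loglik_ML, as.numeric(logLik(ref_ml)),
                 tolerance = 1e-6)
    expect_lt(max(abs(fit$coefficients - coef(ref_reml))), 1e-2)
    expect_lt(max(abs(fit$se - sqrt(diag(ref_reml$varBeta)))), 1e-2)
  }
})

test_that("ML log-likelihoods are monotone along the nested family", {
  truth <- di_truth(the_pool)
  sim <- simulate_experiment(design5, truth, the_pool, years = 1, seed = 24)
  md <- model_data(sim, 1, "planted", the_pool)
  g <- factor(rep("all", nrow(md)))
  ll <- vapply(c("M1", "M2", "M3", "FULL"), function(st) {
    mm <- build_design_matrix(md, di_spec(st), the_pool)
    fit_gls(md$y, mm, g)$loglik_ML
  }, 1)
  expect_true(all(diff(ll) >= -1e-6))
  # M4 nests M2 as well
  mm4 <- build_design_matrix(md, di_spec("M4"), the_pool)
  expect_gte(fit_gls(md$y, mm4, g)$loglik_ML, ll[["M2"]] - 1e-6)
})

test_that("variance-group estimates are invariant to row permutation", {
  truth <- di_truth(the_pool)
  sim <- simulate_experiment(design2, truth, the_pool, years = 1, seed = 25)
  md <- model_data(sim, 1, "planted", the_pool)
  mm <- build_design_matrix(md, di_spec("M2"), the_pool)
  g <- variance_groups(md, "mono_vs_mixture", the_pool)
  fit <- fit_gls(md$y, mm, g)
  set.seed(26)
  perm <- sample.int(nrow(md))
  fit_p <- fit_gls(md$y[perm], mm$X[perm, ], g[perm])
  expect_equal(fit$sigma2, fit_p$sigma2, tolerance = 1e-8)
  expect_equal(fit$coefficients, fit_p$coefficients, tolerance = 1e-8)
})

test_that("duplicating every row scales the log-likelihood sensibly", {
  truth <- di_truth(the_pool)
  sim <- simulate_experiment(design2, truth, the_pool, years = 1, seed = 27)
  md <- model_data(sim, 1, "planted", the_pool)
  mm <- build_design_matrix(md, di_spec("M2"), the_pool)
  g <- factor(rep("all", nrow(md)))
  f1 <- fit_gls(md$y, mm, g)
  f2 <- fit_gls(rep(md$y, 2), rbind(mm$X, mm$X), factor(rep(g, 2)))
  expect_gt(abs(f2$loglik_ML), abs(f1$loglik_ML))
})

test_that("rank-deficient designs report aliased coefficients", {
  dat <- planted_frame(design2)
  mm <- build_design_matrix(dat, di_spec("M2"), the_pool)
  X <- cbind(mm$X, dup = mm$X[, 1])  # duplicate column
  set.seed(28)
  y <- drop(mm$X %*% rnorm(ncol(mm$X), 100, 30)) + rnorm(nrow(X), 0, 10)
  fit <- fit_gls(y, X, factor(rep("all", nrow(X))))
  expect_equal(fit$rank, ncol(mm$X))
  expect_length(fit$aliased, 1L)
  expect_true(is.na(fit$coefficients["dup"]))
})

test_that("random-pairwise fit reduces to GLS when sigma_u is held at zero", {
  truth <- di_truth(the_pool)
  sim <- simulate_experiment(design5, truth, the_pool, years = 1, seed = 29)
  md <- model_data(sim, 1, "planted", the_pool)
  mm <- build_design_matrix(md, di_spec("M2", "P11"), the_pool)
  g <- variance_groups(md, "mono_vs_mixture", the_pool)
  f0 <- fit_gls(md$y, mm, g)
  f1 <- fit_random_pairwise(md$y, mm, g, fix_sigma_u = 0)
  expect_lt(max(abs(f0$coefficients - f1$coefficients)), 1e-10)
  expect_equal(f0$loglik_REML, f1$loglik_REML, tolerance = 1e-8)
  expect_equal(f0$loglik_ML, f1$loglik_ML, tolerance = 1e-8)
})

test_that("the pair variance is recovered at the boundary and away from it", {
  # under sigma_u = 0 truth the REML estimate has (asymptotically) equal
  # mass exactly at zero and above it - the chi-square 0/1 mixture; assert
  # the boundary mass rather than the knife-edge median
  su <- vapply(1:60, function(r) {
    truth <- di_truth(the_pool, sigma_u = 0)
    sim <- simulate_experiment(design5, truth, the_pool, years = 1,
                               seed = 300 + r)
    md <- model_data(sim, 1, "planted", the_pool)
    mm <- build_design_matrix(md, di_spec("M2", "P11"), the_pool)
    g <- variance_groups(md, "mono_vs_focalmix_vs_othermix", the_pool)
    fit_random_pairwise(md$y, mm, g)$sigma2_u
  }, 1)
  expect_gte(mean(su == 0), 0.3)
  expect_lte(mean(su == 0), 0.7)
  # strong pair heterogeneity is detected
  truth <- di_truth(the_pool, sigma_u = 600)
  detected <- vapply(1:10, function(r) {
    sim <- simulate_experiment(design5, truth, the_pool, years = 1,
                               seed = 400 + r)
    md <- model_data(sim, 1, "planted", the_pool)
    mm <- build_design_matrix(md, di_spec("M2", "P11"), the_pool)
    g <- variance_groups(md, "mono_vs_focalmix_vs_othermix", the_pool)
    f0 <- fit_gls(md$y, mm, g)
    f1 <- fit_random_pairwise(md$y, mm, g)
    compare_lrt(f0, f1, "variance", boundary = TRUE)$p < 0.05
  }, TRUE)
  expect_gte(mean(detected), 0.8)
})

test_that("empty variance groups are rejected", {
  dat <- planted_frame(design2)
  mm <- build_design_matrix(dat, di_spec("M2"), the_pool)
  g <- factor(rep("a", nrow(dat)), levels = c("a", "b"))
  set.seed(31)
  y <- rnorm(nrow(dat), 500, 50)
  expect_silent(fit_gls(y, mm, g))  # empty level dropped
  expect_error(fit_gls(y[1:10], mm$X[1:10, ], factor(rep("a", 9))))
})
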