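# Estimation of DI models: generalized least squares with grouped residual
# variances (ML by iterative reweighting, REML by numeric profile), and an
# optional shared-variance random effect for every species pair, fitted by
# REML on the marginal covariance V = sigma_u^2 Z Z' + diag(group variances).

VARIANCE_STRUCTURES <- c("homoscedastic", "mono_vs_mixture",
                         "mono_vs_focalmix_vs_othermix")

#' Residual variance grouping of plot observations
#'
#' Maps each plot row to a variance group under one of the candidate
#' heteroscedasticity structures: a single variance; separate monoculture
#' and mixture variances; or separate variances for monocultures, mixtures
#' containing the focal species, and the remaining mixtures (the focal
#' species' mixtures being markedly more variable motivates the third).
#'
#' @param data modeling data.frame (columns `pattern` and the species
#'   proportion columns).
#' @param structure one of `"homoscedastic"`, `"mono_vs_mixture"`,
#'   `"mono_vs_focalmix_vs_othermix"`.
#' @param pool a [species_pool()]; needed for the focal-mixture rule.
#' @return Factor of variance-group labels, one per row.
#' @export
variance_groups <- function(data, structure = "homoscedastic",
                            pool = NULL) {
  structure <- match.arg(structure, VARIANCE_STRUCTURES)
  n <- nrow(data)
  mono <- data$pattern == "monoculture"
  g <- switch(structure,
    homoscedastic = rep("all", n),
    mono_vs_mixture = ifelse(mono, "mono", "mix"),
    mono_vs_focalmix_vs_othermix = {
      if (is.null(pool) || is.na(pool$focal))
        stop("focal-mixture variance structure needs a pool with a focal species")
      pf <- data[[pool$species$abbr[pool$focal]]]
      ifelse(mono, "mono", ifelse(pf > 0, "focalmix", "othermix"))
    })
  factor(g)
}

# scale-relative floor keeping weights finite on (near) noise-free data
variance_floor <- function(y) 1e-12 * (stats::var(y) + mean(y)^2 + 1)

# weighted least squares on the estimable column set; returns residuals on
# the original scale
wls <- function(y, X, w) {
  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0  # X is pre-reduced to full rank; NA only if w kills a col
  list(beta = beta, residuals = y - drop(X %*% beta))
}

# Gaussian log-likelihoods for diagonal V = diag(sigma2[g])
diag_logliks <- function(y, X, g, sigma2, rank) {
  n <- length(y)
  w <- 1 / sigma2[as.integer(g)]
  f <- wls(y, X, w)
  rss_w <- sum(w * f$residuals^2)
  logdetV <- sum(tabulate(g, nbins = nlevels(g)) * log(sigma2))
  ml <- -0.5 * (n * log(2 * pi) + logdetV + rss_w)
  qrX <- qr(sqrt(w) * X)
  logdetXtWX <- 2 * sum(log(abs(diag(qr.R(qrX)))))
  reml <- -0.5 * ((n - rank) * log(2 * pi) + logdetV + logdetXtWX + rss_w)
  list(ML = ml, REML = reml, beta = f$beta, residuals = f$residuals)
}

#' Fit a DI model by generalized least squares with grouped variances
#'
#' Maximum-likelihood variances are found by iterating weighted least
#' squares against per-group mean squared residuals (relative tolerance
#' 1e-8, at most 200 iterations); REML variances by numeric maximization of
#' the restricted likelihood started at the ML solution.  Reported
#' coefficients and standard errors use the REML variances; the ML
#' log-likelihood (at the ML optimum) feeds AIC and fixed-effect likelihood
#' ratio tests.  With a single variance group the coefficient estimates
#' coincide with ordinary least squares.
#'
#' Rank-deficient design matrices are handled by dropping aliased columns
#' (pivoted QR); the corresponding coefficients are reported as `NA` and the
#' identifiable subspace is fitted.
#'
#' @param y numeric response vector (total plot biomass, g).
#' @param X numeric design matrix or a `di_model_matrix`.
#' @param groups factor of variance-group labels per row (see
#'   [variance_groups()]); a single level gives the homoscedastic fit.
#' @return An object of class `di_fit`; see [fit_random_pairwise()] for the
#'   random-effect variant.  Components include `coefficients` (with `NA`
#'   for aliased columns), `se`, `vcov`, `sigma2` (named per group),
#'   `sigma2_u` (zero here), `loglik_ML`, `loglik_REML`, `aic`, `rank`,
#'   `n_fixed`, `df_residual`, `residuals`, `fitted`.
#' @examples
#' pool <- space_pool()
#' des <- build_design(pool, n_blocks = 2, seed = 1)
#' dat <- cbind(des[c("block", "pattern")], planted_proportions(des, pool))
#' mm <- build_design_matrix(dat, di_spec("M2"), pool)
#' y <- drop(mm$X %*% rnorm(ncol(mm$X), 300, 50)) + rnorm(nrow(mm$X), 0, 10)
#' fit <- fit_gls(y, mm, factor(rep("all", length(y))))
#' fit$rank
#' @export
fit_gls <- function(y, X, groups) {
  mm <- NULL
  if (inherits(X, "di_model_matrix")) { mm <- X; X <- mm$X }
  groups <- droplevels(factor(groups))
  n <- length(y)
  stopifnot(nrow(X) == n, length(groups) == n)
  if (any(tabulate(groups) == 0L)) stop("empty variance group")

  qrX <- qr(X)
  rank <- qrX$rank
  est <- sort(qrX$pivot[seq_len(rank)])
  aliased <- setdiff(seq_len(ncol(X)), est)
  Xe <- X[, est, drop = FALSE]

  G <- nlevels(groups)
  gi <- as.integer(groups)
  ng <- tabulate(gi, nbins = G)
  floor2 <- variance_floor(y)

  # --- ML: iterate WLS <-> per-group variance update
  f <- wls(y, Xe, rep(1, n))
  sigma2 <- pmax(vapply(seq_len(G), function(g)
    mean(f$residuals[gi == g]^2), 1), floor2)
  trace <- list(sigma2)
  converged <- (G == 1L)  # one group: OLS is already the ML fixed-effect fit
  iter <- 0L
  if (!converged) {
    for (iter in seq_len(200L)) {
      f <- wls(y, Xe, 1 / sigma2[gi])
      new <- pmax(vapply(seq_len(G), function(g)
        mean(f$residuals[gi == g]^2), 1), floor2)
      rel <- max(abs(new - sigma2) / (sigma2 + floor2))
      sigma2 <- new
      trace[[length(trace) + 1L]] <- sigma2
      if (rel < 1e-8) { converged <- TRUE; break }
    }
    if (!converged) {
      cond <- simpleError("GLS variance iteration failed to converge in 200 steps")
      cond$trace <- trace
      stop(cond)
    }
  } else {
    # ML variance of the single group, at the OLS coefficients
    sigma2 <- pmax(mean(f$residuals^2), floor2)
  }
  names(sigma2) <- levels(groups)
  ll_ml <- diag_logliks(y, Xe, groups, sigma2, rank)$ML

  # --- REML variances
  if (G == 1L) {
    sigma2_reml <- pmax(sum(f$residuals^2) / (n - rank), floor2)
    names(sigma2_reml) <- levels(groups)
    lr <- diag_logliks(y, Xe, groups, sigma2_reml, rank)
  } else {
    obj <- function(ls2) -diag_logliks(y, Xe, groups, exp(ls2), rank)$REML
    opt <- stats::optim(log(sigma2), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    sigma2_reml <- stats::setNames(pmax(exp(opt$par), floor2), levels(groups))
    lr <- diag_logliks(y, Xe, groups, sigma2_reml, rank)
  }

  finish_fit(y, X, Xe, est, aliased, mm, groups,
             sigma2_ml = sigma2, sigma2_reml = sigma2_reml,
             sigma2_u = 0, loglik_ML = ll_ml, loglik_REML = lr$REML,
             beta_e = lr$beta, residuals = lr$residuals,
             vcov_e = {
               w <- 1 / sigma2_reml[as.integer(groups)]
               chol2inv(chol(crossprod(Xe * sqrt(w))))
             },
             rank = rank, n_varpar = G, iterations = iter,
             Z = NULL, blup = NULL)
}

# logliks for V = sigma2_u Z Z' + diag(sigma2[g]); profile of fixed effects
full_logliks <- function(y, Xe, Z, g, sigma2, sigma2_u, rank) {
  n <- length(y)
  V <- diag(sigma2[as.integer(g)], n)
  if (sigma2_u > 0) V <- V + sigma2_u * tcrossprod(Z)
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(NULL)
  logdetV <- 2 * sum(log(diag(cV)))
  # whiten with R'^-1 where V = R'R, so crossprod(whitened) = X' V^-1 X
  U <- forwardsolve(t(cV), Xe)
  u_y <- forwardsolve(t(cV), y)
  qrW <- qr(U)
  beta <- qr.coef(qrW, u_y)
  beta[is.na(beta)] <- 0
  rss <- sum((u_y - U %*% beta)^2)
  logdetXtViX <- 2 * sum(log(abs(diag(qr.R(qrW)))))
  ml <- -0.5 * (n * log(2 * pi) + logdetV + rss)
  reml <- -0.5 * ((n - rank) * log(2 * pi) + logdetV + logdetXtViX + rss)
  resid <- y - drop(Xe %*% beta)
  list(ML = ml, REML = reml, beta = beta, residuals = resid,
       XtViX = crossprod(U), chol_V = cV)
}

#' Fit a DI model with random pairwise interaction deviations
#'
#' Adds to the fixed DI structure a random effect for every species pair,
#' all constrained to share one variance `sigma_u^2`: the marginal model is
#' `y ~ N(X beta, sigma_u^2 Z Z' + diag(group variances))` with `Z` the
#' matrix of pairwise proportion products.  Variance parameters are
#' estimated by REML (fixed effects profiled out); `sigma_u^2 = 0` is a
#' valid boundary solution at which the fit coincides with [fit_gls()].
#' Pair-level deviations are predicted by BLUP.
#'
#' @inheritParams fit_gls
#' @param Z matrix of pairwise products (`S(S-1)/2` columns; see
#'   [pairwise_products()]).
#' @param fix_sigma_u optionally hold the pair variance at a given value
#'   (e.g. 0) instead of estimating it; at 0 the fit reproduces
#'   [fit_gls()] exactly.
#' @return A `di_fit` with `sigma2_u` and `blup` (named pair deviations)
#'   filled in.
#' @export
fit_random_pairwise <- function(y, X, groups, Z, fix_sigma_u = NULL) {
  mm <- NULL
  if (inherits(X, "di_model_matrix")) {
    mm <- X
    if (missing(Z) || is.null(Z)) {
      Z <- pairwise_products(mm$P)
      pr <- pair_index(mm$pool$S)
      colnames(Z) <- paste0(mm$pool$species$abbr[pr$i], ".",
                            mm$pool$species$abbr[pr$j])
    }
    X <- mm$X
  }
  groups <- droplevels(factor(groups))
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(Z) == n)

  base <- fit_gls(y, if (is.null(mm)) X else mm, groups)
  if (!is.null(fix_sigma_u) && fix_sigma_u == 0) {
    # exact reduction: the marginal model IS the grouped-variance GLS model
    out <- base
    out$Z <- Z
    out$blup <- stats::setNames(rep(0, ncol(Z)), colnames(Z))
    return(out)
  }
  est <- which(!is.na(base$coefficients))
  Xe <- X[, est, drop = FALSE]
  rank <- base$rank
  G <- nlevels(groups)
  floor2 <- variance_floor(y)

  # optimize REML over (log group variances, sigma_u on sd scale)
  scale_u <- sqrt(mean(base$sigma2))
  fixed_u <- !is.null(fix_sigma_u)
  objective <- function(par, kind) {
    s2 <- exp(par[seq_len(G)])
    su <- if (fixed_u) fix_sigma_u else (par[G + 1L] * scale_u)^2
    ll <- full_logliks(y, Xe, Z, groups, s2, su, rank)
    if (is.null(ll)) return(1e10)
    -ll[[kind]]
  }
  npar <- G + !fixed_u
  start <- c(log(base$sigma2), if (!fixed_u) 0.3)
  lower <- c(rep(log(floor2), G), if (!fixed_u) 0)
  upper <- c(rep(log(.Machine$double.xmax) / 2, G), if (!fixed_u) 1e3)
  opt_reml <- stats::optim(start, objective, kind = "REML",
                           method = "L-BFGS-B",
                           lower = lower, upper = upper,
                           control = list(factr = 1e4, maxit = 500))
  s2_reml <- stats::setNames(exp(opt_reml$par[seq_len(G)]), levels(groups))
  s2u_reml <- if (fixed_u) fix_sigma_u else (opt_reml$par[G + 1L] * scale_u)^2
  # snap to the boundary when the restricted likelihood is flat at zero
  if (!fixed_u && s2u_reml > 0) {
    at0 <- full_logliks(y, Xe, Z, groups, base$sigma2, 0, rank)
    atu <- full_logliks(y, Xe, Z, groups, s2_reml, s2u_reml, rank)
    if (!is.null(at0) && !is.null(atu) && at0$REML >= atu$REML - 1e-6) {
      s2u_reml <- 0
      s2_reml <- base$sigma2
    }
  }
  llr <- full_logliks(y, Xe, Z, groups, s2_reml, s2u_reml, rank)

  opt_ml <- stats::optim(opt_reml$par, objective, kind = "ML",
                         method = "L-BFGS-B",
                         lower = lower, upper = upper,
                         control = list(factr = 1e4, maxit = 500))
  s2_ml <- exp(opt_ml$par[seq_len(G)])
  s2u_ml <- if (fixed_u) fix_sigma_u else (opt_ml$par[G + 1L] * scale_u)^2
  ll_ml <- full_logliks(y, Xe, Z, groups, s2_ml, s2u_ml, rank)$ML

  # BLUP of pair deviations: sigma_u^2 Z' V^-1 (y - X beta)
  cV <- llr$chol_V
  Vi_r <- backsolve(cV, forwardsolve(t(cV), llr$residuals))  # V^-1 r
  blup <- drop(s2u_reml * crossprod(Z, Vi_r))
  names(blup) <- colnames(Z)

  finish_fit(y, X, Xe, est, setdiff(seq_len(ncol(X)), est), mm, groups,
             sigma2_ml = stats::setNames(s2_ml, levels(groups)),
             sigma2_reml = s2_reml,
             sigma2_u = s2u_reml, loglik_ML = ll_ml, loglik_REML = llr$REML,
             beta_e = llr$beta, residuals = llr$residuals,
             vcov_e = chol2inv(chol(llr$XtViX)),
             rank = rank, n_varpar = G + !fixed_u,
             iterations = opt_reml$counts[[1L]],
             Z = Z, blup = blup)
}

finish_fit <- function(y, X, Xe, est, aliased, mm, groups,
                       sigma2_ml, sigma2_reml, sigma2_u,
                       loglik_ML, loglik_REML, beta_e, residuals, vcov_e,
                       rank, n_varpar, iterations, Z, blup) {
  p_all <- ncol(X)
  beta <- rep(NA_real_, p_all)
  se <- rep(NA_real_, p_all)
  beta[est] <- beta_e
  se[est] <- sqrt(pmax(diag(vcov_e), 0))
  names(beta) <- names(se) <- colnames(X)
  dimnames(vcov_e) <- list(colnames(X)[est], colnames(X)[est])
  n <- length(y)
  aic <- -2 * loglik_ML + 2 * (rank + n_varpar)
  structure(list(
    coefficients = beta, se = se, vcov = vcov_e, estimable = est,
    aliased = colnames(X)[aliased],
    sigma2 = sigma2_reml, sigma2_ml = sigma2_ml, sigma2_u = sigma2_u,
    loglik_ML = loglik_ML, loglik_REML = loglik_REML, aic = aic,
    n = n, rank = rank, n_fixed = p_all, n_varpar = n_varpar,
    df_residual = n - rank,
    fitted = y - residuals, residuals = residuals, y = y,
    groups = groups, iterations = iterations,
    X = X, mm = mm, Z = Z, blup = blup), class = "di_fit")
}

#' Log-likelihood of a fitted DI model
#'
#' @param fit a `di_fit`.
#' @param kind `"ML"` (used for AIC and fixed-effect comparisons) or
#'   `"REML"` (used for variance-parameter comparisons).
#' @return Scalar log-likelihood.
#' @export
loglik <- function(fit, kind = c("ML", "REML")) {
  kind <- match.arg(kind)
  if (kind == "ML") fit$loglik_ML else fit$loglik_REML
}

#' @export
logLik.di_fit <- function(object, REML = FALSE, ...) {
  val <- if (REML) object$loglik_REML else object$loglik_ML
  structure(val, df = object$rank + object$n_varpar, class = "logLik")
}

#' @export
AIC.di_fit <- function(object, ..., k = 2) object$aic

#' @export
print.di_fit <- function(x, ...) {
  if (!is.null(x$mm)) print(x$mm$spec)
  cat(sprintf("n = %d, fixed coefficients = %d (rank %d), variance params = %d\n",
              x$n, x$n_fixed, x$rank, x$n_varpar))
  cat(sprintf("logLik(ML) = %.3f, logLik(REML) = %.3f, AIC = %.3f\n",
              x$loglik_ML, x$loglik_REML, x$aic))
  cat("Residual variances (REML):\n")
  print(x$sigma2)
  if (x$sigma2_u > 0)
    cat(sprintf("Random pairwise variance: %.4g\n", x$sigma2_u))
  invisible(x)
}

#' Coefficient table of a DI fit
#'
#' @param fit a `di_fit`.
#' @return data.frame with estimate, SE, t value and two-sided p value
#'   (t distribution on residual degrees of freedom); aliased coefficients
#'   appear with `NA`.
#' @export
coef_table <- function(fit) {
  est <- fit$coefficients
  se <- fit$se
  tval <- est / se
  p <- 2 * stats::pt(abs(tval), fit$df_residual, lower.tail = FALSE)
  data.frame(term = names(est), estimate = est, se = se,
             t = tval, p = p, row.names = NULL)
}

#' Fit a DI model specification to plot data
#'
#' Convenience wrapper: builds the design matrix for `spec`, derives the
#' variance grouping, and dispatches to [fit_gls()] or
#' [fit_random_pairwise()].
#'
#' @param data modeling data.frame: columns `block`, `pattern`, `y` (total
#'   plot biomass, g) and one proportion column per species abbreviation.
#' @param spec a [di_spec()].
#' @param pool a [species_pool()].
#' @return A `di_fit`.
#' @examples
#' pool <- space_pool()
#' truth <- di_truth(pool)
#' sim <- simulate_experiment(build_design(pool, 5, seed = 1), truth,
#'                            pool, years = 1, seed = 2)
#' dat <- model_data(sim, year = 1, source = "planted", pool = pool)
#' fit_di_model(dat, di_spec("M2", "P11",
#'                           variance_structure = "mono_vs_mixture"), pool)
#' @export
fit_di_model <- function(data, spec, pool) {
  y <- data$y
  if (is.null(y)) stop("data must contain a 'y' response column")
  mm <- build_design_matrix(data, spec, pool)
  g <- variance_groups(data, spec$variance_structure, pool)
  if (spec$random_pairwise) fit_random_pairwise(y, mm, g, NULL)
  else fit_gls(y, mm, g)
}
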