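# Hierarchical model selection for the DI family: structure choice
# (M1 -> M2 -> {M3, M4} -> FULL capacity check), diversity-effect expansion
# tests, variance-structure REML comparisons, the boundary test for the
# random pairwise component, and the AIC comparison of planted vs. realized
# reference proportions.

#' F-test between nested DI fixed-effects models
#'
#' Compares two fits of the same response under the same variance grouping,
#' the smaller model's fixed-effect column space nested in the larger's.
#' Residuals are standardized by the larger model's estimated group
#' variances, so the statistic reduces to the classical nested-regression F
#' in the homoscedastic case.
#'
#' @param fit_small,fit_big `di_fit` objects (see [fit_gls()]).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
compare_nested_F <- function(fit_small, fit_big) {
  check_same_response(fit_small, fit_big)
  if (!identical(as.character(fit_small$groups), as.character(fit_big$groups)))
    stop("F-test requires the same variance grouping in both models")
  check_nested(fit_small, fit_big)
  w <- 1 / fit_big$sigma2[as.integer(fit_big$groups)]
  rss_w <- function(fit) {
    Xe <- fit$X[, fit$estimable, drop = FALSE]
    f <- wls(fit$y, Xe, w)
    sum(w * f$residuals^2)
  }
  rss_s <- rss_w(fit_small)
  rss_b <- rss_w(fit_big)
  df1 <- fit_big$rank - fit_small$rank
  df2 <- fit_big$n - fit_big$rank
  if (df1 <= 0L) return(list(F = 0, df1 = 0L, df2 = df2, p = 1))
  Fstat <- max(0, (rss_s - rss_b) / df1) / (rss_b / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

check_same_response <- function(a, b) {
  if (a$n != b$n || max(abs(a$y - b$y)) > 0)
    stop("models were fitted to different responses")
}

check_nested <- function(fit_small, fit_big) {
  Xs <- fit_small$X[, fit_small$estimable, drop = FALSE]
  Xb <- fit_big$X[, fit_big$estimable, drop = FALSE]
  qrb <- qr(Xb)
  resid <- qr.resid(qrb, Xs)
  rel <- sqrt(colSums(resid^2)) / pmax(sqrt(colSums(Xs^2)), 1e-300)
  if (any(rel > 1e-8))
    stop("models are not nested: small-model columns outside the big model's span")
  invisible(TRUE)
}

#' Likelihood-ratio test between nested DI models
#'
#' `kind = "fixed"` compares fixed-effects structures by ML;
#' `kind = "variance"` compares variance structures (matching fixed effects)
#' by REML.  When a single variance component is tested on the boundary of
#' its parameter space (`boundary = TRUE`, e.g. the random pairwise
#' variance), the p value uses the 50:50 mixture of chi-square 0 and 1
#' reference.
#'
#' @param fit_small,fit_big `di_fit` objects.
#' @param kind `"fixed"` or `"variance"`.
#' @param boundary logical; single-component boundary test.
#' @return list with `X2`, `df`, `p`.
#' @export
compare_lrt <- function(fit_small, fit_big, kind = c("fixed", "variance"),
                        boundary = FALSE) {
  kind <- match.arg(kind)
  check_same_response(fit_small, fit_big)
  if (kind == "fixed") {
    X2 <- 2 * (fit_big$loglik_ML - fit_small$loglik_ML)
    df <- fit_big$rank - fit_small$rank
  } else {
    if (fit_small$rank != fit_big$rank)
      stop("variance-structure LRT requires matching fixed effects")
    X2 <- 2 * (fit_big$loglik_REML - fit_small$loglik_REML)
    df <- fit_big$n_varpar - fit_small$n_varpar
  }
  scale <- abs(fit_big$loglik_REML) + abs(fit_big$loglik_ML) + 1
  if (X2 < -1e-6 * scale)
    stop(sprintf("negative LRT statistic (%.4g): larger model not converged", X2))
  X2 <- max(X2, 0)
  p <- if (boundary) {
    if (X2 <= 0) 1
    else if (df == 1L) 0.5 * stats::pchisq(X2, 1, lower.tail = FALSE)
    else stop("boundary mixture reference implemented for df = 1")
  } else {
    if (df <= 0L) 1 else stats::pchisq(X2, df, lower.tail = FALSE)
  }
  list(X2 = X2, df = df, p = p)
}

new_step <- function(step, small, big, test, statistic, df, p_or_delta,
                     decision) {
  data.frame(step = step, model_small = small, model_big = big, test = test,
             statistic = statistic, df = df, p_or_delta = p_or_delta,
             decision = decision, stringsAsFactors = FALSE)
}

#' Hierarchical DI model selection
#'
#' Runs the selection cascade on one year's observations:
#' \enumerate{
#'   \item Variance structure first: REML likelihood-ratio chain
#'     homoscedastic -> monoculture/mixture ->
#'     monoculture/focal-mixture/other-mixture, under a rich baseline fixed
#'     model (M2 with both DE expansions), so that all subsequent
#'     fixed-effect F-tests are correctly weighted.
#'   \item Entry test for any diversity effect: M1 vs the expanded average
#'     pairwise model (M2 + Sp + P11; one 3-df F-test, so the entry type-I
#'     error stays at `alpha` while diversity effects expressed only
#'     through the pattern or focal interactions are still caught).  If not
#'     significant the identity model M1 is final.
#'   \item DE expansions on M2 (the entry test already screened them
#'     jointly): forward single-term F-tests in both orders (a disagreement
#'     between orders is recorded and resolved by AIC).
#'   \item Interaction structure with the chosen expansions attached:
#'     M2 vs M3 and M2 vs M4 (F-tests); if both improve, the lower-AIC
#'     structure carries forward (ties within 2 AIC broken toward the model
#'     with fewer parameters).  The winner is compared against the full
#'     pairwise model as a recorded capacity diagnostic (a significant
#'     result flags residual lack of fit but FULL is never selected).
#'   \item Variance chain re-run under the final fixed model.
#'   \item Shared-variance random pairwise component: REML boundary test
#'     (50:50 chi-square 0/1 mixture).
#' }
#' Singular or failing fits are recorded in the trace and their branch
#' skipped.
#'
#' @param data modeling data.frame (see [fit_di_model()]).
#' @param pool a [species_pool()].
#' @param proportion_source `"planted"` or `"realized"` (recorded in the
#'   final spec; `data` must already carry the matching proportions).
#' @param alpha significance level for every F/LRT decision.
#' @param test_random_pairwise logical; include step 5.
#' @return Object of class `di_selection`: list with `steps` (data.frame
#'   trace), `final_spec` ([di_spec()]) and `final_fit` (`di_fit`).
#' @export
select_model <- function(data, pool, proportion_source = "planted",
                         alpha = 0.05, test_random_pairwise = TRUE) {
  cache <- new.env(parent = emptyenv())
  fit1 <- function(structure, expansions = character(),
                   vs = "homoscedastic", rp = FALSE) {
    spec <- di_spec(structure, expansions, proportion_source, vs, rp)
    key <- format_spec(spec)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- tryCatch(fit_di_model(data, spec, pool), error = function(e) e)
    cache[[key]] <- f
    f
  }
  steps <- NULL
  add <- function(...) steps <<- rbind(steps, new_step(...))
  label <- function(structure, expansions = character(), vs = "homo",
                    rp = FALSE)
    paste0(structure,
           if (length(expansions)) paste0("+", paste(expansions, collapse = "+"))
           else "")

  ftest <- function(step, small, big, sm_lab, bg_lab) {
    if (inherits(small, "error") || inherits(big, "error")) {
      add(step, sm_lab, bg_lab, "F", NA, NA,
          NA, "skipped: fit failed")
      return(NULL)
    }
    r <- compare_nested_F(small, big)
    dec <- if (r$p < alpha) "larger model" else "smaller model"
    add(step, sm_lab, bg_lab, "F", r$F, r$df1, r$p, dec)
    r
  }

  variance_chain <- function(structure, expansions, stage) {
    vs <- "homoscedastic"
    for (cand in c("mono_vs_mixture", "mono_vs_focalmix_vs_othermix")) {
      step <- paste0("variance (", stage, "): ", vs, " vs ", cand)
      small <- fit1(structure, expansions, vs)
      big <- fit1(structure, expansions, cand)
      if (inherits(small, "error") || inherits(big, "error")) {
        add(step, vs, cand, "LRT(REML)", NA, NA, NA, "skipped: fit failed")
        next
      }
      r <- tryCatch(compare_lrt(small, big, "variance"),
                    error = function(e) e)
      if (inherits(r, "error")) {
        add(step, vs, cand, "LRT(REML)", NA, NA, NA,
            paste("skipped:", conditionMessage(r)))
        next
      }
      dec <- if (r$p < alpha) cand else vs
      add(step, vs, cand, "LRT(REML)", r$X2, r$df, r$p, dec)
      vs <- dec
    }
    vs
  }

  # --- step 1: variance structure under a rich baseline fixed model
  vs <- variance_chain("M2", c("P11", "Sp"), "baseline")

  # --- step 2: entry test for any diversity effect
  m1 <- fit1("M1", vs = vs)
  m2x <- fit1("M2", c("P11", "Sp"), vs)
  r_entry <- ftest("entry: M1 vs M2+Sp+P11", m1, m2x, "M1", "M2+Sp+P11")
  structure <- if (!is.null(r_entry) && r_entry$p < alpha) "M2" else "M1"

  # --- step 3: DE expansions on the average pairwise model
  expansions <- character(0)
  if (structure != "M1") {
    forward <- function(order) {
      cur <- character(0)
      for (e in order) {
        small <- fit1("M2", cur, vs)
        big <- fit1("M2", sort(c(cur, e)), vs)
        r <- ftest(paste0("expansion: +", e, " given {",
                          paste(cur, collapse = ","), "}"),
                   small, big, label("M2", cur), label("M2", c(cur, e)))
        if (!is.null(r) && r$p < alpha) cur <- sort(c(cur, e))
      }
      cur
    }
    setA <- forward(c("Sp", "P11"))
    setB <- forward(c("P11", "Sp"))
    if (identical(setA, setB)) {
      expansions <- setA
    } else {
      fa <- fit1("M2", setA, vs); fb <- fit1("M2", setB, vs)
      d <- fb$aic - fa$aic
      expansions <- if (d <= 0) setB else setA
      add("expansion: order disagreement resolved by AIC",
          label("M2", setA), label("M2", setB), "AIC", d, NA, d,
          paste(expansions, collapse = "+"))
    }
  }

  # --- step 4: interaction structure, expansions attached
  if (structure == "M2") {
    m2 <- fit1("M2", expansions, vs)
    m3 <- fit1("M3", expansions, vs)
    m4 <- fit1("M4", expansions, vs)
    r23 <- ftest("structure: M2 vs M3", m2, m3,
                 label("M2", expansions), label("M3", expansions))
    r24 <- ftest("structure: M2 vs M4", m2, m4,
                 label("M2", expansions), label("M4", expansions))
    win3 <- !is.null(r23) && r23$p < alpha
    win4 <- !is.null(r24) && r24$p < alpha
    if (win3 && win4) {
      d <- m4$aic - m3$aic
      # |dAIC| < 2: prefer the model with fewer parameters (M4)
      structure <- if (abs(d) < 2) "M4" else if (d < 0) "M4" else "M3"
      add("structure: M3 vs M4 (AIC)", "M4", "M3", "AIC", d, NA, d,
          structure)
    } else if (win3) structure <- "M3"
    else if (win4) structure <- "M4"
    # capacity diagnostic against the full pairwise model (never selected)
    wfit <- fit1(structure, expansions, vs)
    mf <- fit1("FULL", expansions, vs)
    if (!inherits(wfit, "error") && !inherits(mf, "error")) {
      rf <- tryCatch(compare_nested_F(wfit, mf), error = function(e) e)
      if (!inherits(rf, "error"))
        add(paste0("capacity: ", structure, " vs FULL"),
            label(structure, expansions), label("FULL", expansions), "F",
            rf$F, rf$df1, rf$p,
            if (rf$p < alpha) "lack-of-fit flag" else "adequate")
    }
  }

  # --- step 5: variance structure re-checked under the final fixed model
  vs <- variance_chain(structure, expansions, "final")

  # --- step 5: random pairwise component (REML boundary test)
  random_pairwise <- FALSE
  if (test_random_pairwise && structure != "M1") {
    small <- fit1(structure, expansions, vs)
    big <- fit1(structure, expansions, vs, rp = TRUE)
    if (!inherits(small, "error") && !inherits(big, "error")) {
      r <- tryCatch(compare_lrt(small, big, "variance", boundary = TRUE),
                    error = function(e) e)
      if (inherits(r, "error")) {
        add("random pairwise", "fixed only", "+random pairwise",
            "LRT(REML, boundary)", NA, NA, NA,
            paste("skipped:", conditionMessage(r)))
      } else {
        random_pairwise <- r$p < alpha
        add("random pairwise", "fixed only", "+random pairwise",
            "LRT(REML, boundary)", r$X2, r$df, r$p,
            if (random_pairwise) "include" else "exclude")
      }
    } else {
      add("random pairwise", "fixed only", "+random pairwise",
          "LRT(REML, boundary)", NA, NA, NA, "skipped: fit failed")
    }
  }

  final_spec <- di_spec(structure, expansions, proportion_source, vs,
                        random_pairwise)
  final_fit <- fit1(structure, expansions, vs, random_pairwise)
  if (inherits(final_fit, "error"))
    stop("final model failed to fit: ", conditionMessage(final_fit))
  structure(list(steps = steps, final_spec = final_spec,
                 final_fit = final_fit, alpha = alpha),
            class = "di_selection")
}

#' @export
print.di_selection <- function(x, ...) {
  cat("DI model selection trace (alpha =", x$alpha, ")\n")
  df <- x$steps
  df$statistic <- signif(df$statistic, 4)
  df$p_or_delta <- signif(df$p_or_delta, 4)
  print(df, row.names = FALSE)
  cat("\nFinal model: ")
  print(x$final_spec)
  invisible(x)
}

#' Compare planted- and realized-proportion models by AIC
#'
#' Given the final selected fits for the same year's responses under the
#' two reference-proportion conventions, reports
#' `dAIC = AIC(realized) - AIC(planted)`; positive values favor the
#' planted-proportion model.
#'
#' @param trace_planted,trace_realized `di_selection` objects (or bare
#'   `di_fit`s) for the same response vector.
#' @return list with `dAIC`, `winner` (`"planted"` or `"realized"`),
#'   `aic_planted`, `aic_realized`.
#' @export
compare_proportion_sources <- function(trace_planted, trace_realized) {
  fp <- if (inherits(trace_planted, "di_selection"))
    trace_planted$final_fit else trace_planted
  fr <- if (inherits(trace_realized, "di_selection"))
    trace_realized$final_fit else trace_realized
  check_same_response(fp, fr)
  d <- fr$aic - fp$aic
  list(dAIC = d, winner = if (d >= 0) "planted" else "realized",
       aic_planted = fp$aic, aic_realized = fr$aic)
}
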