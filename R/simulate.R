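# Synthetic multi-year biomass generator emulating a patterned biodiversity
# experiment: plot totals follow the DI model (identity + block + diversity
# effect + grouped Gaussian noise, optional shared pair random effects);
# species-level biomass is a Dirichlet-perturbed allocation of the total.

#' Truth parameters for the biomass simulator
#'
#' Defines the generative side of a DI model.  The defaults describe a
#' productive tallgrass-prairie-like system: monoculture means of a few
#' hundred g/plot with a strongly dominant focal forb, a positive average
#' pairwise interaction whose strength grows with the focal species'
#' proportion, larger residual variability in focal-species mixtures than in
#' other mixtures or monocultures, and year effects peaking in year 2.
#'
#' @param pool a [species_pool()].
#' @param beta monoculture means (g/plot), length S.
#' @param alpha block effects summing to zero, length B.
#' @param structure DE truth form: `"none"`, `"M2"`, `"M3"`, `"M4"`, `"FULL"`.
#' @param delta base DE coefficients: scalar for `"M2"`, length-S lambda for
#'   `"M3"`, length-`T(T+1)/2` omega for `"M4"`, length-`S(S-1)/2` for
#'   `"FULL"`; ignored for `"none"`.
#' @param delta_Sp optional pattern modifier with the same shape as `delta`
#'   (added to pair coefficients in aggregated plots); `NULL` for none.
#' @param delta_P11 optional focal modifier with the same shape as `delta`
#'   (added after scaling by the focal species' proportion); `NULL` for none.
#' @param variance_structure grouping of residual variances (see
#'   [variance_groups()]).
#' @param sigma residual standard deviations (g), named by variance group.
#' @param sigma_u standard deviation of the shared pair random deviations
#'   (0 disables them).
#' @param year_scalars multiplicative year effects on the identity terms.
#' @param allocation_conc Dirichlet concentration scaling for the
#'   species-level allocation of plot totals (larger = species shares closer
#'   to their expected shares).
#' @return An object of class `di_truth`.
#' @export
di_truth <- function(pool,
                     beta = default_beta(pool),
                     alpha = c(60, 30, 0, -30, -60),
                     structure = "M2",
                     delta = 93.6,
                     delta_Sp = NULL,
                     delta_P11 = 2347.6,
                     variance_structure = "mono_vs_focalmix_vs_othermix",
                     sigma = c(mono = 75, focalmix = 200, othermix = 100),
                     sigma_u = 0,
                     year_scalars = c(1, 1.6, 1.3),
                     allocation_conc = 15) {
  structure <- match.arg(structure, c("none", "M2", "M3", "M4", "FULL"))
  variance_structure <- match.arg(variance_structure, VARIANCE_STRUCTURES)
  stopifnot(length(beta) == pool$S, all(beta > 0), all(sigma > 0),
            sigma_u >= 0, abs(sum(alpha)) < 1e-8)
  want <- de_truth_length(structure, pool)
  for (nm in c("delta", "delta_Sp", "delta_P11")) {
    v <- get(nm)
    if (structure == "none" || is.null(v)) next
    if (!length(v) %in% c(1L, want))
      stop(nm, " must be scalar or length ", want, " for structure ", structure)
  }
  # probe rows covering every variance group of the chosen structure
  focal <- if (is.na(pool$focal)) 2L else pool$focal
  Pp <- matrix(0, 3L, pool$S, dimnames = list(NULL, pool$species$abbr))
  Pp[1L, 1L] <- 1
  Pp[2L, focal] <- 0.5; Pp[2L, 1L] <- 0.5
  Pp[3L, 1L] <- 0.5; Pp[3L, 2L] <- 0.5
  probe <- cbind(data.frame(pattern = c("monoculture", "dispersed",
                                        "dispersed")),
                 as.data.frame(Pp))
  glevels <- levels(variance_groups(probe, variance_structure, pool))
  if (!all(glevels %in% names(sigma)))
    stop("sigma must be named with groups: ", paste(glevels, collapse = ", "))
  structure(list(pool = pool, beta = beta, alpha = alpha,
                 structure = structure, delta = delta, delta_Sp = delta_Sp,
                 delta_P11 = delta_P11,
                 variance_structure = variance_structure,
                 sigma2 = stats::setNames(sigma[glevels]^2, glevels),
                 sigma_u = sigma_u, year_scalars = year_scalars,
                 allocation_conc = allocation_conc),
            class = "di_truth")
}

de_truth_length <- function(structure, pool) {
  switch(structure, none = 0L, M2 = 1L, M3 = pool$S,
         M4 = pool$T * (pool$T + 1L) / 2L, FULL = pool$S * (pool$S - 1L) / 2L)
}

#' Default monoculture means of the prairie simulator
#'
#' Fixed species-level monoculture expectations (g/plot): grasses and
#' legumes in the 250-600 g range, forbs similar except the focal species,
#' which is set several-fold higher to reproduce the dominance of a large
#' rhizomatous forb.
#'
#' @param pool a [species_pool()].
#' @return Named numeric vector of length S.
#' @export
default_beta <- function(pool) {
  base <- rep(c(550, 400, 500, 600,   # warm-season grasses
                450, 350, 300, 250,   # cool-season grasses
                300, 700, 1500, 350,  # forbs (focal = 1500)
                400, 600, 250, 300),  # legumes
              length.out = pool$S)
  stats::setNames(base, pool$species$abbr)
}

# symmetric S x S matrix of pair coefficients from truth coefficients of a
# given structural form (scalar recycled to the form's length)
pair_coef_matrix <- function(coefs, structure, pool) {
  S <- pool$S
  D <- matrix(0, S, S)
  if (structure == "none" || is.null(coefs)) return(D)
  want <- de_truth_length(structure, pool)
  v <- rep(coefs, length.out = want)
  pr <- pair_index(S)
  dij <- switch(structure,
    M2 = rep(v, length(pr$i)),
    M3 = v[pr$i] + v[pr$j],
    M4 = {
      key <- function(k, l) paste0(pmin(k, l), ".", pmax(k, l))
      T <- pool$T
      nm <- c(paste0(1:T, ".", 1:T),
              unlist(lapply(seq_len(T - 1L), function(k)
                paste0(k, ".", (k + 1L):T))))
      names(v) <- nm
      v[key(pool$fg[pr$i], pool$fg[pr$j])]
    },
    FULL = v)
  D[cbind(pr$i, pr$j)] <- dij
  D[cbind(pr$j, pr$i)] <- dij
  D
}

# expected plot total and per-species expected contributions for one row
expected_row <- function(P, Sp, block, truth, year, u_pairs = NULL) {
  pool <- truth$pool
  ys <- truth$year_scalars[min(year, length(truth$year_scalars))]
  D <- pair_coef_matrix(truth$delta, truth$structure, pool)
  if (!is.null(truth$delta_Sp))
    D <- D + Sp * pair_coef_matrix(truth$delta_Sp, truth$structure, pool)
  if (!is.null(truth$delta_P11))
    D <- D + P[pool$focal] *
      pair_coef_matrix(truth$delta_P11, truth$structure, pool)
  if (!is.null(u_pairs)) {
    Du <- matrix(0, pool$S, pool$S)
    pr <- pair_index(pool$S)
    Du[cbind(pr$i, pr$j)] <- u_pairs
    Du[cbind(pr$j, pr$i)] <- u_pairs
    D <- D + Du
  }
  PP <- outer(P, P) * D
  de_by_species <- rowSums(PP) / 2  # each pair's term split equally
  id_by_species <- ys * truth$beta * P
  alpha_b <- truth$alpha[block]
  list(total = sum(id_by_species) + alpha_b + sum(PP[upper.tri(PP)]),
       shares = id_by_species + de_by_species)
}

#' Simulate one year of plot and species biomass
#'
#' Plot totals are drawn from the DI truth (identity + block + diversity
#' effect + optional shared pair deviations + group-variance Gaussian
#' noise); each total is then allocated to the species present by a
#' Dirichlet perturbation of their expected shares, so species biomass is
#' non-negative and sums exactly to the plot total.  Plots whose noise draw
#' would make the total non-positive are re-drawn (up to 20 times, then
#' truncated just above zero); the number of such redraws is recorded in the
#' `allocation_events` attribute.
#'
#' @param design a [build_design()] data.frame.
#' @param truth a [di_truth()].
#' @param pool a [species_pool()].
#' @param year integer year (scales identity effects via
#'   `truth$year_scalars`).
#' @param seed integer seed.
#' @param P optional n-by-S matrix of generative reference proportions;
#'   defaults to the planted proportions of `design`.
#' @param u_pairs optional vector of pair deviations (length `S(S-1)/2`),
#'   e.g. drawn once and reused across years; drawn internally when
#'   `truth$sigma_u > 0` and not supplied.
#' @return data.frame: design columns, `year`, `y` (total biomass, g) and
#'   one `bio_<abbr>` column per species.
#' @export
simulate_year <- function(design, truth, pool, year = 1L, seed = 1L,
                          P = NULL, u_pairs = NULL) {
  if (is.null(P)) P <- planted_proportions(design, pool)
  n <- nrow(design)
  stopifnot(nrow(P) == n)
  gdat <- cbind(design[, c("block", "pattern")],
                as.data.frame(P) |> stats::setNames(pool$species$abbr))
  grp <- variance_groups(gdat, truth$variance_structure, pool)
  sd_row <- sqrt(truth$sigma2[as.character(grp)])
  with_seed(seed, {
    if (is.null(u_pairs) && truth$sigma_u > 0)
      u_pairs <- stats::rnorm(pool$S * (pool$S - 1L) / 2L, 0, truth$sigma_u)
    y <- numeric(n)
    bio <- matrix(0, n, pool$S, dimnames = list(NULL, pool$species$abbr))
    redraws <- 0L
    for (r in seq_len(n)) {
      Sp <- as.numeric(design$pattern[r] == "aggregated")
      ex <- expected_row(P[r, ], Sp, design$block[r], truth, year, u_pairs)
      total <- ex$total + stats::rnorm(1L, 0, sd_row[r])
      tries <- 0L
      while (total <= 0 && tries < 20L) {
        total <- ex$total + stats::rnorm(1L, 0, sd_row[r])
        tries <- tries + 1L
        redraws <- redraws + 1L
      }
      if (total <= 0) total <- 1e-3
      y[r] <- total
      present <- P[r, ] > 0
      sh <- ex$shares[present]
      sh <- pmax(sh, 1e-6 * sum(abs(sh)))  # clamp rare negative DE shares
      if (sum(present) == 1L) {
        bio[r, present] <- total
      } else {
        g <- stats::rgamma(sum(present),
                           shape = truth$allocation_conc * sh / sum(sh))
        if (sum(g) <= 0) g <- sh  # degenerate gamma draw: fall back to shares
        bio[r, present] <- total * g / sum(g)
      }
    }
    out <- cbind(design[, setdiff(names(design), "grid")],
                 year = year, y = y,
                 as.data.frame(bio) |>
                   stats::setNames(paste0("bio_", pool$species$abbr)))
    attr(out, "u_pairs") <- u_pairs
    attr(out, "allocation_events") <- redraws
    out
  })
}

#' Simulate a multi-year experiment
#'
#' Runs [simulate_year()] for consecutive years with pair deviations drawn
#' once and held fixed across years.  Generative proportions are either the
#' planted proportions every year (`truth_source = "planted"`) or, from year
#' 2 on, the previous simulated year's realized biomass proportions
#' (`truth_source = "realized"`).
#'
#' @inheritParams simulate_year
#' @param years number of years.
#' @param truth_source `"planted"` or `"realized"` generative proportions.
#' @return Object of class `di_sim`: list with `records` (row-bound yearly
#'   data.frames), `design`, `pool`, `truth`.
#' @export
simulate_experiment <- function(design, truth, pool, years = 3L, seed = 1L,
                                truth_source = c("planted", "realized")) {
  truth_source <- match.arg(truth_source)
  P_planted <- planted_proportions(design, pool)
  u_pairs <- NULL
  if (truth$sigma_u > 0)
    u_pairs <- with_seed(seed + 1000003L,
      stats::rnorm(pool$S * (pool$S - 1L) / 2L, 0, truth$sigma_u))
  P <- P_planted
  recs <- vector("list", years)
  for (t in seq_len(years)) {
    recs[[t]] <- simulate_year(design, truth, pool, year = t,
                               seed = seed + t, P = P, u_pairs = u_pairs)
    if (truth_source == "realized") {
      P <- realized_proportions(recs[[t]], pool)
      P[is.na(P)] <- 0
    }
  }
  structure(list(records = do.call(rbind, recs), design = design,
                 pool = pool, truth = truth), class = "di_sim")
}

#' Realized biomass proportions
#'
#' Per plot, each species' harvested biomass divided by the plot total.
#' Plots with zero total yield `NA` proportions with a warning.
#'
#' @param records a yearly data.frame from [simulate_year()] (or any frame
#'   with `bio_<abbr>` columns), or the species biomass matrix itself.
#' @param pool a [species_pool()].
#' @return n-by-S matrix of proportions; rows sum to 1 (or are `NA`).
#' @examples
#' realized_proportions(matrix(c(10, 30, 60), 1), species_pool(
#'   data.frame(name = c("a", "b", "c"), abbr = c("a", "b", "c"),
#'              functional_group = c(1, 1, 2))))
#' @export
realized_proportions <- function(records, pool) {
  bio <- if (is.matrix(records)) records
         else as.matrix(records[, paste0("bio_", pool$species$abbr)])
  tot <- rowSums(bio)
  zero <- tot <= 0
  if (any(zero)) {
    warning(sum(zero), " plot(s) with zero total biomass; proportions NA")
    tot[zero] <- NA_real_
  }
  out <- bio / tot
  colnames(out) <- pool$species$abbr
  out
}

#' Build a modeling data.frame from a simulated experiment
#'
#' Joins one simulated year's totals with reference proportions: planted
#' (counts / 64) or realized in the preceding year.
#'
#' @param sim a `di_sim` from [simulate_experiment()].
#' @param year which year's response to model.
#' @param source `"planted"` or `"realized"` reference proportions
#'   (realized requires `year >= 2`; the preceding year's biomass is used).
#' @param pool a [species_pool()].
#' @return data.frame with `plot_id`, `block`, `pattern`, `y` and one
#'   proportion column per species abbreviation, ready for
#'   [build_design_matrix()] / [fit_di_model()].
#' @export
model_data <- function(sim, year = 1L, source = c("planted", "realized"),
                       pool = sim$pool) {
  source <- match.arg(source)
  yr <- sim$records[sim$records$year == year, , drop = FALSE]
  if (!nrow(yr)) stop("no simulated records for year ", year)
  yr <- yr[match(sim$design$plot_id, yr$plot_id), , drop = FALSE]
  P <- if (source == "planted") {
    planted_proportions(sim$design, pool)
  } else {
    if (year < 2L)
      stop("realized reference proportions need a preceding year")
    prev <- sim$records[sim$records$year == year - 1L, , drop = FALSE]
    prev <- prev[match(sim$design$plot_id, prev$plot_id), , drop = FALSE]
    realized_proportions(prev, pool)
  }
  out <- data.frame(plot_id = sim$design$plot_id, block = sim$design$block,
                    pattern = sim$design$pattern, y = yr$y,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(P) |> stats::setNames(pool$species$abbr))
}

#' Parameter-recovery experiment
#'
#' Simulates repeated single-year datasets from a truth, refits the matching
#' model, and tabulates bias, empirical SE, mean reported SE and 95%
#' confidence-interval coverage per coefficient.  Optionally also runs the
#' model-selection cascade on each replicate and tabulates how often each
#' structure is chosen.
#'
#' @param truth a [di_truth()].
#' @param spec the [di_spec()] to refit (normally the truth's own form).
#' @param pool a [species_pool()].
#' @param n_replicates number of simulated datasets.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param n_blocks blocks per simulated design.
#' @param select also run [select_model()] per replicate (slower).
#' @param terms coefficient names to summarize (default: all DE terms).
#' @return list with `summary` (data.frame: term, truth, mean estimate,
#'   bias, empirical SE, mean SE, coverage) and, if `select = TRUE`,
#'   `structure_freq` (named table of selected structures).
#' @export
recovery_experiment <- function(truth, spec, pool, n_replicates = 100L,
                                seed = 1L, n_blocks = 5L, select = FALSE,
                                terms = NULL) {
  design <- build_design(pool, n_blocks = n_blocks, seed = seed)
  theta <- true_coefficients(truth, spec, pool, n_blocks)
  est <- se <- NULL
  chosen <- character(0)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_experiment(design, truth, pool, years = 1L,
                               seed = seed + r)
    dat <- model_data(sim, 1L, "planted", pool)
    fit <- fit_di_model(dat, spec, pool)
    est <- rbind(est, fit$coefficients)
    se <- rbind(se, fit$se)
    if (select) {
      tr <- select_model(dat, pool, proportion_source = "planted")
      chosen <- c(chosen, tr$final_spec$structure)
    }
  }
  if (is.null(terms)) terms <- grep("^DE_", colnames(est), value = TRUE)
  tc <- theta[match(terms, names(theta))]
  emp_se <- apply(est[, terms, drop = FALSE], 2, stats::sd)
  mean_est <- colMeans(est[, terms, drop = FALSE])
  zcrit <- stats::qt(0.975, 34 * n_blocks - length(theta))
  cover <- vapply(terms, function(tm)
    mean(abs(est[, tm] - tc[tm]) <= zcrit * se[, tm]), 1)
  out <- list(summary = data.frame(
    term = terms, truth = tc, mean_estimate = mean_est,
    bias = mean_est - tc, empirical_se = emp_se,
    mean_se = colMeans(se[, terms, drop = FALSE]),
    coverage = cover, row.names = NULL))
  if (select) out$structure_freq <- table(chosen)
  out
}

#' True coefficient vector of a truth under its matching model matrix
#'
#' Lays out `di_truth` parameters in the column order of
#' [build_design_matrix()] (year-1 scaling), for bias computations.
#'
#' @param truth a [di_truth()].
#' @param spec the matching [di_spec()].
#' @param pool a [species_pool()].
#' @param n_blocks blocks in the design the model will be fitted on.
#' @return Named numeric vector matching the design-matrix columns.
#' @export
true_coefficients <- function(truth, spec, pool, n_blocks = 5L) {
  if (truth$structure != spec$structure && truth$structure != "none")
    stop("spec structure does not match truth")
  base_len <- de_truth_length(spec$structure, pool)
  alpha <- rep(truth$alpha, length.out = n_blocks)
  theta <- c(truth$beta * truth$year_scalars[1],
             alpha[seq_len(n_blocks - 1L)])
  de <- function(v) if (is.null(v)) rep(0, base_len) else rep(v, length.out = base_len)
  if (spec$structure != "M1") {
    theta <- c(theta, de(truth$delta))
    if ("Sp" %in% spec$expansions) theta <- c(theta, de(truth$delta_Sp))
    if ("P11" %in% spec$expansions) theta <- c(theta, de(truth$delta_P11))
  }
  # name by building a tiny matching matrix
  dummy <- data.frame(block = rep(seq_len(n_blocks), 2),
                      pattern = "dispersed")
  Pd <- matrix(1 / pool$S, nrow(dummy), pool$S,
               dimnames = list(NULL, pool$species$abbr))
  mm <- build_design_matrix(cbind(dummy, as.data.frame(Pd)), spec, pool)
  stats::setNames(theta, colnames(mm$X))
}
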