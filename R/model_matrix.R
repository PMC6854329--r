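# Fixed-effects design matrices for the Diversity-Interactions model family.
#
# A DI model decomposes plot yield into identity effects (proportion-weighted
# monoculture expectations), block effects, and a diversity effect (DE) built
# from products of species proportions:
#
#   y = sum_i beta_i P_i + alpha_b + sum_{i<j} delta_ij P_i P_j + eps
#
# The family constrains delta_ij progressively:
#   M1   identity            delta_ij = 0
#   M2   average pairwise    delta_ij = delta
#   M3   additive            delta_ij = lambda_i + lambda_j
#   M4   functional group    delta_ij = omega_kl by group membership
#   FULL unconstrained       one delta_ij per pair
# The DE block can additionally interact with the planting pattern (Sp,
# coded 1 for aggregated mixtures, 0 for dispersed plots and monocultures)
# and with the focal species' proportion (P11 expansion).

DI_STRUCTURES <- c("M1", "M2", "M3", "M4", "FULL")
DI_EXPANSIONS <- c("Sp", "P11")

# ordered species pairs i < j, in combn order: (1,2),(1,3),...,(S-1,S)
pair_index <- function(S) {
  idx <- utils::combn(S, 2L)
  list(i = idx[1L, ], j = idx[2L, ])
}

#' Pairwise proportion products
#'
#' The covariates of the full pairwise DI model: one product `P_i * P_j` per
#' ordered species pair `i < j` (length `S(S-1)/2`; 120 for 16 species).
#' All entries are exactly zero for a monoculture.
#'
#' @param P proportion vector of length S, or an n-by-S matrix of rows.
#' @return Vector (or matrix with one row per input row) of pair products,
#'   named `"<i>.<j>"` by species index.
#' @param drop return a plain vector for single-composition input.
#' @examples
#' pairwise_products(c(0.5, 0.5, 0, 0))   # single nonzero entry 0.25
#' @export
pairwise_products <- function(P, drop = TRUE) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  S <- ncol(P)
  pr <- pair_index(S)
  out <- P[, pr$i, drop = FALSE] * P[, pr$j, drop = FALSE]
  colnames(out) <- paste0(pr$i, ".", pr$j)
  if (drop && nrow(out) == 1L) out[1L, ] else out
}

#' Additive species-specific interaction covariates
#'
#' Covariates of the additive DI model, in which each species carries one
#' interaction coefficient `lambda_i` and pairs interact with strength
#' `lambda_i + lambda_j`.  Entry `i` equals `P_i * sum_{j != i} P_j`, so that
#' `sum_i lambda_i * entry_i` reproduces the pair-sum
#' `sum_{i<j} (lambda_i + lambda_j) P_i P_j` for every lambda.
#'
#' @inheritParams pairwise_products
#' @return Vector (or matrix) of length/width S.
#' @examples
#' additive_covariates(rep(0.25, 4))   # four entries of 0.1875
#' @export
additive_covariates <- function(P, drop = TRUE) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  tot <- rowSums(P)
  out <- P * (tot - P)
  if (drop && nrow(out) == 1L) out[1L, ] else out
}

#' Functional-group interaction covariates
#'
#' Covariates of the functional-group DI model: for each of the
#' `T(T+1)/2` group pairs (within-group `kk` first, then between-group `kl`,
#' `k < l`), the summed proportion products over species pairs in those
#' groups.  The covariates conserve the total pair sum: they add up to
#' `sum_{i<j} P_i P_j`.
#'
#' @inheritParams pairwise_products
#' @param pool a [species_pool()] giving group membership.
#' @return Vector (or matrix) with `T(T+1)/2` entries (10 for four groups),
#'   named `FGk.k` / `FGk.l`.
#' @export
functional_group_covariates <- function(P, pool, drop = TRUE) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  stopifnot(ncol(P) == pool$S)
  T <- pool$T
  fg <- pool$fg
  gs <- sapply(seq_len(T), function(k) rowSums(P[, fg == k, drop = FALSE]))
  gs <- matrix(gs, nrow = nrow(P))  # group proportion sums
  cols <- list()
  for (k in seq_len(T)) {
    Pk <- P[, fg == k, drop = FALSE]
    # sum_{i<j in FGk} P_i P_j = (gk^2 - sum_i P_i^2) / 2
    cols[[paste0("FG", k, ".", k)]] <- (gs[, k]^2 - rowSums(Pk^2)) / 2
  }
  for (k in seq_len(T - 1L)) {
    for (l in (k + 1L):T) {
      cols[[paste0("FG", k, ".", l)]] <- gs[, k] * gs[, l]
    }
  }
  out <- do.call(cbind, cols)
  if (drop && nrow(out) == 1L) out[1L, ] else out
}

#' Specify a Diversity-Interactions model
#'
#' @param structure one of `"M1"` (identity), `"M2"` (average pairwise),
#'   `"M3"` (additive species-specific), `"M4"` (functional group),
#'   `"FULL"` (unconstrained pairwise).
#' @param expansions character subset of `c("Sp", "P11")`: interact every DE
#'   covariate with the planting-pattern indicator and/or the focal species'
#'   proportion.  `M1` has no DE terms and admits no expansions.
#' @param proportion_source `"planted"` or `"realized"`: which reference
#'   proportions the predictors use.
#' @param variance_structure residual variance grouping: `"homoscedastic"`,
#'   `"mono_vs_mixture"`, or `"mono_vs_focalmix_vs_othermix"`.
#' @param random_pairwise logical; add a shared-variance random effect for
#'   every species pair.
#' @return An object of class `di_spec`.
#' @export
di_spec <- function(structure = "M2", expansions = character(),
                    proportion_source = "planted",
                    variance_structure = "homoscedastic",
                    random_pairwise = FALSE) {
  structure <- match.arg(structure, DI_STRUCTURES)
  if (length(expansions))
    expansions <- sort(unique(match.arg(expansions, DI_EXPANSIONS,
                                        several.ok = TRUE)))
  proportion_source <- match.arg(proportion_source, c("planted", "realized"))
  variance_structure <- match.arg(variance_structure, VARIANCE_STRUCTURES)
  if (structure == "M1" && length(expansions))
    stop("M1 has no diversity-effect terms to expand")
  structure(list(structure = structure, expansions = expansions,
                 proportion_source = proportion_source,
                 variance_structure = variance_structure,
                 random_pairwise = isTRUE(random_pairwise)),
            class = "di_spec")
}

#' @export
print.di_spec <- function(x, ...) {
  cat(sprintf("DI model spec: %s%s | proportions: %s | variance: %s%s\n",
              x$structure,
              if (length(x$expansions))
                paste0(" + DE*", paste(x$expansions, collapse = " + DE*"))
              else "",
              x$proportion_source, x$variance_structure,
              if (x$random_pairwise) " | random pairwise" else ""))
  invisible(x)
}

format_spec <- function(spec) {
  paste0(spec$structure,
         if (length(spec$expansions))
           paste0("+", paste(spec$expansions, collapse = "+")) else "",
         "[", spec$proportion_source, ",", spec$variance_structure,
         if (spec$random_pairwise) ",ranpair" else "", "]")
}

# Extract and validate the proportion matrix from a modeling data.frame.
# Rows off unity by more than `hard` are an error; smaller deviations are
# renormalized (warning beyond `soft`).
proportion_matrix <- function(data, pool, soft = 1e-9, hard = 1e-3) {
  miss <- setdiff(pool$species$abbr, names(data))
  if (length(miss))
    stop("data is missing proportion columns: ", paste(miss, collapse = ", "))
  P <- as.matrix(data[, pool$species$abbr, drop = FALSE])
  if (any(P < 0)) stop("negative species proportions")
  tot <- rowSums(P)
  off <- abs(tot - 1)
  if (any(off > hard))
    stop("species proportions deviate from 1 by more than ", hard,
         " in row(s) ", paste(utils::head(which(off > hard), 5L), collapse = ", "))
  if (any(off > soft)) {
    warning(sum(off > soft), " row(s) renormalized to unit proportion sum")
  }
  P / tot
}

de_base_covariates <- function(P, structure, pool) {
  switch(structure,
    M1 = matrix(numeric(0), nrow = nrow(P), ncol = 0L),
    M2 = {
      out <- matrix(rowSums(pairwise_products(P, drop = FALSE)), ncol = 1L)
      colnames(out) <- "AV"
      out
    },
    M3 = {
      out <- additive_covariates(P, drop = FALSE)
      colnames(out) <- paste0("add_", pool$species$abbr)
      out
    },
    M4 = functional_group_covariates(P, pool, drop = FALSE),
    FULL = {
      out <- pairwise_products(P, drop = FALSE)
      pr <- pair_index(pool$S)
      colnames(out) <- paste0(pool$species$abbr[pr$i], ".",
                              pool$species$abbr[pr$j])
      out
    })
}

#' Build the fixed-effects design matrix of a DI model
#'
#' Assembles `X = [identity | block | DE_base | DE_base x Sp | DE_base x P11]`
#' for a set of plot observations.  Identity columns are the S species
#' proportions (species-specific intercepts; there is no global intercept).
#' Block effects use sum-to-zero contrasts (B - 1 columns), so identity
#' coefficients are block-average expected monoculture yields and predictions
#' at zero block columns are block averages.  Every DE column is exactly zero
#' on monoculture rows.
#'
#' @param data data.frame with columns `block`, `pattern` (`"dispersed"`,
#'   `"aggregated"` or `"monoculture"`) and one proportion column per species
#'   abbreviation.  Proportions off unit sum by more than 1e-9 are
#'   renormalized (error beyond 1e-3).
#' @param spec a [di_spec()].
#' @param pool a [species_pool()]; the `P11` expansion uses `pool$focal`.
#' @return An object of class `di_model_matrix`: list with `X` (numeric
#'   matrix), `groups` (named list of column index vectors: `identity`,
#'   `block`, `DE_base`, `DE_Sp`, `DE_P11`), `spec`, `pool`, `Sp`,
#'   `monoculture` (logical), and `block_levels`.
#' @examples
#' pool <- space_pool()
#' des <- build_design(pool, n_blocks = 5, seed = 1)
#' dat <- cbind(des[c("block", "pattern")],
#'              planted_proportions(des, pool))
#' mm <- build_design_matrix(dat, di_spec("M2", "P11"), pool)
#' ncol(mm$X)    # 16 + 4 + 2
#' @export
build_design_matrix <- function(data, spec, pool) {
  stopifnot(inherits(spec, "di_spec"))
  if (!all(c("block", "pattern") %in% names(data)))
    stop("data must have 'block' and 'pattern' columns")
  P <- proportion_matrix(data, pool)
  n <- nrow(P)
  mono <- data$pattern == "monoculture"
  # guard: a row flagged monoculture must have a single nonzero proportion
  if (any(mono & rowSums(P > 0) != 1L))
    stop("monoculture rows must have exactly one nonzero proportion")
  Sp <- as.numeric(data$pattern == "aggregated")

  id_cols <- P
  colnames(id_cols) <- paste0("ID_", pool$species$abbr)

  blk <- factor(data$block)
  B <- nlevels(blk)
  if (B > 1L) {
    blk_cols <- stats::contr.sum(B)[as.integer(blk), , drop = FALSE]
    colnames(blk_cols) <- paste0("block_", levels(blk)[-B])
  } else {
    blk_cols <- matrix(numeric(0), nrow = n, ncol = 0L)
  }

  base <- de_base_covariates(P, spec$structure, pool)
  if (ncol(base))
    colnames(base) <- paste0("DE_", colnames(base))
  pieces <- list(identity = id_cols, block = blk_cols, DE_base = base)
  if ("Sp" %in% spec$expansions) {
    sp_cols <- base * Sp
    if (ncol(sp_cols)) colnames(sp_cols) <- paste0(colnames(base), ":Sp")
    pieces$DE_Sp <- sp_cols
  }
  if ("P11" %in% spec$expansions) {
    if (is.na(pool$focal)) stop("pool has no focal species for the P11 expansion")
    p11_cols <- base * P[, pool$focal]
    if (ncol(p11_cols)) colnames(p11_cols) <- paste0(colnames(base), ":P11")
    pieces$DE_P11 <- p11_cols
  }

  X <- do.call(cbind, pieces)
  colnames(X) <- unlist(lapply(pieces, colnames))
  sizes <- vapply(pieces, ncol, 1L)
  ends <- cumsum(sizes)
  groups <- Map(function(s, e) if (e >= s) s:e else integer(0),
                c(1L, utils::head(ends, -1L) + 1L), ends)
  names(groups) <- names(pieces)
  for (g in setdiff(c("DE_Sp", "DE_P11"), names(groups)))
    groups[[g]] <- integer(0)

  structure(list(X = X, groups = groups, spec = spec, pool = pool,
                 Sp = Sp, monoculture = mono, P = P,
                 block_levels = levels(blk)),
            class = "di_model_matrix")
}

#' Number of DE columns of a model matrix
#' @param mm a `di_model_matrix`.
#' @return Integer count of diversity-effect columns (base plus expansions).
#' @export
n_de_columns <- function(mm) {
  length(mm$groups$DE_base) + length(mm$groups$DE_Sp) + length(mm$groups$DE_P11)
}
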