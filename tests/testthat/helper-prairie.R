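# Shared fixtures, built in code at test time.

the_pool <- space_pool()

# small reference designs (2 blocks keeps module tests fast; 5 blocks is the
# full study layout used by the calibration tests)
design2 <- build_design(the_pool, n_blocks = 2, seed = 42)
design5 <- build_design(the_pool, n_blocks = 5, seed = 42)

# modeling frame with planted proportions attached
planted_frame <- function(design, pool = the_pool) {
  cbind(design[c("plot_id", "block", "pattern")],
        as.data.frame(planted_proportions(design, pool)))
}

# deterministic response y = X theta (no noise) for a given spec
exact_response <- function(design, spec, theta, pool = the_pool) {
  dat <- planted_frame(design, pool)
  mm <- build_design_matrix(dat, spec, pool)
  stopifnot(length(theta) == ncol(mm$X))
  dat$y <- drop(mm$X %*% theta)
  list(data = dat, mm = mm, theta = theta)
}

# random compositions on the simplex (k species active out of S)
random_compositions <- function(n, S, seed, k = NULL) {
  with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  with_seed(seed, {
    P <- matrix(0, n, S)
    for (r in seq_len(n)) {
      kk <- if (is.null(k)) sample(2:S, 1) else k
      act <- sample.int(S, kk)
      w <- stats::rgamma(kk, 1)
      P[r, act] <- w / sum(w)
    }
    P
  })
}

# brute-force DE oracle: sum over pairs of coefficient * P_i * P_j
brute_force_de <- function(P, coef_fun) {
  S <- length(P)
  tot <- 0
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      tot <- tot + coef_fun(i, j) * P[i] * P[j]
    }
  }
  tot
}
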