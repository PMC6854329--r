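# Experimental-design generator: plots varying in richness, evenness and
# fine-scale planting pattern on an 8x8 grid of 64 planted individuals.

GRID_DIM <- 8L
N_CELLS <- 64L

# planted-count ratios per richness x evenness; each sums to 64 and every
# count is a multiple of 4, so both layout styles are always constructible
EVENNESS_RATIOS <- list(
  `2` = list(low = c(8L, 56L),
             intermediate = c(16L, 48L),
             high = c(32L, 32L)),
  `4` = list(low = c(4L, 4L, 28L, 28L),
             intermediate = c(8L, 8L, 24L, 24L),
             high = c(16L, 16L, 16L, 16L)),
  `8` = list(low = c(4L, 4L, 4L, 4L, 4L, 8L, 16L, 20L),
             intermediate = c(4L, 4L, 4L, 4L, 12L, 12L, 12L, 12L),
             high = c(8L, 8L, 8L, 8L, 8L, 8L, 8L, 8L))
)

# run expr with a private, seeded RNG stream, restoring global state after
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# sample() without its size-1 surprise (sample(5L) != always 5)
sample_vec <- function(x, size = length(x)) x[sample.int(length(x), size)]

#' Generate the randomized block design of a pattern-by-diversity experiment
#'
#' Builds the full plot list of a mixture experiment: per block, one
#' monoculture of every species plus 18 mixtures crossing richness
#' (2, 4, 8 species), planted evenness (low, intermediate, high) and
#' fine-scale planting pattern (dispersed vs. aggregated).  Each plot is an
#' 8x8 grid of 64 planted individuals.  Species are assigned to mixtures at
#' random under functional-group constraints: a 2-species plot pairs one
#' grass (warm- or cool-season) with one forb or legume, a 4-species plot
#' takes one species per functional group, an 8-species plot two per group.
#' Within a plot, species are randomly assigned to the abundance ranks of the
#' evenness ratio.  The same composition is used for the dispersed and
#' aggregated plot of a block/richness/evenness combination, so the pattern
#' treatment is compared at equal composition.
#'
#' @param pool a [species_pool()] with equal-sized functional groups.
#' @param n_blocks number of complete blocks (the reference design uses 5).
#' @param seed integer seed controlling all randomization.
#' @return A data.frame of class `di_design` with one row per plot: columns
#'   `plot_id`, `block`, `richness`, `evenness`, `pattern`, one planted-count
#'   column per species abbreviation, and `grid` (the 64 cell species
#'   indices, row-major, dash-separated).
#' @examples
#' des <- build_design(space_pool(), n_blocks = 5, seed = 1)
#' nrow(des)                               # 170
#' table(des$pattern[des$block == 1])
#' @export
build_design <- function(pool, n_blocks = 5L, seed = 1L) {
  check_balanced_pool(pool)
  stopifnot(n_blocks >= 1L)
  per_fg <- pool$S / pool$T
  if (pool$S < 8L) stop("pool too small for 8-species mixtures")
  fg_members <- split(seq_len(pool$S), pool$fg)

  with_seed(seed, {
    rows <- list()
    for (b in seq_len(n_blocks)) {
      # monocultures: one per species
      for (i in seq_len(pool$S)) {
        counts <- integer(pool$S)
        counts[i] <- N_CELLS
        grid <- matrix(i, GRID_DIM, GRID_DIM)
        rows[[length(rows) + 1L]] <- list(
          block = b, richness = 1L, evenness = "monoculture",
          pattern = "monoculture", counts = counts, grid = grid)
      }
      # mixtures: richness x evenness, composition shared across patterns
      for (r in c(2L, 4L, 8L)) {
        for (ev in c("low", "intermediate", "high")) {
          members <- switch(as.character(r),
            `2` = c(sample_vec(unlist(fg_members[1:2]), 1L),
                    sample_vec(unlist(fg_members[3:4]), 1L)),
            `4` = vapply(fg_members, function(m) sample_vec(m, 1L), 1L),
            `8` = unlist(lapply(fg_members, sample_vec, size = 2L)))
          ratio <- EVENNESS_RATIOS[[as.character(r)]][[ev]]
          # random assignment of species to abundance ranks
          members <- sample_vec(members)
          counts <- integer(pool$S)
          counts[members] <- ratio
          for (pat in c("dispersed", "aggregated")) {
            grid <- if (pat == "dispersed") dispersed_layout(counts)
                    else aggregate_pattern_layout(counts)
            rows[[length(rows) + 1L]] <- list(
              block = b, richness = r, evenness = ev,
              pattern = pat, counts = counts, grid = grid)
          }
        }
      }
    }
    design_frame(rows, pool)
  })
}

design_frame <- function(rows, pool) {
  counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
  colnames(counts) <- pool$species$abbr
  out <- data.frame(
    plot_id = sprintf("P%03d", seq_along(rows)),
    block = vapply(rows, `[[`, 1L, "block"),
    richness = vapply(rows, `[[`, 1L, "richness"),
    evenness = vapply(rows, `[[`, "", "evenness"),
    pattern = vapply(rows, `[[`, "", "pattern"),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(counts))
  out$grid <- vapply(rows, function(r) paste(t(r$grid), collapse = "-"), "")
  class(out) <- c("di_design", "data.frame")
  out
}

#' Random dispersed planting layout
#'
#' Assigns each of the 64 grid cells a species uniformly at random subject to
#' the planted counts, so conspecifics are interspersed.
#'
#' @param counts integer vector of planted individuals per species (length S,
#'   zeros allowed), summing to 64.
#' @return 8x8 integer matrix of species indices.
#' @export
dispersed_layout <- function(counts) {
  stopifnot(sum(counts) == N_CELLS)
  cells <- sample_vec(rep(seq_along(counts), counts))
  matrix(cells, GRID_DIM, GRID_DIM, byrow = TRUE)
}

#' Aggregated planting layout from 2x2 conspecific squares
#'
#' Tiles the 8x8 grid with sixteen disjoint 2x2 squares and assigns each
#' square a single species, so each species occupies `count/4` contiguous
#' squares.  This concentrates conspecific nearest-neighbor contacts relative
#' to the dispersed layout.  Requires every count to be a multiple of 4.
#'
#' @inheritParams dispersed_layout
#' @return 8x8 integer matrix of species indices.
#' @export
aggregate_pattern_layout <- function(counts) {
  stopifnot(sum(counts) == N_CELLS)
  if (any(counts %% 4L != 0L))
    stop("aggregated layout undefined: planted counts must be multiples of 4")
  squares <- sample_vec(rep(seq_along(counts), counts %/% 4L))  # 16 squares
  grid <- matrix(0L, GRID_DIM, GRID_DIM)
  k <- 0L
  for (sr in seq_len(GRID_DIM / 2L)) {
    for (sc in seq_len(GRID_DIM / 2L)) {
      k <- k + 1L
      grid[(2L * sr - 1L):(2L * sr), (2L * sc - 1L):(2L * sc)] <- squares[k]
    }
  }
  grid
}

#' Planted proportions of a design
#'
#' Converts planted counts to proportions of the 64 grid cells, the
#' "planted proportion" predictor of the DI models.
#'
#' @param design a `di_design` data.frame (or any data.frame carrying the
#'   per-species count columns).
#' @param pool the matching [species_pool()].
#' @return Numeric matrix, one row per plot and one column per species; each
#'   row sums to 1.
#' @examples
#' des <- build_design(space_pool(), n_blocks = 1, seed = 1)
#' P <- planted_proportions(des, space_pool())
#' range(rowSums(P))   # 1 1
#' @export
planted_proportions <- function(design, pool) {
  counts <- as.matrix(design[, pool$species$abbr, drop = FALSE])
  bad <- which(rowSums(counts) != N_CELLS)
  if (length(bad))
    stop("planted counts must sum to 64; violated in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  P <- counts / N_CELLS
  rownames(P) <- design$plot_id
  P
}

#' Parse a serialized plot grid back to a matrix
#'
#' @param grid_string 64 dash-separated species indices, row-major.
#' @return 8x8 integer matrix.
#' @export
parse_grid <- function(grid_string) {
  cells <- as.integer(strsplit(grid_string, "-", fixed = TRUE)[[1]])
  stopifnot(length(cells) == N_CELLS)
  matrix(cells, GRID_DIM, GRID_DIM, byrow = TRUE)
}

#' Conspecific nearest-neighbor fraction of a planting grid
#'
#' For each cell, the fraction of its rook (4-neighborhood) neighbors planted
#' with the same species, averaged over all 64 cells.  The aggregated layout
#' is designed to raise this fraction relative to the dispersed layout at
#' equal composition.
#'
#' @param grid 8x8 integer matrix of species indices (or a serialized grid
#'   string as stored in a `di_design`).
#' @return Scalar in `[0, 1]`.
#' @export
conspecific_neighbor_fraction <- function(grid) {
  if (is.character(grid)) grid <- parse_grid(grid)
  n <- nrow(grid)
  same <- 0
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      nb <- rbind(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
      nb <- nb[nb[, 1] >= 1L & nb[, 1] <= n & nb[, 2] >= 1L & nb[, 2] <= n, ,
               drop = FALSE]
      vals <- grid[nb]
      same <- same + sum(vals == grid[i, j])
      total <- total + length(vals)
    }
  }
  same / total
}
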