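#' Construct a species pool
#'
#' A species pool describes the candidate species of a mixture experiment:
#' their names, abbreviations and functional-group membership, plus an
#' optional focal species whose proportion can modify diversity effects.
#'
#' @param species data.frame with columns `name`, `abbr` and
#'   `functional_group` (integer codes `1..T` or a factor).  Row order fixes
#'   the species indices `1..S`.
#' @param fg_names optional character vector of functional-group labels.
#' @param focal index of the focal species, or `NA` for none.
#'
#' @return An object of class `species_pool`: a list with elements
#'   `species` (data.frame), `S`, `T`, `fg` (integer vector of group codes),
#'   `fg_names` and `focal`.
#' @seealso [space_pool()] for the 16-species tallgrass prairie pool.
#' @export
species_pool <- function(species, fg_names = NULL, focal = NA_integer_) {
  stopifnot(is.data.frame(species),
            all(c("name", "abbr", "functional_group") %in% names(species)))
  fg <- as.integer(factor(species$functional_group,
                          levels = unique(species$functional_group)))
  S <- nrow(species)
  T <- length(unique(fg))
  if (anyDuplicated(species$abbr))
    stop("species abbreviations must be unique")
  if (!is.na(focal) && (focal < 1L || focal > S))
    stop("focal index out of range")
  if (is.null(fg_names)) fg_names <- as.character(unique(species$functional_group))
  structure(list(species = species, S = S, T = T, fg = fg,
                 fg_names = fg_names, focal = as.integer(focal)),
            class = "species_pool")
}

#' The 16-species tallgrass prairie pool
#'
#' The pool used throughout the package's worked examples: 16 common
#' tallgrass prairie species in four functional groups of four members each
#' (warm-season grasses, cool-season grasses, forbs, legumes).  The focal
#' species is *Helianthus maximiliani* (Maximilian sunflower, species 11),
#' whose proportion can scale diversity effects in expanded models.
#'
#' @return A [species_pool()] with `S = 16`, `T = 4`, `focal = 11`.
#' @examples
#' pool <- space_pool()
#' pool$S                      # 16
#' table(pool$fg)              # four groups of four
#' pool$species$abbr[pool$focal]  # "HM"
#' @export
space_pool <- function() {
  sp <- data.frame(
    name = c("Andropogon gerardii", "Schizachyrium scoparium",
             "Sorghastrum nutans", "Panicum virgatum",
             "Elymus canadensis", "Elymus trachycaulus",
             "Pascopyrum smithii", "Nassella viridula",
             "Monarda fistulosa", "Solidago rigida",
             "Helianthus maximiliani", "Ratibida columnifera",
             "Desmodium canadense", "Astragalus canadensis",
             "Dalea purpurea", "Glycyrrhiza lepidota"),
    abbr = c("AG", "SS", "SN", "PV", "EC", "ET", "PS", "NV",
             "MF", "SR", "HM", "RC", "DC", "AC", "DP", "GL"),
    functional_group = rep(1:4, each = 4),
    stringsAsFactors = FALSE
  )
  species_pool(sp,
               fg_names = c("warm-season grass", "cool-season grass",
                            "forb", "legume"),
               focal = 11L)
}

#' @export
print.species_pool <- function(x, ...) {
  cat("Species pool:", x$S, "species in", x$T, "functional groups\n")
  if (!is.na(x$focal))
    cat("Focal species:", x$species$name[x$focal],
        sprintf("(%s, index %d)\n", x$species$abbr[x$focal], x$focal))
  print(x$species)
  invisible(x)
}

# check the pool satisfies the balanced 4x4 layout assumed by the design
# generator (S species split evenly across T groups)
check_balanced_pool <- function(pool) {
  if (!inherits(pool, "species_pool")) stop("not a species_pool")
  sizes <- tabulate(pool$fg, nbins = pool$T)
  if (length(unique(sizes)) != 1L)
    stop("design generation requires equal-sized functional groups; got ",
         paste(sizes, collapse = ", "))
  invisible(pool)
}
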