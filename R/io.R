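# Delimited-text input/output: designs, simulated plot records, fit
# reports.  CSV, UTF-8, mandatory header; species columns keyed by
# abbreviation.

#' Write / read an experimental design
#'
#' One row per plot: `plot_id`, `block`, `richness`, `evenness`, `pattern`,
#' a planted-count column per species abbreviation, and the serialized
#' 64-cell grid.
#'
#' @param design a `di_design` from [build_design()].
#' @param path file path.
#' @return `write_design` returns `path` invisibly; `read_design` the
#'   design data.frame.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @param pool a [species_pool()] used to validate the count columns.
#' @export
read_design <- function(path, pool) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("plot_id", "block", "richness", "evenness", "pattern",
            pool$species$abbr)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design file missing column(s): ", paste(miss, collapse = ", "))
  counts <- as.matrix(d[, pool$species$abbr])
  bad <- which(rowSums(counts) != 64L)
  if (length(bad))
    stop("planted counts must sum to 64; violated at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  class(d) <- c("di_design", "data.frame")
  d
}

#' Write / read plot-year records
#'
#' Long-format species biomass: one row per plot-year-species with columns
#' `plot_id`, `block`, `year`, `pattern`, `abbr`, `biomass_g`, plus the
#' plot's planted count for that species (`count`).  Totals are recomputed
#' on read, so the wide modeling table never stores redundant sums.
#'
#' @param records wide yearly records from [simulate_year()] /
#'   [simulate_experiment()] (`$records`).
#' @param design the matching `di_design`.
#' @param pool a [species_pool()].
#' @param path file path.
#' @return `write_plot_data` returns `path` invisibly.
#' @export
write_plot_data <- function(records, design, pool, path) {
  abbr <- pool$species$abbr
  rows <- lapply(seq_len(nrow(records)), function(r) {
    des <- design[design$plot_id == records$plot_id[r], ]
    data.frame(plot_id = records$plot_id[r], block = records$block[r],
               year = records$year[r], pattern = records$pattern[r],
               abbr = abbr,
               count = as.integer(des[1, abbr]),
               biomass_g = as.numeric(records[r, paste0("bio_", abbr)]),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  long <- long[long$count > 0 | long$biomass_g > 0, ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plot_data
#' @return `read_plot_data` returns a list with `records` (wide, one row
#'   per plot-year: totals and `bio_<abbr>` columns) and `counts` (wide
#'   planted counts per plot).
#' @export
read_plot_data <- function(path, pool) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("plot_id", "block", "year", "pattern", "abbr", "count",
            "biomass_g")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop("plot data file missing column(s): ", paste(miss, collapse = ", "))
  if (any(long$biomass_g < 0))
    stop("negative biomass at row(s) ",
         paste(utils::head(which(long$biomass_g < 0), 5L), collapse = ", "))
  bad_sp <- setdiff(unique(long$abbr), pool$species$abbr)
  if (length(bad_sp))
    stop("unknown species abbreviation(s): ", paste(bad_sp, collapse = ", "))
  key <- paste(long$plot_id, long$year, long$abbr)
  if (anyDuplicated(key))
    stop("duplicate plot-year-species row(s), e.g. row ",
         which(duplicated(key))[1L])
  abbr <- pool$species$abbr
  wide_one <- function(df) {
    bio <- stats::setNames(numeric(pool$S), abbr)
    bio[df$abbr] <- df$biomass_g
    cbind(data.frame(plot_id = df$plot_id[1L], block = df$block[1L],
                     year = df$year[1L], pattern = df$pattern[1L],
                     y = sum(bio), stringsAsFactors = FALSE),
          as.data.frame(t(bio)) |> stats::setNames(paste0("bio_", abbr)))
  }
  pieces <- split(long, paste(long$plot_id, long$year))
  records <- do.call(rbind, lapply(pieces, wide_one))
  rownames(records) <- NULL
  records <- records[order(records$year, records$plot_id), ]
  counts_long <- long[long$year == min(long$year), ]
  cpieces <- split(counts_long, counts_long$plot_id)
  counts <- do.call(rbind, lapply(cpieces, function(df) {
    cnt <- stats::setNames(integer(pool$S), abbr)
    cnt[df$abbr] <- df$count
    cbind(data.frame(plot_id = df$plot_id[1L], stringsAsFactors = FALSE),
          as.data.frame(t(cnt)))
  }))
  rownames(counts) <- NULL
  bad <- which(rowSums(counts[, abbr]) != 64L)
  if (length(bad))
    stop("planted counts must sum to 64; violated for plot(s) ",
         paste(utils::head(counts$plot_id[bad], 5L), collapse = ", "))
  list(records = records, counts = counts)
}

#' Plain-text report of a fitted DI model
#'
#' Writes the coefficient table, variance estimates and fit statistics as a
#' small JSON-like text block plus a CSV coefficient table.
#'
#' @param fit a `di_fit`.
#' @param path_report path for the text report.
#' @param path_coefs optional path for the coefficient CSV.
#' @return `path_report`, invisibly.
#' @export
write_fit_report <- function(fit, path_report, path_coefs = NULL) {
  con <- file(path_report, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("{")
  w('  "n": %d,', fit$n)
  w('  "n_fixed": %d,', fit$n_fixed)
  w('  "rank": %d,', fit$rank)
  w('  "loglik_ML": %.6f,', fit$loglik_ML)
  w('  "loglik_REML": %.6f,', fit$loglik_REML)
  w('  "AIC": %.6f,', fit$aic)
  w('  "sigma2": {%s},',
    paste(sprintf('"%s": %.6f', names(fit$sigma2), fit$sigma2),
          collapse = ", "))
  w('  "sigma2_u": %.6f', fit$sigma2_u)
  w("}")
  if (!is.null(path_coefs))
    utils::write.csv(coef_table(fit), path_coefs, row.names = FALSE)
  invisible(path_report)
}
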