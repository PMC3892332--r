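#' Species occurrence records
#'
#' A thin data-frame wrapper holding presence points for one species:
#' columns `species`, `lon`, `lat`, `source` and optional `region` (a state
#' or country label used for thinning).  True absences are deliberately not
#' representable — absence information only ever enters the workflow as
#' randomly sampled pseudo-absences.
#'
#' @param species species name (single string).
#' @param lon,lat numeric coordinates in decimal degrees.
#' @param source per-point provenance tag (recycled).
#' @param region optional per-point region label (recycled; `NA` allowed).
#' @return an object of class `occurrence_set` (also a data.frame).
#' @export
occurrence_set <- function(species, lon, lat, source = "unknown", region = NA_character_) {
  stopifnot(is.character(species), length(species) == 1L,
            length(lon) == length(lat))
  df <- data.frame(species = species, lon = as.numeric(lon), lat = as.numeric(lat),
                   source = rep_len(as.character(source), length(lon)),
                   region = rep_len(as.character(region), length(lon)),
                   stringsAsFactors = FALSE)
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' Read / write occurrence CSV tables
#'
#' CSV layout: columns `species`, `lon`, `lat`, optional `source`, `region`.
#'
#' @param path CSV file path.
#' @return [occurrence_set] (for `read_occurrences`).
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns species, lon, lat")
  occurrence_set(df$species[1L], df$lon, df$lat,
                 source = if ("source" %in% names(df)) df$source else "unknown",
                 region = if ("region" %in% names(df)) df$region else NA_character_)
}

#' @rdname read_occurrences
#' @param occ an [occurrence_set].
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' Clean occurrence records against a predictor stack
#'
#' Applies the three standard cleaning rules, in order: (1) drop records with
#' invalid coordinates (non-finite, |lon| > 180, |lat| > 90); (2) drop
#' records falling outside the stack extent or on a cell that is invalid in
#' any layer (e.g. sea cells); (3) deduplicate to at most one record per grid
#' cell, keeping the first by input order.  The removal counts per rule are
#' attached as attribute `"cleaning_log"`.
#'
#' @param occ an [occurrence_set].
#' @param stack a [predictor_stack].
#' @return the cleaned [occurrence_set]; errors if nothing survives, since
#'   such a species cannot be modelled.
#' @export
clean_occurrences <- function(occ, stack) {
  n0 <- nrow(occ)
  good_coord <- is.finite(occ$lon) & is.finite(occ$lat) &
    occ$lon >= -180 & occ$lon <= 180 & occ$lat >= -90 & occ$lat <= 90
  occ1 <- occ[good_coord, , drop = FALSE]
  ex <- extract_values(stack, occ1$lon, occ1$lat)
  occ2 <- occ1[ex$valid, , drop = FALSE]
  idx <- cell_index(stack$layers[[1L]], occ2$lon, occ2$lat)
  cell <- paste(idx[, "row"], idx[, "col"])
  keep <- !duplicated(cell)
  out <- occ2[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    stop("no occurrence records survive cleaning; the species cannot be modelled")
  attr(out, "cleaning_log") <- c(bad_coordinates = n0 - nrow(occ1),
                                 invalid_cell = nrow(occ1) - nrow(occ2),
                                 duplicate_cell = nrow(occ2) - nrow(out))
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Thin oversampled regions to a per-region quota
#'
#' Regions (states or countries) with heavy sampling effort can dominate a
#' model's view of the niche; this caps every labelled region at `quota`
#' points, chosen uniformly at random without replacement.  Unlabelled points
#' (`NA` region) are never touched.  The default quota is the median point
#' count across labelled regions, so only clearly oversampled regions lose
#' records.
#'
#' @param occ an [occurrence_set] with region labels.
#' @param quota maximum points retained per region (>= 1).
#' @param seed RNG seed; the same seed reproduces the same selection.
#' @return thinned [occurrence_set].
#' @export
thin_by_region <- function(occ, quota = NULL, seed = 1L) {
  labelled <- !is.na(occ$region)
  if (!any(labelled)) return(occ)
  counts <- table(occ$region[labelled])
  if (is.null(quota)) quota <- as.integer(ceiling(stats::median(counts)))
  if (!is.numeric(quota) || quota < 1) stop("quota must be at least 1")
  keep <- rep(TRUE, nrow(occ))
  with_seed(seed, {
    for (reg in names(counts)) {
      rows <- which(labelled & occ$region == reg)
      if (length(rows) > quota)
        keep[setdiff(rows, sample(rows, quota))] <- FALSE
    }
  })
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Screen predictor collinearity at occurrence points
#'
#' Computes the pairwise Pearson correlation matrix of the predictor values
#' extracted at the supplied points and checks every off-diagonal |r| against
#' the threshold.  Correlated predictors inflate coefficient variance and can
#' distort projected suitability, so the workflow refuses stacks failing the
#' screen (default |r| < 0.7).
#'
#' @param stack a [predictor_stack].
#' @param lon,lat point coordinates (>= 3 valid points required).
#' @param threshold collinearity threshold on |r|.
#' @return object of class `collinearity_report`: list with `r` (p x p
#'   matrix), `threshold`, `pass`, and `failure_cause` (`NULL` when
#'   computable; a constant predictor makes its correlations undefined and
#'   the report fails with that cause).
#' @export
collinearity_report <- function(stack, lon, lat, threshold = 0.7) {
  ex <- extract_values(stack, lon, lat)
  X <- ex$values[ex$valid, , drop = FALSE]
  if (nrow(X) < 3L) stop("collinearity screen needs at least 3 valid points")
  sds <- apply(X, 2L, stats::sd)
  out <- list(predictors = colnames(X), threshold = threshold,
              n_points = nrow(X), failure_cause = NULL)
  if (any(sds == 0)) {
    out$r <- matrix(NA_real_, ncol(X), ncol(X),
                    dimnames = list(colnames(X), colnames(X)))
    diag(out$r) <- 1
    out$pass <- FALSE
    out$failure_cause <- paste0("predictor constant at the points: ",
                                paste(colnames(X)[sds == 0], collapse = ", "))
  } else {
    out$r <- stats::cor(X, method = "pearson")
    off <- abs(out$r[upper.tri(out$r)])
    out$pass <- all(off < threshold)
  }
  class(out) <- "collinearity_report"
  out
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat(sprintf("<collinearity_report> %d predictors at %d points, |r| < %.2f: %s\n",
              length(x$predictors), x$n_points, x$threshold,
              if (x$pass) "PASS" else "FAIL"))
  if (!is.null(x$failure_cause)) cat("  cause:", x$failure_cause, "\n")
  print(round(x$r, 3))
  invisible(x)
}
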