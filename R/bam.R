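#' Combine symbiont (A) and host (B) binary suitability maps
#'
#' The BAM framework decomposes a species' geography into the abiotically
#' suitable area A, the biotically suitable area B and the accessible area
#' M.  Here A is the symbiont's climatically suitable area, B the host's
#' (host availability standing in for the biotic factor), and M is assumed
#' to cover the whole study window (no dispersal barriers).  The subtraction
#' raster operation yields:
#'
#' * `g_bi = A \ B` — climatically suitable for the symbiont but without
#'   the host: the zone where the symbiont is restricted by host
#'   availability;
#' * `bi = B \ A` — host present but climate unsuitable: the zone where the
#'   symbiont is restricted by its own climatic tolerance;
#' * `overlap = A` \eqn{\cap} `B` — the estimate of the jointly suitable
#'   (occupiable) area under the total-mobility assumption.
#'
#' Cells invalid in either map are excluded from every part and from the
#' union denominator.
#'
#' @param A,B binary [bam_grid]s on identical lattices.
#' @param epsilon emptiness tolerance forwarded to [diagnose_bam].
#' @return object of class `bam_result`: list with grids `A`, `B`, `g_bi`,
#'   `bi`, `overlap` (binary, on the shared mask), `counts` (named cell
#'   counts incl. `union`), `shares` (list with `cell_count` and
#'   `cos_latitude` proportions of g_bi/bi/overlap over the union), and
#'   `diagnosis` (see [diagnose_bam]).
#' @export
bam_combine <- function(A, B, epsilon = 0.01) {
  if (A$kind != "binary" || B$kind != "binary")
    stop("bam_combine expects binary grids")
  if (!isTRUE(all.equal(A$extent, B$extent)) ||
      !isTRUE(all.equal(A$resolution, B$resolution)) ||
      !identical(dim(A$values), dim(B$values)))
    stop("A and B are not on identical lattices")
  mask <- A$mask & B$mask
  if (!any(mask)) stop("shared valid mask is empty")
  a <- A$values == 1 & mask
  b <- B$values == 1 & mask
  g_bi <- a & !b
  bi <- b & !a
  ov <- a & b
  as_grid <- function(x) {
    v <- matrix(NA_real_, nrow(x), ncol(x))
    v[mask] <- as.numeric(x[mask])
    bam_grid(v, A$extent, A$resolution, mask = mask, kind = "binary")
  }
  counts <- c(A = sum(a), B = sum(b), g_bi = sum(g_bi), bi = sum(bi),
              overlap = sum(ov), union = sum(a | b))
  res <- structure(
    list(A = as_grid(a), B = as_grid(b), g_bi = as_grid(g_bi),
         bi = as_grid(bi), overlap = as_grid(ov),
         counts = counts, shares = NULL, epsilon = epsilon,
         diagnosis = NA_character_),
    class = "bam_result")
  res$shares <- list(cell_count = area_proportions(res, "cell_count"),
                     cos_latitude = area_proportions(res, "cos_latitude"))
  res$diagnosis <- diagnose_bam(res, epsilon = epsilon)
  res
}

#' Area shares of the BAM parts
#'
#' Proportions of `g_bi`, `bi` and `overlap` over the union A \eqn{\cup} B.
#' `cell_count` weights every cell equally; `cos_latitude` weights each cell
#' by the cosine of its center latitude, approximating equal-area measure on
#' the lon/lat lattice (cells shrink towards the poles), which is the
#' appropriate basis for judging "relative proportion" of geographic area.
#'
#' @param result a [bam_combine] result.
#' @param weighting `"cell_count"` or `"cos_latitude"`.
#' @return named numeric: `g_bi`, `bi`, `overlap` (summing to 1).
#' @export
area_proportions <- function(result, weighting = c("cell_count", "cos_latitude")) {
  weighting <- match.arg(weighting)
  parts <- list(g_bi = result$g_bi, bi = result$bi, overlap = result$overlap)
  g1 <- result$g_bi
  w <- matrix(1, nrow(g1$values), ncol(g1$values))
  if (weighting == "cos_latitude") {
    lat <- grid_lat_centers(g1)
    w <- matrix(cos(lat * pi / 180), nrow(g1$values), ncol(g1$values))
  }
  tot <- vapply(parts, function(p) sum(w[p$mask & p$values == 1], na.rm = TRUE),
                numeric(1L))
  if (sum(tot) == 0) stop("A union B is empty; proportions undefined")
  tot / sum(tot)
}

#' Diagnose the BAM interaction case
#'
#' Only three configurations of A and B are possible when both are
#' non-empty: (1) B inside A (`B_subset_A`: the symbiont's climatic range
#' contains the host's, so only g_bi appears); (2) A inside B
#' (`A_subset_B`: the symbiont is the climatically narrower partner, only
#' bi appears); (3) partial overlap (both g_bi and bi present).  Because
#' estimated maps are never exactly empty, a part whose union share falls
#' below `epsilon` is treated as empty.  Degenerate inputs get the two
#' extra labels `equal` (both differences empty) and `disjoint` (no
#' overlap), so the function is total.
#'
#' @param result a [bam_combine] result.
#' @param epsilon emptiness tolerance on union shares (default 1%).
#' @param weighting which share weighting to diagnose on.
#' @return one of `"B_subset_A"`, `"A_subset_B"`, `"partial_overlap"`,
#'   `"equal"`, `"disjoint"`.
#' @export
diagnose_bam <- function(result, epsilon = 0.01,
                         weighting = c("cell_count", "cos_latitude")) {
  weighting <- match.arg(weighting)
  sh <- if (!is.null(result$shares)) result$shares[[weighting]]
        else area_proportions(result, weighting)
  g <- sh[["g_bi"]]; b <- sh[["bi"]]; ov <- sh[["overlap"]]
  if (g < epsilon && b < epsilon) return("equal")
  if (ov == 0 && g >= epsilon && b >= epsilon) return("disjoint")
  if (b < epsilon) return("B_subset_A")
  if (g < epsilon) return("A_subset_B")
  "partial_overlap"
}

#' @export
print.bam_result <- function(x, ...) {
  cat("<bam_result>\n")
  cat(sprintf("  cells: |A| = %d, |B| = %d, union = %d\n",
              x$counts[["A"]], x$counts[["B"]], x$counts[["union"]]))
  s <- x$shares$cell_count
  cat(sprintf("  shares (cell count): g_bi %.3f, bi %.3f, overlap %.3f\n",
              s[["g_bi"]], s[["bi"]], s[["overlap"]]))
  s <- x$shares$cos_latitude
  cat(sprintf("  shares (cos lat)   : g_bi %.3f, bi %.3f, overlap %.3f\n",
              s[["g_bi"]], s[["bi"]], s[["overlap"]]))
  cat(sprintf("  diagnosis (epsilon %.3g): %s\n", x$epsilon, x$diagnosis))
  invisible(x)
}

#' Write the parts of a BAM result to disk
#'
#' Writes the five binary grids as ESRI ASCII files plus a `summary.json`
#' holding counts, both share weightings, epsilon and the diagnosis.
#'
#' @param result a [bam_combine] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bam_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("A", "B", "g_bi", "bi", "overlap"))
    write_grid(result[[nm]], file.path(dir, paste0(nm, ".asc")))
  jsonlite::write_json(
    list(counts = as.list(result$counts),
         shares = lapply(result$shares, as.list),
         epsilon = result$epsilon, diagnosis = result$diagnosis),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
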