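# Virtual-species simulator: spatially autocorrelated climate predictors,
# parametric niche responses with known true suitability, occurrence
# sampling proportional to suitability, and symbiont-host niche pairs whose
# true BAM configuration is controlled by construction.  Everything is
# deterministic under (seed, parameters), so the whole modelling workflow
# can be validated against known ground truth without external downloads.

# Box-blur a matrix (separable, two passes) with reflective edge padding.
smooth_field <- function(m, halfwidth = 3L, passes = 2L) {
  k <- as.integer(halfwidth)
  if (k < 1L) return(m)
  blur1d <- function(x) {
    n <- length(x)
    xp <- c(rev(x[seq_len(k)]), x, rev(x[(n - k + 1L):n]))
    stats::filter(xp, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)[(k + 1L):(k + n)]
  }
  for (i in seq_len(passes)) {
    m <- apply(m, 2L, blur1d)
    m <- t(apply(m, 1L, blur1d))
  }
  m
}

#' Generate a synthetic climate predictor stack
#'
#' Builds `n_predictors` spatially autocorrelated fields (box-smoothed
#' Gaussian noise) over a regular lon/lat lattice, each with a mild,
#' distinct large-scale gradient and a realistic range: minimum temperature
#' of the coldest month (`MinT`, degC, latitudinal gradient), maximum
#' temperature of the warmest month (`MaxT`, degC, weak latitudinal
#' gradient), annual precipitation (`AnPrec`, mm, longitudinal gradient)
#' and precipitation seasonality (`PrecSeas`, CV %, no gradient).
#' Gradients are deliberately weak relative to the smoothed noise so the
#' layers stay weakly correlated; the stack is regenerated under rotated
#' seeds until every pairwise |r| over valid cells is at most
#' `max_pairwise_r`, mirroring the collinearity screen applied to real
#' predictors.
#'
#' @param seed RNG seed; the same seed yields a bit-identical stack.
#' @param shape `c(rows, cols)`, at least 20 x 20.
#' @param resolution cell size in degrees.
#' @param origin `c(lon_min, lat_min)` of the lattice.
#' @param n_predictors number of layers (first four get the named
#'   climates; extras are generic smoothed fields).
#' @param smoothness box-blur half-width in cells.
#' @param max_pairwise_r collinearity bound enforced by regeneration.
#' @return a [predictor_stack].
#' @export
generate_climate_stack <- function(seed = 1L, shape = c(60L, 60L),
                                   resolution = 0.5, origin = c(-10, 30),
                                   n_predictors = 4L, smoothness = 3L,
                                   max_pairwise_r = 0.7) {
  if (any(shape < 20L)) stop("shape must be at least 20 x 20")
  nr <- shape[1L]; nc <- shape[2L]
  extent <- c(origin[1L], origin[1L] + nc * resolution,
              origin[2L], origin[2L] + nr * resolution)
  lat <- matrix(rep(extent[4L] - (seq_len(nr) - 0.5) * resolution, nc), nr, nc)
  lon <- matrix(rep(extent[1L] + (seq_len(nc) - 0.5) * resolution, each = nr), nr, nc)
  lat01 <- (lat - extent[3L]) / (extent[4L] - extent[3L])
  lon01 <- (lon - extent[1L]) / (extent[2L] - extent[1L])
  specs <- list(
    MinT = function(z) 10 - 18 * lat01 + 6 * z,
    MaxT = function(z) 32 - 8 * lat01 + 6 * z,
    AnPrec = function(z) pmax(900 - 500 * lon01 + 350 * z, 0),
    PrecSeas = function(z) pmax(45 + 18 * z, 2))
  nm <- names(specs)
  if (n_predictors > 4L) {
    extra <- paste0("Pred", seq(5L, n_predictors))
    for (e in extra) specs[[e]] <- function(z) z
    nm <- c(nm, extra)
  }
  nm <- nm[seq_len(n_predictors)]
  for (attempt in seq_len(50L)) {
    layers <- list()
    for (j in seq_along(nm)) {
      z <- with_seed(derive_seed(seed, attempt, j, 77L),
                     matrix(stats::rnorm(nr * nc), nr, nc))
      z <- smooth_field(z, smoothness)
      z <- (z - mean(z)) / stats::sd(z)
      layers[[nm[j]]] <- bam_grid(specs[[nm[j]]](z), extent, resolution)
    }
    st <- predictor_stack(layers)
    X <- do.call(cbind, lapply(st$layers, function(g) g$values[g$mask]))
    r <- stats::cor(X)
    if (all(abs(r[upper.tri(r)]) <= max_pairwise_r)) return(st)
  }
  stop("could not generate a stack meeting the collinearity bound in 50 attempts")
}

#' Parametric niche response set
#'
#' A virtual species' niche is a set of per-predictor response functions
#' combined multiplicatively (limiting-factor style, so suitability stays in
#' \[0, 1\] and is 1 only where every predictor sits at its optimum).
#' Responses are either Gaussian (`optimum`, `breadth` = the Gaussian sd) or
#' logistic (`inflection`, `slope`, `direction` +1/-1; value 0.5 exactly at
#' the inflection).
#'
#' The default `presence_threshold = NULL` resolves, when the niche is
#' evaluated on a stack, to the *mean suitability over valid cells*.  This
#' prevalence-consistent choice makes the ground truth self-consistent with
#' the estimation procedure: under uniform background sampling, the
#' sensitivity+specificity-optimal ROC threshold converges to the landscape
#' mean of the suitability surface, so an ideal model binarised by the
#' workflow recovers exactly this range.
#'
#' @param responses named list (one entry per predictor) of
#'   `list(kind = "gaussian", optimum =, breadth =)` or
#'   `list(kind = "logistic", inflection =, slope =, direction =)`.
#' @param presence_threshold suitability level defining the species' true
#'   binary range, or `NULL` for the prevalence-consistent default (mean
#'   suitability over valid cells).
#' @return object of class `virtual_niche`.
#' @export
virtual_niche <- function(responses, presence_threshold = NULL) {
  for (nm in names(responses)) {
    r <- responses[[nm]]
    if (!r$kind %in% c("gaussian", "logistic"))
      stop("unknown response kind for '", nm, "'")
    if (r$kind == "gaussian" && (is.null(r$optimum) || is.null(r$breadth) || r$breadth <= 0))
      stop("gaussian response for '", nm, "' needs optimum and positive breadth")
    if (r$kind == "logistic" && (is.null(r$inflection) || is.null(r$slope)))
      stop("logistic response for '", nm, "' needs inflection and slope")
  }
  structure(list(responses = responses,
                 presence_threshold = presence_threshold),
            class = "virtual_niche")
}

niche_response <- function(r, x) {
  switch(r$kind,
    gaussian = exp(-0.5 * ((x - r$optimum) / r$breadth)^2),
    logistic = stats::plogis((if (is.null(r$direction)) 1 else r$direction) *
                             r$slope * (x - r$inflection)))
}

#' True suitability of a virtual niche over a stack
#'
#' Cell-wise product of the niche's per-predictor responses, plus the true
#' binary range (`suitability >= presence_threshold`; a `NULL` threshold
#' resolves to the mean suitability over valid cells, see [virtual_niche]).
#'
#' @param niche a [virtual_niche].
#' @param stack a [predictor_stack] whose layer names cover the niche's
#'   response names.
#' @return list with `suitability` (probability [bam_grid]) and `range`
#'   (binary [bam_grid]).
#' @export
true_suitability <- function(niche, stack) {
  miss <- setdiff(names(niche$responses), names(stack$layers))
  if (length(miss)) stop("stack lacks predictors: ", paste(miss, collapse = ", "))
  g1 <- stack$layers[[1L]]
  s <- matrix(1, nrow(g1$values), ncol(g1$values))
  for (nm in names(niche$responses))
    s <- s * niche_response(niche$responses[[nm]], stack$layers[[nm]]$values)
  s[!stack$mask] <- NA_real_
  thr <- niche$presence_threshold
  if (is.null(thr)) thr <- mean(s[stack$mask])
  suit <- bam_grid(s, g1$extent, g1$resolution, mask = stack$mask,
                   kind = "probability")
  rng <- bam_grid(ifelse(s >= thr, 1, 0), g1$extent,
                  g1$resolution, mask = stack$mask, kind = "binary")
  list(suitability = suit, range = rng, threshold = thr)
}

#' Sample occurrence records from a true suitability surface
#'
#' Draws `n` cells (with replacement across draws) with probability
#' proportional to suitability and places one record at each drawn cell's
#' center — emulating presence sampling that favours high-suitability
#' habitat.  Duplicates are expected and are later collapsed by
#' [clean_occurrences].
#'
#' @param suitability a probability [bam_grid] with positive total mass.
#' @param n number of draws.
#' @param seed RNG seed.
#' @param species species name stored on the records.
#' @return an [occurrence_set] with `n` rows.
#' @export
sample_occurrences <- function(suitability, n, seed = 1L, species = "virtual") {
  v <- suitability$values
  keep <- which(suitability$mask & v > 0)
  if (!length(keep)) stop("total suitability mass is zero; nothing to sample")
  pr <- v[keep]
  pick <- with_seed(seed, sample(keep, n, replace = TRUE, prob = pr))
  nr <- nrow(v)
  row <- ((pick - 1L) %% nr) + 1L
  col <- ((pick - 1L) %/% nr) + 1L
  occurrence_set(species,
                 lon = suitability$extent[1L] + (col - 0.5) * suitability$resolution,
                 lat = suitability$extent[4L] - (row - 0.5) * suitability$resolution,
                 source = "simulated")
}

#' Construct a symbiont-host virtual pair with a known true BAM case
#'
#' Builds two niches structured along the first predictor so that the true
#' binary ranges realise the requested interaction case exactly:
#'
#' * case 1 (`B_subset_A`): host response strictly narrower than the
#'   symbiont's at the same optimum — nesting follows analytically because
#'   a narrower Gaussian is everywhere below a wider one;
#' * case 2 (`A_subset_B`): the symmetric construction;
#' * case 3 (`partial_overlap`): equal breadths with offset optima.
#'
#' The realised truth is verified with [bam_combine]/[diagnose_bam] at
#' epsilon 0.01 and the construction is re-drawn (jittered optimum) until it
#' holds, up to 50 attempts.
#'
#' @param stack a [predictor_stack] (first layer is the structuring axis).
#' @param target_case 1, 2 or 3.
#' @param seed RNG seed.
#' @param presence_threshold suitability level defining the true ranges
#'   (`NULL` = per-species prevalence-consistent default).
#' @return object of class `virtual_pair`: list with `symbiont` and `host`
#'   ([virtual_niche]s), `target_case`, `true_A`, `true_B` (binary
#'   [bam_grid]s), `suitability_A`, `suitability_B`, `diagnosis`.
#' @export
make_virtual_pair <- function(stack, target_case, seed = 1L,
                              presence_threshold = NULL) {
  if (!target_case %in% 1:3) stop("target_case must be 1, 2 or 3")
  axis <- names(stack$layers)[1L]
  ax <- stack$layers[[axis]]$values[stack$mask]
  ax_med <- stats::median(ax); ax_sd <- stats::sd(ax)
  # non-axis responses are deliberately weak (very broad) so the pair's set
  # relations are governed by the structuring axis
  broad <- lapply(stack$layers[-1L], function(g) {
    v <- g$values[g$mask]
    list(kind = "gaussian", optimum = stats::median(v), breadth = 4 * stats::sd(v))
  })
  names(broad) <- names(stack$layers)[-1L]
  expected <- c("B_subset_A", "A_subset_B", "partial_overlap")[target_case]
  for (attempt in seq_len(50L)) {
    jit <- with_seed(derive_seed(seed, attempt, target_case, 5L),
                     stats::rnorm(2L, 0, 0.15 * ax_sd))
    opt <- ax_med + jit[1L]
    # breadths chosen so an ideal model separates presences from uniform
    # background at AUC > 0.8 (learnable species, cf. the rank-statistic
    # argument in the methods vignette); ratio ~1.8 keeps nesting decisive
    wide <- 0.32 * ax_sd; narrow <- 0.18 * ax_sd
    if (target_case == 1L) {
      rs <- c(list(list(kind = "gaussian", optimum = opt, breadth = wide)), broad)
      rh <- c(list(list(kind = "gaussian", optimum = opt, breadth = narrow)), broad)
    } else if (target_case == 2L) {
      rs <- c(list(list(kind = "gaussian", optimum = opt, breadth = narrow)), broad)
      rh <- c(list(list(kind = "gaussian", optimum = opt, breadth = wide)), broad)
    } else {
      off <- 0.65 * ax_sd + abs(jit[2L])
      rs <- c(list(list(kind = "gaussian", optimum = opt - off / 2, breadth = wide)), broad)
      rh <- c(list(list(kind = "gaussian", optimum = opt + off / 2, breadth = wide)), broad)
    }
    names(rs)[1L] <- axis; names(rh)[1L] <- axis
    sym <- virtual_niche(rs, presence_threshold)
    hst <- virtual_niche(rh, presence_threshold)
    ts_ <- true_suitability(sym, stack)
    th_ <- true_suitability(hst, stack)
    ok <- tryCatch({
      res <- bam_combine(ts_$range, th_$range)
      res$diagnosis == expected &&
        (target_case != 3L || all(res$counts[c("g_bi", "bi", "overlap")] > 0))
    }, error = function(e) FALSE)
    if (ok)
      return(structure(list(symbiont = sym, host = hst,
                            target_case = target_case,
                            true_A = ts_$range, true_B = th_$range,
                            suitability_A = ts_$suitability,
                            suitability_B = th_$suitability,
                            diagnosis = expected),
                       class = "virtual_pair"))
  }
  stop("could not realise BAM case ", target_case, " in 50 attempts")
}
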