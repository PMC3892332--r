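#' AUC-weighted ensemble of one (pseudo-absence set, repetition) group
#'
#' Averages the projections of all successful member runs sharing a
#' pseudo-absence selection and calibration/test repetition, weighting each
#' member by its held-out test AUC: `w_i = AUC_i / sum_j AUC_j`.  Members
#' with test AUC <= 0.5 carry no usable signal and are excluded before
#' weighting.  When the member runs carry their held-out test scores, the
#' ensemble's own test scores (same weighted average) are formed and the
#' ROC-optimised threshold for this ensemble is filled in.
#'
#' @param runs list of [fit_and_project] results sharing
#'   `(pa_set_id, rep_id)`.
#' @return object of class `ensemble_projection`: list with `pa_set_id`,
#'   `rep_id`, `grid` (probability [bam_grid]), `weights`, `member_aucs`,
#'   `optimized_threshold` (`NA` if test scores unavailable).
#' @export
weighted_ensemble <- function(runs) {
  runs <- Filter(function(r) r$status == "ok", runs)
  if (!length(runs)) stop("no successful member runs in group")
  ids_pa <- unique(vapply(runs, `[[`, integer(1L), "pa_set_id"))
  ids_rep <- unique(vapply(runs, `[[`, integer(1L), "rep_id"))
  if (length(ids_pa) != 1L || length(ids_rep) != 1L)
    stop("member runs must share (pa_set_id, rep_id)")
  aucs <- vapply(runs, `[[`, numeric(1L), "test_auc")
  keep <- aucs > 0.5
  if (!any(keep))
    stop("all member runs excluded (test AUC <= 0.5)")
  runs <- runs[keep]; aucs <- aucs[keep]
  w <- aucs / sum(aucs)
  names(w) <- vapply(runs, `[[`, character(1L), "alg_id")
  g1 <- runs[[1L]]$grid
  acc <- matrix(0, nrow(g1$values), ncol(g1$values))
  mask <- g1$mask
  for (i in seq_along(runs)) {
    acc <- acc + w[i] * ifelse(runs[[i]]$grid$mask, runs[[i]]$grid$values, 0)
    mask <- mask & runs[[i]]$grid$mask
  }
  acc[!mask] <- NA_real_
  acc <- pmin(pmax(acc, 0), 1)  # argument order preserves the matrix dims
  thr <- NA_real_
  if (all(vapply(runs, function(r) !is.null(r$test_scores), logical(1L)))) {
    sc <- Reduce(`+`, Map(function(r, wi) wi * r$test_scores, runs, w))
    thr <- optimize_threshold(sc, runs[[1L]]$test_labels)
  }
  structure(list(pa_set_id = ids_pa, rep_id = ids_rep,
                 grid = bam_grid(acc, g1$extent, g1$resolution, mask = mask,
                                 kind = "probability"),
                 weights = w, member_aucs = stats::setNames(aucs, names(w)),
                 optimized_threshold = thr),
            class = "ensemble_projection")
}

#' Group workflow runs and build all ensemble projections
#'
#' Convenience wrapper applying [weighted_ensemble] to every
#' (pseudo-absence set, repetition) group of a workflow — 100 ensembles
#' under the default 10 x 10 design.
#'
#' @param wf an [run_workflow] result.
#' @return list of `ensemble_projection` objects.
#' @export
build_ensembles <- function(wf) {
  key <- paste(wf$run_table$pa_set_id, wf$run_table$rep_id)
  out <- lapply(split(wf$runs, key), function(g)
    tryCatch(weighted_ensemble(g), error = function(e) e))
  bad <- vapply(out, inherits, logical(1L), "error")
  if (any(bad))
    warning(sum(bad), " ensemble group(s) dropped: ",
            conditionMessage(out[bad][[1L]]))
  out[!bad]
}

#' Consensus across ensemble projections
#'
#' Per-cell unweighted mean of the ensemble projections (the species'
#' consensus suitability map) and their per-cell sample standard deviation
#' (the uncertainty map: high SD marks cells where ensembles disagree,
#' typically near range boundaries).  A cell invalid in any ensemble is
#' invalid in the consensus.  The threshold/binary fields are filled by
#' [binarize] at the consensus threshold.
#'
#' @param ensembles list of at least two `ensemble_projection` objects on
#'   identical lattices.
#' @return object of class `consensus_result`: list with `mean` and `sd`
#'   ([bam_grid]s), `n_ensembles`, `consensus_threshold` (`NA` until set),
#'   `binary` (`NULL` until set).
#' @export
consensus <- function(ensembles) {
  if (length(ensembles) < 2L) stop("need at least two ensembles for a consensus")
  g1 <- ensembles[[1L]]$grid
  for (e in ensembles[-1L]) {
    g <- e$grid
    if (!isTRUE(all.equal(g$extent, g1$extent)) ||
        !isTRUE(all.equal(g$resolution, g1$resolution)) ||
        !identical(dim(g$values), dim(g1$values)))
      stop("ensemble projections are not on identical lattices")
  }
  mask <- Reduce(`&`, lapply(ensembles, function(e) e$grid$mask))
  n <- length(ensembles)
  s <- matrix(0, nrow(g1$values), ncol(g1$values))
  for (e in ensembles) s <- s + ifelse(e$grid$mask, e$grid$values, 0)
  m <- s / n
  # two-pass sample variance: exactly zero where all ensembles agree
  ss <- matrix(0, nrow(g1$values), ncol(g1$values))
  for (e in ensembles) {
    d <- ifelse(e$grid$mask, e$grid$values, 0) - m
    ss <- ss + d * d
  }
  var_ <- ss / (n - 1)
  m[!mask] <- NA_real_
  sdv <- sqrt(var_); sdv[!mask] <- NA_real_
  structure(list(mean = bam_grid(pmin(pmax(m, 0), 1), g1$extent, g1$resolution,
                                 mask = mask, kind = "probability"),
                 sd = bam_grid(sdv, g1$extent, g1$resolution, mask = mask,
                               kind = "continuous"),
                 n_ensembles = n,
                 consensus_threshold = NA_real_, binary = NULL),
            class = "consensus_result")
}

#' Finalise a consensus: threshold and binary map
#'
#' Averages the per-ensemble optimised thresholds into the species-level
#' consensus threshold and binarises the consensus mean with it.
#'
#' @param cons a [consensus] result.
#' @param ensembles the ensembles it was built from (for their thresholds),
#'   or a numeric vector of thresholds.
#' @return `cons` with `consensus_threshold` and `binary` filled.
#' @export
finalize_consensus <- function(cons, ensembles) {
  thr <- if (is.numeric(ensembles)) ensembles
         else vapply(ensembles, `[[`, numeric(1L), "optimized_threshold")
  if (anyNA(thr)) stop("ensemble thresholds missing; cannot finalise")
  # sentinel candidates can sit marginally outside [0, 1]; probability maps
  # only support thresholds inside it
  cons$consensus_threshold <- min(1, max(0, consensus_threshold(thr)))
  cons$binary <- binarize(cons$mean, cons$consensus_threshold)
  cons
}
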