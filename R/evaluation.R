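#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney estimate of the probability that a randomly chosen positive
#' is scored above a randomly chosen negative; tied scores count one half.
#' This is the skill measure behind both the ensemble weights and the
#' held-out test evaluation of every fitted niche model.
#'
#' @param scores numeric scores (higher = more presence-like).
#' @param labels binary labels (1 = presence, 0 = pseudo-absence).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must be complete")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Candidate thresholds for the empirical ROC: midpoints between adjacent
# distinct sorted scores, plus one sentinel below the minimum and one above
# the maximum (so the all-positive and all-negative classifications are
# reachable).  Shared by optimize_threshold and its tests' exhaustive scan.
roc_threshold_candidates <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1L) return(c(u - 0.5, u + 0.5))
  mids <- (u[-length(u)] + u[-1L]) / 2
  step <- min(diff(u)) / 2
  c(u[1L] - step, mids, u[length(u)] + step)
}

#' Optimise a presence threshold on the ROC curve
#'
#' Returns the threshold maximising sensitivity + specificity (equivalently
#' TSS + 1) over the empirical ROC: candidates are midpoints between
#' adjacent distinct scores plus outer sentinels, classification is
#' `score >= threshold`, and ties are broken toward the smallest maximising
#' candidate.
#'
#' @inheritParams auc
#' @return the optimised threshold.
#' @export
optimize_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("threshold optimisation needs both classes present")
  cands <- roc_threshold_candidates(scores)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  obj <- vapply(cands, function(t)
    mean(pos >= t) + mean(neg < t), numeric(1L))
  cands[which.max(obj)]  # which.max takes the first (smallest) maximiser
}

#' Average per-ensemble thresholds into a consensus threshold
#'
#' One optimised threshold is produced per ensemble projection; their
#' arithmetic mean is the species-level threshold applied to the consensus
#' suitability map.
#'
#' @param thresholds numeric vector of per-ensemble optimised thresholds.
#' @return scalar mean.
#' @export
consensus_threshold <- function(thresholds) {
  if (!length(thresholds)) stop("no thresholds to average")
  mean(thresholds)
}

#' Binarise a probability grid at a threshold
#'
#' Valid cells become 1 where `value >= threshold` (cells exactly at the
#' threshold count as presence) and 0 otherwise; invalid cells stay invalid.
#'
#' @param grid a probability [bam_grid].
#' @param threshold scalar in \[0, 1\].
#' @return a binary [bam_grid].
#' @export
binarize <- function(grid, threshold) {
  if (grid$kind != "probability") stop("binarize expects a probability grid")
  if (!is.finite(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  v <- ifelse(grid$values >= threshold, 1, 0)
  bam_grid(v, grid$extent, grid$resolution, mask = grid$mask, kind = "binary")
}

#' Binomial-logit GLM with a deviance report
#'
#' Fits a logit-link binomial GLM of the response on the predictor columns
#' by iteratively reweighted least squares (deviance tolerance 1e-8, up to
#' 100 iterations) and assembles the coefficient table and deviance block
#' used to judge predictor performance: per-term estimate, standard error,
#' z, p; null and residual deviance with degrees of freedom; and a
#' goodness-of-fit p value from the upper tail of chi-square(residual
#' deviance, df).  Fractional responses in (0, 1), such as AUC values, are
#' accepted via the quasi-binomial trick (same point estimates as binomial).
#'
#' @param labels response in \[0, 1\] (binary or fractional).
#' @param X numeric predictor matrix or data frame (columns = terms).
#' @return object of class `glm_report`: list with `coefficients` (data
#'   frame: term, estimate, se, z, p), `null_deviance`, `residual_deviance`,
#'   `df_null`, `df_residual`, `gof_p`, `converged`, `flag` (`NULL` or a
#'   cause string when the fit is unreliable).
#' @export
fit_binomial_glm <- function(labels, X) {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(!nzchar(names(X))))
    names(X) <- paste0("x", seq_along(X))
  n <- length(labels)
  if (nrow(X) != n) stop("labels and X differ in length")
  if (n <= ncol(X) + 1L) stop("need more records than model terms")
  fractional <- any(labels > 0 & labels < 1)
  fam <- if (fractional) stats::quasibinomial("logit") else stats::binomial("logit")
  dat <- cbind(.y = labels, X)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = fam,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) invokeRestart("muffleWarning"))
  sm <- summary(fit)
  co <- stats::coef(sm)
  # quasi families report t statistics; rescale to z (dispersion = 1) to
  # match the binomial-logit convention used for fractional responses
  if (fractional) {
    se <- sqrt(diag(stats::vcov(fit)) / sm$dispersion)
    z <- co[, 1L] / se
    coefs <- data.frame(term = rownames(co), estimate = co[, 1L], se = se,
                        z = z, p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  } else {
    coefs <- data.frame(term = rownames(co), estimate = co[, 1L], se = co[, 2L],
                        z = co[, 3L], p = co[, 4L], row.names = NULL)
  }
  flag <- NULL
  if (!fit$converged) flag <- "IRLS did not converge within 100 iterations"
  if (!fractional && any(abs(coefs$estimate[-1L]) > 15))
    flag <- paste(c(flag, "possible separation (runaway coefficients)"),
                  collapse = "; ")
  out <- list(coefficients = coefs,
              null_deviance = fit$null.deviance,
              residual_deviance = fit$deviance,
              df_null = fit$df.null,
              df_residual = fit$df.residual,
              gof_p = stats::pchisq(fit$deviance, fit$df.residual,
                                    lower.tail = FALSE),
              converged = fit$converged,
              flag = flag)
  class(out) <- "glm_report"
  out
}

#' @export
print.glm_report <- function(x, ...) {
  cat("<glm_report>\n")
  print(transform(x$coefficients,
                  estimate = signif(estimate, 4), se = signif(se, 4),
                  z = signif(z, 4), p = signif(p, 3)))
  cat(sprintf("  null deviance %.4g (df %d); residual deviance %.4g (df %d); GoF P(>chi2) = %.3g\n",
              x$null_deviance, x$df_null, x$residual_deviance, x$df_residual,
              x$gof_p))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Test the effect of algorithm type on AUC
#'
#' Fits a fractional-response binomial-logit GLM of the per-run test AUC on
#' algorithm-type indicators and reports the deviance explained by the
#' algorithm factor with its chi-square p value — the check for whether some
#' model families systematically out-score others across the replicate
#' design.
#'
#' @param auc_table data frame with columns `alg_id` and `auc`.
#' @return a `glm_report` with extra fields `explained_deviance`,
#'   `df_explained` and `effect_p`.
#' @export
algorithm_effect_glm <- function(auc_table) {
  stopifnot(all(c("alg_id", "auc") %in% names(auc_table)))
  alg <- factor(auc_table$alg_id)
  if (nlevels(alg) < 2L) stop("need at least two algorithm levels")
  if (any(table(alg) < 2L)) stop("need at least two AUC rows per algorithm")
  X <- as.data.frame(stats::model.matrix(~alg)[, -1L, drop = FALSE])
  rep_ <- fit_binomial_glm(auc_table$auc, X)
  rep_$explained_deviance <- rep_$null_deviance - rep_$residual_deviance
  rep_$df_explained <- rep_$df_null - rep_$df_residual
  rep_$effect_p <- stats::pchisq(rep_$explained_deviance, rep_$df_explained,
                                 lower.tail = FALSE)
  rep_
}
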