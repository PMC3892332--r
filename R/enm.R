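#' Sample pseudo-absence points
#'
#' True absences are unreliable for low-prevalence symbionts, so the models
#' are calibrated against background cells instead: `n` distinct valid cells
#' are drawn uniformly at random, without replacement, from the whole stack
#' extent, excluding every cell that contains a presence record.  By default
#' `n` equals the number of occurrences.  Points are returned at cell
#' centers.
#'
#' @param stack a [predictor_stack].
#' @param occ a cleaned [occurrence_set].
#' @param n number of pseudo-absences (default: one per occurrence).
#' @param seed RNG seed.
#' @return data frame with columns `lon`, `lat`.
#' @export
sample_pseudo_absences <- function(stack, occ, n = nrow(occ), seed = 1L) {
  cells <- stack_cell_table(stack)
  idx <- cell_index(stack$layers[[1L]], occ$lon, occ$lat)
  pres_flat <- (idx[, "col"] - 1L) * nrow(stack$mask) + idx[, "row"]
  pool <- which(!(cells$cell %in% pres_flat))
  if (length(pool) < n)
    stop(sprintf("only %d valid non-presence cells available, %d requested",
                 length(pool), n))
  pick <- with_seed(seed, pool[sample.int(length(pool), n)])
  data.frame(lon = cells$lon[pick], lat = cells$lat[pick])
}

#' Assemble a training set from presences and pseudo-absences
#'
#' Extracts the predictor values at both point sets and stacks them into one
#' labelled table (1 = presence, 0 = pseudo-absence).  Records with invalid
#' predictors are dropped (presences should already be clean).
#'
#' @param stack a [predictor_stack].
#' @param occ presence [occurrence_set].
#' @param pa pseudo-absence data frame (`lon`, `lat`).
#' @param pa_set_id identifier of the pseudo-absence selection.
#' @return object of class `training_set`: list with `data` (data frame:
#'   `label`, predictors, `lon`, `lat`), `split` (`NULL` until
#'   [split_calibration_test]), `pa_set_id`, `rep_id`.
#' @export
make_training_set <- function(stack, occ, pa, pa_set_id = 1L) {
  exp_ <- extract_values(stack, occ$lon, occ$lat)
  exa <- extract_values(stack, pa$lon, pa$lat)
  dp <- data.frame(label = 1L, exp_$values[exp_$valid, , drop = FALSE],
                   lon = occ$lon[exp_$valid], lat = occ$lat[exp_$valid])
  da <- data.frame(label = 0L, exa$values[exa$valid, , drop = FALSE],
                   lon = pa$lon[exa$valid], lat = pa$lat[exa$valid])
  structure(list(data = rbind(dp, da), split = NULL,
                 pa_set_id = pa_set_id, rep_id = NA_integer_,
                 predictors = names(stack$layers)),
            class = "training_set")
}

#' Split a training set into calibration and test partitions
#'
#' Stratified by label: `round(fraction * n)` records of each class go to
#' calibration, the rest to test, assigned uniformly at random under the
#' seed.  70/30 is the package-wide default.
#'
#' @param ts a [make_training_set] result.
#' @param fraction calibration share in (0, 1).
#' @param seed RNG seed.
#' @param rep_id repetition identifier stored on the result.
#' @return `ts` with `split` filled (`"calibration"`/`"test"` per record).
#' @export
split_calibration_test <- function(ts, fraction = 0.7, seed = 1L, rep_id = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1 (both partitions non-empty)")
  lab <- ts$data$label
  if (sum(lab == 1L) < 2L || sum(lab == 0L) < 2L)
    stop("need at least 2 records of each class to split")
  split <- character(length(lab))
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      rows <- which(lab == cl)
      ncal <- round(fraction * length(rows))
      if (ncal == 0L || ncal == length(rows))
        stop("fraction leaves an empty partition for one class")
      cal <- sample(rows, ncal)
      split[cal] <- "calibration"
      split[setdiff(rows, cal)] <- "test"
    }
  })
  ts$split <- split
  ts$rep_id <- rep_id
  ts
}

#' The eight niche-modelling families
#'
#' Returns the registry of model families used in the ensemble, keyed by the
#' conventional algorithm ids: GLM (logistic regression with linear +
#' quadratic terms), GAM (thin-plate smooths, mgcv), GBM (gradient boosted
#' trees, xgboost), ANN (single-hidden-layer network, nnet), CTA
#' (classification tree, rpart), FDA (discriminant analysis posterior
#' probabilities, MASS), MARS (logistic regression on natural-spline bases —
#' a fixed-knot adaptive-splines equivalent), and RF (probability forest,
#' ranger).  Each entry is a list with `fit(data, predictors, seed)`
#' returning a fitted object and `predict(model, newdata)` returning
#' presence probabilities in \[0, 1\].  Hyperparameters are frozen at the
#' documented defaults; the registry is the single place they live.
#'
#' @return named list of family definitions.
#' @export
model_families <- function() {
  clamp01 <- function(p) pmin(1, pmax(0, as.numeric(p)))
  list(
    GLM = list(
      fit = function(data, predictors, seed) {
        f <- stats::as.formula(paste("label ~",
          paste(c(predictors, sprintf("I(%s^2)", predictors)), collapse = " + ")))
        suppressWarnings(stats::glm(f, data = data, family = stats::binomial()))
      },
      predict = function(m, nd) clamp01(stats::predict(m, nd, type = "response"))),
    GAM = list(
      fit = function(data, predictors, seed) {
        f <- stats::as.formula(paste("label ~",
          paste(sprintf("s(%s, k = 4)", predictors), collapse = " + ")))
        mgcv::gam(f, data = data, family = stats::binomial(), method = "REML")
      },
      predict = function(m, nd) clamp01(mgcv::predict.gam(m, nd, type = "response"))),
    GBM = list(
      fit = function(data, predictors, seed) {
        dm <- xgboost::xgb.DMatrix(as.matrix(data[predictors]),
                                   label = data$label, nthread = 1)
        m <- xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 3,
                        eta = 0.1, nthread = 1, seed = seed),
          data = dm, nrounds = 40, verbose = 0)
        list(booster = m, predictors = predictors)
      },
      predict = function(m, nd)
        clamp01(stats::predict(m$booster,
                               xgboost::xgb.DMatrix(as.matrix(nd[m$predictors]),
                                                    nthread = 1)))),
    ANN = list(
      fit = function(data, predictors, seed) {
        X <- as.matrix(data[predictors])
        ctr <- colMeans(X); scl <- apply(X, 2L, stats::sd)
        scl[scl == 0] <- 1
        Xs <- scale(X, ctr, scl)
        m <- with_seed(seed,
          nnet::nnet(Xs, data$label, size = 4, decay = 0.01, maxit = 200,
                     entropy = TRUE, trace = FALSE))
        list(net = m, center = ctr, scale = scl, predictors = predictors)
      },
      predict = function(m, nd) {
        Xs <- scale(as.matrix(nd[m$predictors]), m$center, m$scale)
        clamp01(stats::predict(m$net, Xs))
      }),
    CTA = list(
      fit = function(data, predictors, seed) {
        d <- data[c("label", predictors)]
        d$label <- factor(d$label, levels = c(0L, 1L))
        with_seed(seed, rpart::rpart(label ~ ., data = d, method = "class"))
      },
      predict = function(m, nd) clamp01(stats::predict(m, nd, type = "prob")[, "1"])),
    FDA = list(
      # quadratic discriminant posterior: a flexible (curved-boundary)
      # discriminant, able to represent band-shaped niche responses
      fit = function(data, predictors, seed) {
        m <- MASS::qda(as.matrix(data[predictors]),
                       grouping = factor(data$label, levels = c(0L, 1L)))
        list(qda = m, predictors = predictors)
      },
      predict = function(m, nd)
        clamp01(stats::predict(m$qda, as.matrix(nd[m$predictors]))$posterior[, "1"])),
    MARS = list(
      fit = function(data, predictors, seed) {
        f <- stats::as.formula(paste("label ~",
          paste(sprintf("splines::ns(%s, df = 3)", predictors), collapse = " + ")))
        suppressWarnings(stats::glm(f, data = data, family = stats::binomial()))
      },
      predict = function(m, nd)
        clamp01(suppressWarnings(stats::predict(m, nd, type = "response")))),
    RF = list(
      fit = function(data, predictors, seed) {
        d <- data[c("label", predictors)]
        d$label <- factor(d$label, levels = c(0L, 1L))
        ranger::ranger(label ~ ., data = d, probability = TRUE,
                       num.trees = 100, seed = seed, num.threads = 1)
      },
      predict = function(m, nd)
        clamp01(stats::predict(m, nd, num.threads = 1)$predictions[, "1"]))
  )
}

#' Fit one model family and project it over a window
#'
#' Fits the family on the calibration records only, evaluates AUC on the
#' held-out test records, and projects presence probability over every valid
#' cell of the (optionally cropped) stack.  A family that errors (e.g.
#' perfect separation) yields a run with `status = "failed"` rather than an
#' exception, so one bad member never aborts a batch.
#'
#' @param alg_id family name, a key of [model_families()].
#' @param ts a split [training_set].
#' @param stack the [predictor_stack] to project over.
#' @param window optional lon/lat projection window ([crop_grid] semantics).
#' @param seed RNG seed for stochastic families.
#' @param cell_table optional precomputed `stack_cell_table(stack)` (after
#'   cropping) to avoid recomputation across runs.
#' @return object of class `projection_run`: list with `pa_set_id`,
#'   `alg_id`, `rep_id`, `grid` (probability [bam_grid] or `NULL`),
#'   `test_auc`, `calibration_auc`, `test_scores`, `test_labels`, `status`
#'   (`"ok"`/`"failed"`), `message`.
#' @export
fit_and_project <- function(alg_id, ts, stack, window = NULL, seed = 1L,
                            cell_table = NULL) {
  if (is.null(ts$split)) stop("training set must be split before fitting")
  fam <- model_families()[[alg_id]]
  if (is.null(fam)) stop("unknown model family: ", alg_id)
  if (!is.null(window)) stack <- crop_stack(stack, window)
  if (is.null(cell_table)) cell_table <- stack_cell_table(stack)
  cal <- ts$data[ts$split == "calibration", , drop = FALSE]
  tst <- ts$data[ts$split == "test", , drop = FALSE]
  run <- list(pa_set_id = ts$pa_set_id, alg_id = alg_id, rep_id = ts$rep_id,
              grid = NULL, test_auc = NA_real_, calibration_auc = NA_real_,
              test_scores = NULL, test_labels = tst$label,
              status = "failed", message = "")
  class(run) <- "projection_run"
  res <- tryCatch({
    m <- fam$fit(cal, ts$predictors, seed)
    p_tst <- fam$predict(m, tst)
    p_cal <- fam$predict(m, cal)
    p_map <- fam$predict(m, cell_table)
    list(m = m, p_tst = p_tst, p_cal = p_cal, p_map = p_map)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    run$message <- conditionMessage(res)
    return(run)
  }
  g1 <- stack$layers[[1L]]
  vals <- matrix(NA_real_, nrow(g1$values), ncol(g1$values))
  vals[cell_table$cell] <- res$p_map
  run$grid <- bam_grid(vals, g1$extent, g1$resolution, kind = "probability")
  run$test_scores <- res$p_tst
  run$test_auc <- auc(res$p_tst, tst$label)
  run$calibration_auc <- auc(res$p_cal, cal$label)
  run$status <- "ok"
  run
}

#' Run the full replicate modelling design for one species
#'
#' Orchestrates the complete ensemble design: `n_pa_sets` pseudo-absence
#' selections x `n_reps` calibration/test repetitions x the model families —
#' 10 x 10 x 8 = 800 individual projections under the default configuration.
#' Per-run seeds are derived deterministically from `master_seed` and the
#' (pseudo-absence set, repetition, family) indices, so a rerun with the
#' same master seed reproduces every projection and AUC exactly.  Failed
#' fits are kept as flagged runs and excluded downstream.
#'
#' @param occ cleaned [occurrence_set].
#' @param stack fitting [predictor_stack] (global extent).
#' @param n_pa_sets number of pseudo-absence selections.
#' @param n_reps number of calibration/test repetitions per selection.
#' @param families character vector of family ids (default: all eight).
#' @param window projection window (`NULL` = full stack extent).
#' @param split_fraction calibration share.
#' @param master_seed master RNG seed.
#' @return object of class `enm_workflow`: list with `runs` (list of
#'   [fit_and_project] results), `run_table` (data frame: pa_set_id, alg_id,
#'   rep_id, test_auc, status), and the configuration.
#' @export
run_workflow <- function(occ, stack, n_pa_sets = 10L, n_reps = 10L,
                         families = names(model_families()), window = NULL,
                         split_fraction = 0.7, master_seed = 1L) {
  proj_stack <- if (is.null(window)) stack else crop_stack(stack, window)
  cell_table <- stack_cell_table(proj_stack)
  runs <- vector("list", n_pa_sets * n_reps * length(families))
  k <- 0L
  for (pa_i in seq_len(n_pa_sets)) {
    pa <- sample_pseudo_absences(stack, occ, seed = derive_seed(master_seed, pa_i, 0L, 1L))
    ts0 <- make_training_set(stack, occ, pa, pa_set_id = pa_i)
    for (rep_i in seq_len(n_reps)) {
      ts <- split_calibration_test(ts0, fraction = split_fraction,
                                   seed = derive_seed(master_seed, pa_i, rep_i, 2L),
                                   rep_id = rep_i)
      for (alg_i in seq_along(families)) {
        k <- k + 1L
        runs[[k]] <- fit_and_project(
          families[alg_i], ts, proj_stack, window = NULL,
          seed = derive_seed(master_seed, pa_i, rep_i, 10L + alg_i),
          cell_table = cell_table)
      }
    }
  }
  run_table <- data.frame(
    pa_set_id = vapply(runs, `[[`, integer(1L), "pa_set_id"),
    alg_id = vapply(runs, `[[`, character(1L), "alg_id"),
    rep_id = vapply(runs, `[[`, integer(1L), "rep_id"),
    test_auc = vapply(runs, `[[`, numeric(1L), "test_auc"),
    status = vapply(runs, `[[`, character(1L), "status"))
  structure(list(runs = runs, run_table = run_table,
                 config = list(n_pa_sets = n_pa_sets, n_reps = n_reps,
                               families = families, window = window,
                               split_fraction = split_fraction,
                               master_seed = master_seed)),
            class = "enm_workflow")
}

#' @export
print.enm_workflow <- function(x, ...) {
  tab <- x$run_table
  cat(sprintf("<enm_workflow> %d runs (%d pseudo-absence sets x %d reps x %d families); %d ok, %d failed\n",
              nrow(tab), x$config$n_pa_sets, x$config$n_reps,
              length(x$config$families),
              sum(tab$status == "ok"), sum(tab$status != "ok")))
  ok <- tab$test_auc[tab$status == "ok"]
  if (length(ok))
    cat(sprintf("  test AUC: median %.3f, range [%.3f, %.3f]\n",
                stats::median(ok), min(ok), max(ok)))
  invisible(x)
}
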