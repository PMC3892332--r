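#' Configuration for a symbiont-host BAM analysis
#'
#' Bundles every input and tunable of [run_pipeline] into one validated
#' list, so a run is fully determined by its configuration (plus the master
#' seed).  Occurrences may be given as [occurrence_set] objects or CSV
#' paths; predictors as a [predictor_stack] or a named list of ESRI ASCII
#' paths.
#'
#' @param symbiont_occ,host_occ [occurrence_set] or CSV path.
#' @param predictors [predictor_stack] or named list of raster paths.
#' @param window projection window `c(lon_min, lon_max, lat_min, lat_max)`
#'   or `NULL` for the full stack extent.  (The continental default used for
#'   real European runs is `c(-12, 60, 30, 75)`.)
#' @param n_pa_sets,n_reps,families,split_fraction replicate design; the
#'   defaults reproduce the 10 x 10 x 8 = 800-run design.
#' @param collinearity_threshold |r| bound for the predictor screen.
#' @param thin_quota per-region thinning quota (`NULL` = median rule; `NA` =
#'   skip thinning).
#' @param epsilon BAM emptiness tolerance.
#' @param weighting share weighting used for the diagnosis.
#' @param master_seed master RNG seed.
#' @param output_dir directory for artifacts (`NULL` = nothing written).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(symbiont_occ, host_occ, predictors,
                            window = NULL,
                            n_pa_sets = 10L, n_reps = 10L,
                            families = names(model_families()),
                            split_fraction = 0.7,
                            collinearity_threshold = 0.7,
                            thin_quota = NA,
                            epsilon = 0.01,
                            weighting = c("cell_count", "cos_latitude"),
                            master_seed = 1L,
                            output_dir = NULL) {
  weighting <- match.arg(weighting)
  bad <- setdiff(families, names(model_families()))
  if (length(bad)) stop("unknown model families: ", paste(bad, collapse = ", "))
  structure(list(symbiont_occ = symbiont_occ, host_occ = host_occ,
                 predictors = predictors, window = window,
                 n_pa_sets = as.integer(n_pa_sets), n_reps = as.integer(n_reps),
                 families = families, split_fraction = split_fraction,
                 collinearity_threshold = collinearity_threshold,
                 thin_quota = thin_quota, epsilon = epsilon,
                 weighting = weighting, master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map one-to-one onto [pipeline_config] arguments;
#' `symbiont_occ`/`host_occ` are CSV paths and `predictors` a named map of
#' raster paths.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  if (!is.null(args$window)) args$window <- as.numeric(args$window)
  do.call(pipeline_config, args)
}

resolve_occ <- function(x) if (inherits(x, "occurrence_set")) x else read_occurrences(x)

resolve_stack <- function(x) {
  if (is_predictor_stack(x)) return(x)
  predictor_stack(lapply(x, read_grid))
}

# One species' half of the pipeline: clean -> thin -> screen -> replicate
# workflow -> ensembles -> consensus (+ threshold + binary) -> predictor GLM.
run_species <- function(occ, stack, cfg, species_seed) {
  occ <- clean_occurrences(occ, stack)
  if (!isTRUE(is.na(cfg$thin_quota)))
    occ <- thin_by_region(occ, quota = cfg$thin_quota,
                          seed = derive_seed(species_seed, 0L, 0L, 4L))
  screen <- collinearity_report(stack, occ$lon, occ$lat,
                                threshold = cfg$collinearity_threshold)
  if (!screen$pass)
    stop("collinearity screen failed: ",
         if (is.null(screen$failure_cause)) "pairwise |r| at or above threshold"
         else screen$failure_cause)
  wf <- run_workflow(occ, stack, n_pa_sets = cfg$n_pa_sets, n_reps = cfg$n_reps,
                     families = cfg$families, window = cfg$window,
                     split_fraction = cfg$split_fraction,
                     master_seed = species_seed)
  ens <- build_ensembles(wf)
  cons <- finalize_consensus(consensus(ens), ens)
  # predictor-performance GLM on occurrences + the first pseudo-absence set
  pa1 <- sample_pseudo_absences(stack, occ, seed = derive_seed(species_seed, 1L, 0L, 1L))
  ts1 <- make_training_set(stack, occ, pa1)
  pred_glm <- fit_binomial_glm(ts1$data$label, ts1$data[names(stack$layers)])
  ok <- wf$run_table[wf$run_table$status == "ok", , drop = FALSE]
  alg_glm <- tryCatch(algorithm_effect_glm(data.frame(alg_id = ok$alg_id,
                                                      auc = ok$test_auc)),
                      error = function(e) NULL)
  list(occurrences = occ, screen = screen, workflow = wf, ensembles = ens,
       consensus = cons, predictor_glm = pred_glm, algorithm_glm = alg_glm)
}

#' Run the full symbiont-host BAM analysis
#'
#' Executes, independently for the symbiont and its host: occurrence
#' cleaning, regional thinning, the collinearity screen, the replicate
#' ensemble modelling design, AUC-weighted ensembles with per-ensemble
#' ROC-optimised thresholds, the consensus mean/SD maps, and binarisation
#' at the consensus threshold.  The two binary maps (symbiont = A, host =
#' B) are then combined by the subtraction raster operation into g_bi and
#' bi, area shares are computed under both weightings, and the BAM
#' interaction case is diagnosed.  If `output_dir` is set, all consensus
#' grids, run tables, GLM reports and a `summary.json` are written there.
#'
#' @param config a [pipeline_config].
#' @return object of class `bam_pipeline_report`: list with `symbiont` and
#'   `host` stage results, `bam` (the [bam_combine] result), `diagnosis`,
#'   and `summary` (the plain-list content of `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stack <- resolve_stack(config$predictors)
  res <- list()
  seeds <- c(symbiont = derive_seed(config$master_seed, 1L, 0L, 3L),
             host = derive_seed(config$master_seed, 2L, 0L, 3L))
  occs <- list(symbiont = resolve_occ(config$symbiont_occ),
               host = resolve_occ(config$host_occ))
  for (sp in c("symbiont", "host"))
    res[[sp]] <- run_species(occs[[sp]], stack, config, seeds[[sp]])
  bam <- bam_combine(res$symbiont$consensus$binary, res$host$consensus$binary,
                     epsilon = config$epsilon)
  diagnosis <- diagnose_bam(bam, epsilon = config$epsilon,
                            weighting = config$weighting)
  summary <- list(
    n_occurrences = lapply(res, function(r) nrow(r$occurrences)),
    n_runs_ok = lapply(res, function(r) sum(r$workflow$run_table$status == "ok")),
    n_runs_total = lapply(res, function(r) nrow(r$workflow$run_table)),
    n_ensembles = lapply(res, function(r) length(r$ensembles)),
    median_test_auc = lapply(res, function(r) {
      tab <- r$workflow$run_table
      stats::median(tab$test_auc[tab$status == "ok"])
    }),
    consensus_threshold = lapply(res, function(r) r$consensus$consensus_threshold),
    bam = list(counts = as.list(bam$counts),
               shares = lapply(bam$shares, as.list),
               epsilon = config$epsilon, weighting = config$weighting),
    diagnosis = diagnosis,
    master_seed = config$master_seed)
  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (sp in c("symbiont", "host")) {
      write_grid(res[[sp]]$consensus$mean, file.path(out, paste0(sp, "_consensus_mean.asc")))
      write_grid(res[[sp]]$consensus$sd, file.path(out, paste0(sp, "_consensus_sd.asc")))
      write_grid(res[[sp]]$consensus$binary, file.path(out, paste0(sp, "_consensus_binary.asc")))
      utils::write.csv(res[[sp]]$workflow$run_table,
                       file.path(out, paste0(sp, "_runs.csv")), row.names = FALSE)
      utils::write.csv(res[[sp]]$predictor_glm$coefficients,
                       file.path(out, paste0(sp, "_predictor_glm.csv")),
                       row.names = FALSE)
    }
    write_bam_result(bam, file.path(out, "bam"))
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(symbiont = res$symbiont, host = res$host, bam = bam,
                 diagnosis = diagnosis, summary = summary),
            class = "bam_pipeline_report")
}

#' @export
print.bam_pipeline_report <- function(x, ...) {
  cat("<bam_pipeline_report>\n")
  for (sp in c("symbiont", "host"))
    cat(sprintf("  %s: %d occurrences, %d/%d runs ok, %d ensembles, median test AUC %.3f, threshold %.3f\n",
                sp, x$summary$n_occurrences[[sp]], x$summary$n_runs_ok[[sp]],
                x$summary$n_runs_total[[sp]], x$summary$n_ensembles[[sp]],
                x$summary$median_test_auc[[sp]],
                x$summary$consensus_threshold[[sp]]))
  s <- x$bam$shares$cell_count
  cat(sprintf("  BAM shares: g_bi %.3f, bi %.3f, overlap %.3f -> %s\n",
              s[["g_bi"]], s[["bi"]], s[["overlap"]], x$diagnosis))
  invisible(x)
}

#' Simulate a virtual symbiont-host dataset to disk
#'
#' Wraps the synthetic generator into file-level artifacts that the real
#' pipeline reads unchanged: one ESRI ASCII raster per climate predictor,
#' one occurrence CSV per species, the true range grids, and a
#' `manifest.json` recording the generator parameters and the true BAM
#' diagnosis.
#'
#' @param dir output directory.
#' @param target_case true BAM case (1, 2 or 3).
#' @param seed RNG seed.
#' @param shape lattice `c(rows, cols)`.
#' @param n_occurrences draws per species.
#' @param resolution,origin lattice geometry, see [generate_climate_stack].
#' @return the manifest, invisibly.
#' @export
simulate_virtual_data <- function(dir, target_case = 3L, seed = 1L,
                                  shape = c(60L, 60L), n_occurrences = 150L,
                                  resolution = 0.5, origin = c(-10, 30)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stack <- generate_climate_stack(seed = seed, shape = shape,
                                  resolution = resolution, origin = origin)
  pair <- make_virtual_pair(stack, target_case, seed = seed)
  for (nm in names(stack$layers))
    write_grid(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  occ_s <- sample_occurrences(pair$suitability_A, n_occurrences,
                              seed = derive_seed(seed, 1L, 0L, 9L),
                              species = "virtual_symbiont")
  occ_h <- sample_occurrences(pair$suitability_B, n_occurrences,
                              seed = derive_seed(seed, 2L, 0L, 9L),
                              species = "virtual_host")
  write_occurrences(occ_s, file.path(dir, "symbiont_occurrences.csv"))
  write_occurrences(occ_h, file.path(dir, "host_occurrences.csv"))
  write_grid(pair$true_A, file.path(dir, "true_A.asc"))
  write_grid(pair$true_B, file.path(dir, "true_B.asc"))
  manifest <- list(target_case = target_case, diagnosis = pair$diagnosis,
                   seed = seed, shape = as.integer(shape),
                   n_occurrences = n_occurrences, resolution = resolution,
                   origin = as.numeric(origin),
                   predictors = names(stack$layers))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
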