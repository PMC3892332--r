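# Workflow-level machinery: pseudo-absences, splitting, family fits,
# replicate orchestration.  Model-quality checks use small simulated niches.

test_that("pseudo-absences avoid presence cells, are distinct, and respect the default count", {
  st <- tiny_stack()
  occ <- occurrence_set("sp", lon = c(0.5, 1.5, 2.5), lat = rep(49.5, 3))
  pa <- sample_pseudo_absences(st, occ, seed = 3)
  expect_equal(nrow(pa), 3L)  # default n = |occurrences|
  pa2 <- sample_pseudo_absences(st, occ, n = 50, seed = 3)
  idx <- cell_index(st$layers[[1]], pa2$lon, pa2$lat)
  key <- paste(idx[, 1], idx[, 2])
  expect_equal(anyDuplicated(key), 0L)
  pres <- cell_index(st$layers[[1]], occ$lon, occ$lat)
  expect_false(any(key %in% paste(pres[, 1], pres[, 2])))
  # deterministic under the seed
  expect_identical(pa2, sample_pseudo_absences(st, occ, n = 50, seed = 3))
})

test_that("with a single free cell the forced pseudo-absence is returned, and over-requests error", {
  st <- tiny_stack()
  # presences on 99 of the 100 cells; (10, 10) left free
  lon <- rep(0.5 + 0:9, each = 10); lat <- rep(49.5 - 0:9, times = 10)
  occ <- occurrence_set("sp", lon = lon[-100], lat = lat[-100])
  pa <- sample_pseudo_absences(st, occ, n = 1, seed = 9)
  expect_equal(pa$lon, 9.5)
  expect_equal(pa$lat, 40.5)
  expect_error(sample_pseudo_absences(st, occ, n = 2), "available")
})

test_that("calibration/test split is stratified, 70/30 by default, and seed-stable", {
  st <- tiny_stack(nr = 20, nc = 20)
  set.seed(2)
  occ <- occurrence_set("sp", lon = runif(50, 0, 10), lat = runif(50, 40, 50))
  occ <- clean_occurrences(occ, st)
  pa <- sample_pseudo_absences(st, occ, n = 50, seed = 5)
  # pad presences back to 50 rows by construction of the test below
  ts <- make_training_set(st, occ, pa)
  ts <- split_calibration_test(ts, fraction = 0.7, seed = 6)
  for (cl in 0:1) {
    ncl <- sum(ts$data$label == cl)
    expect_equal(sum(ts$data$label == cl & ts$split == "calibration"),
                 round(0.7 * ncl))
  }
  expect_setequal(unique(ts$split), c("calibration", "test"))
  ts2 <- split_calibration_test(ts, fraction = 0.7, seed = 6)
  expect_identical(ts$split, ts2$split)
  expect_error(split_calibration_test(ts, fraction = 1.0), "between 0 and 1")
  expect_error(split_calibration_test(ts, fraction = 0), "between 0 and 1")
})

test_that("an exact 50+50 design yields 35+35 calibration and 15+15 test records", {
  ext <- c(0, 100, 0, 1)
  st <- predictor_stack(list(x = bam_grid(matrix(seq(-2, 2, length.out = 100), 1), ext, 1)))
  occ <- occurrence_set("sp", lon = seq_len(50) - 0.5, lat = rep(0.5, 50))
  pa <- data.frame(lon = 50 + seq_len(50) - 0.5, lat = rep(0.5, 50))
  ts <- split_calibration_test(make_training_set(st, occ, pa), seed = 1)
  expect_equal(sum(ts$split == "calibration"), 70L)
  expect_equal(sum(ts$split == "test"), 30L)
  expect_equal(sum(ts$split == "test" & ts$data$label == 1), 15L)
})

test_that("every family separates a wide linear margin at test AUC >= 0.99", {
  # two clouds far apart on the first predictor
  set.seed(7)
  nr <- 20L; nc <- 20L
  ext <- c(0, nc, 0, nr)
  x1 <- matrix(rnorm(nr * nc, 0, 1), nr, nc)
  x1[, 1:10] <- x1[, 1:10] - 8   # left half strongly negative
  x1[, 11:20] <- x1[, 11:20] + 8
  st <- predictor_stack(list(a = bam_grid(x1, ext, 1),
                             b = bam_grid(matrix(rnorm(nr * nc), nr, nc), ext, 1)))
  lon_pos <- runif(100, 10, 20); lat_pos <- runif(100, 0, 20)
  lon_neg <- runif(100, 0, 10); lat_neg <- runif(100, 0, 20)
  occ <- occurrence_set("sp", lon = lon_pos, lat = lat_pos)
  pa <- data.frame(lon = lon_neg, lat = lat_neg)
  ts <- split_calibration_test(make_training_set(st, occ, pa), seed = 8)
  for (famname in names(model_families())) {
    run <- fit_and_project(famname, ts, st, seed = 99)
    expect_equal(run$status, "ok")
    expect_gte(run$test_auc, 0.99)
    v <- run$grid$values[run$grid$mask]
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("permuted labels give chance-level test AUC on average", {
  set.seed(17)
  nr <- 15L; nc <- 15L
  st <- predictor_stack(list(a = bam_grid(matrix(rnorm(nr * nc), nr, nc), c(0, nc, 0, nr), 1),
                             b = bam_grid(matrix(rnorm(nr * nc), nr, nc), c(0, nc, 0, nr), 1)))
  occ <- occurrence_set("sp", lon = runif(60, 0, nc), lat = runif(60, 0, nr))
  pa <- data.frame(lon = runif(60, 0, nc), lat = runif(60, 0, nr))
  ts0 <- make_training_set(st, occ, pa)
  aucs <- vapply(1:50, function(s) {
    ts <- split_calibration_test(ts0, seed = s)
    # labels carry no signal by construction (random points both sides)
    fit_and_project("GLM", ts, st, seed = s)$test_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("projection propagates invalid cells and stays within [0, 1]", {
  st <- tiny_stack(nr = 12, nc = 12, nodata_cells = cbind(c(2, 5), c(3, 7)))
  set.seed(27)
  occ <- clean_occurrences(
    occurrence_set("sp", lon = runif(40, 0, 12), lat = runif(40, 40, 52)), st)
  pa <- sample_pseudo_absences(st, occ, seed = 1)
  ts <- split_calibration_test(make_training_set(st, occ, pa), seed = 2)
  run <- fit_and_project("GLM", ts, st, seed = 3)
  expect_identical(run$grid$mask, st$mask)
  expect_true(all(run$grid$values[run$grid$mask] >= 0))
  expect_true(all(run$grid$values[run$grid$mask] <= 1))
  expect_equal(run$grid$kind, "probability")
})

test_that("the replicate workflow attempts exactly the configured design and is reproducible", {
  st <- tiny_stack(nr = 20, nc = 20)
  set.seed(37)
  occ <- clean_occurrences(
    occurrence_set("sp", lon = runif(60, 0, 10), lat = runif(60, 40, 50)), st)
  wf <- run_workflow(occ, st, n_pa_sets = 2, n_reps = 2,
                     families = c("GLM", "CTA"), master_seed = 100)
  expect_equal(nrow(wf$run_table), 8L)
  key <- with(wf$run_table, paste(pa_set_id, alg_id, rep_id))
  expect_equal(anyDuplicated(key), 0L)
  wf2 <- run_workflow(occ, st, n_pa_sets = 2, n_reps = 2,
                      families = c("GLM", "CTA"), master_seed = 100)
  expect_identical(wf$run_table$test_auc, wf2$run_table$test_auc)
  # different pseudo-absence sets differ
  pa1 <- sample_pseudo_absences(st, occ, seed = derive_seed(100, 1, 0, 1))
  pa2 <- sample_pseudo_absences(st, occ, seed = derive_seed(100, 2, 0, 1))
  expect_false(identical(pa1, pa2))
})

test_that("calibration and test partitions are disjoint and exhaustive in every run", {
  st <- tiny_stack(nr = 20, nc = 20)
  set.seed(47)
  occ <- clean_occurrences(
    occurrence_set("sp", lon = runif(40, 0, 10), lat = runif(40, 40, 50)), st)
  pa <- sample_pseudo_absences(st, occ, seed = 11)
  ts <- split_calibration_test(make_training_set(st, occ, pa), seed = 12)
  expect_equal(sum(ts$split == "calibration") + sum(ts$split == "test"),
               nrow(ts$data))
  expect_true(all(ts$split %in% c("calibration", "test")))
})
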