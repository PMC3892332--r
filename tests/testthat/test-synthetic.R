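test_that("climate stacks are deterministic, weakly correlated, and spatially autocorrelated", {
  st <- generate_climate_stack(seed = 5, shape = c(30, 30))
  st2 <- generate_climate_stack(seed = 5, shape = c(30, 30))
  expect_identical(lapply(st$layers, `[[`, "values"),
                   lapply(st2$layers, `[[`, "values"))
  expect_named(st$layers, c("MinT", "MaxT", "AnPrec", "PrecSeas"))

  # passes the collinearity screen it was built under
  set.seed(1)
  lon <- runif(200, st$extent[1], st$extent[2])
  lat <- runif(200, st$extent[3], st$extent[4])
  rep_ <- collinearity_report(st, lon, lat, threshold = 0.7)
  expect_true(rep_$pass)

  # positive lag-1 spatial autocorrelation on every layer (rook Moran's I)
  for (nm in names(st$layers))
    expect_gt(bf_moran_i(st$layers[[nm]]$values), 0.2)

  expect_error(generate_climate_stack(shape = c(10, 10)), "20 x 20")
})

test_that("niche responses follow their closed forms and multiply into suitability", {
  st <- tiny_stack(nr = 20, nc = 20)
  n <- virtual_niche(list(
    MinT = list(kind = "gaussian", optimum = 10, breadth = 4),
    MaxT = list(kind = "logistic", inflection = 25, slope = 0.8, direction = 1)),
    presence_threshold = 0.3)
  ts <- true_suitability(n, st)
  # hand-computed product at a specific cell
  x1 <- st$layers$MinT$values[7, 3]; x2 <- st$layers$MaxT$values[7, 3]
  expect_equal(ts$suitability$values[7, 3],
               exp(-0.5 * ((x1 - 10) / 4)^2) * plogis(0.8 * (x2 - 25)),
               tolerance = 1e-12)
  # gaussian response is 1 at its optimum; logistic is 0.5 at its inflection
  st1 <- predictor_stack(list(MinT = bam_grid(matrix(10, 1, 1), c(0, 1, 0, 1), 1)))
  g1 <- true_suitability(virtual_niche(list(
    MinT = list(kind = "gaussian", optimum = 10, breadth = 2)), 0.5), st1)
  expect_equal(g1$suitability$values[1, 1], 1)
  l1 <- true_suitability(virtual_niche(list(
    MinT = list(kind = "logistic", inflection = 10, slope = 2)), 0.4), st1)
  expect_equal(l1$suitability$values[1, 1], 0.5)
  expect_true(all(ts$suitability$values[ts$suitability$mask] >= 0))
  expect_true(all(ts$suitability$values[ts$suitability$mask] <= 1))
  expect_error(virtual_niche(list(MinT = list(kind = "step"))), "kind")
})

test_that("the default presence threshold is the landscape-mean suitability", {
  st <- generate_climate_stack(seed = 8, shape = c(25, 25))
  n <- virtual_niche(list(
    MinT = list(kind = "gaussian",
                optimum = median(st$layers$MinT$values), breadth = 2)))
  ts <- true_suitability(n, st)
  expect_equal(ts$threshold, mean(ts$suitability$values[ts$suitability$mask]))
  expect_equal(ts$range$values[ts$range$mask],
               as.numeric(ts$suitability$values[ts$suitability$mask] >= ts$threshold))
})

test_that("occurrence sampling is suitability-proportional and avoids zero-mass cells", {
  v <- matrix(0, 2, 2)
  v[1, 1] <- 0.6; v[2, 2] <- 0.2  # two cells with mass, two with zero
  g <- bam_grid(v, c(0, 2, 0, 2), 1, kind = "probability")
  occ <- sample_occurrences(g, 200, seed = 3)
  expect_equal(nrow(occ), 200L)
  key <- paste(occ$lon, occ$lat)
  expect_true(all(key %in% c("0.5 1.5", "1.5 0.5")))  # centers of the two mass cells

  # empirical frequencies match suitability proportions within 3 standard errors
  big <- sample_occurrences(g, 20000, seed = 4)
  p_hat <- mean(big$lon == 0.5)
  p_true <- 0.6 / 0.8
  se <- sqrt(p_true * (1 - p_true) / 20000)
  expect_lt(abs(p_hat - p_true), 3 * se)

  expect_identical(sample_occurrences(g, 50, seed = 9)$lon,
                   sample_occurrences(g, 50, seed = 9)$lon)
  empty <- bam_grid(matrix(0, 2, 2), c(0, 2, 0, 2), 1, kind = "probability")
  expect_error(sample_occurrences(empty, 5), "zero")
})

test_that("occurrences from a threshold-zero niche all fall inside the true range", {
  st <- generate_climate_stack(seed = 12, shape = c(25, 25))
  n <- virtual_niche(list(
    MinT = list(kind = "gaussian", optimum = median(st$layers$MinT$values),
                breadth = sd(st$layers$MinT$values))),
    presence_threshold = 0)
  ts <- true_suitability(n, st)
  occ <- sample_occurrences(ts$suitability, 300, seed = 2)
  ex <- extract_values(st, occ$lon, occ$lat)
  idx <- cell_index(st$layers[[1]], occ$lon, occ$lat)
  inside <- mapply(function(r, c) ts$range$values[r, c], idx[, 1], idx[, 2])
  expect_true(all(inside == 1))
})

test_that("virtual pairs realise each target case and verify under the default epsilon", {
  st <- generate_climate_stack(seed = 30, shape = c(40, 40))
  for (case in 1:3) {
    pair <- make_virtual_pair(st, case, seed = 44)
    res <- bam_combine(pair$true_A, pair$true_B)
    expect_equal(res$diagnosis,
                 c("B_subset_A", "A_subset_B", "partial_overlap")[case])
    if (case == 3)
      expect_true(all(res$counts[c("g_bi", "bi", "overlap")] > 0))
  }
  expect_error(make_virtual_pair(st, 4), "target_case")
})

test_that("simulated datasets on disk are reloadable, truthful and seed-stable", {
  d <- withr::local_tempdir()
  man <- simulate_virtual_data(d, target_case = 1, seed = 21,
                               shape = c(30, 30), n_occurrences = 80)
  expect_equal(man$diagnosis, "B_subset_A")
  st <- predictor_stack(sapply(man$predictors, function(nm)
    read_grid(file.path(d, paste0(nm, ".asc"))), simplify = FALSE))
  occ <- read_occurrences(file.path(d, "symbiont_occurrences.csv"))
  expect_equal(nrow(occ), 80L)
  tA <- read_grid(file.path(d, "true_A.asc"), kind = "binary")
  tB <- read_grid(file.path(d, "true_B.asc"), kind = "binary")
  res <- bam_combine(tA, tB)
  expect_equal(res$diagnosis, "B_subset_A")
  expect_equal(res$counts, bf_bam_counts(tA, tB))

  d2 <- withr::local_tempdir()
  simulate_virtual_data(d2, target_case = 1, seed = 21,
                        shape = c(30, 30), n_occurrences = 80)
  expect_identical(readLines(file.path(d, "MinT.asc")),
                   readLines(file.path(d2, "MinT.asc")))
  expect_identical(readLines(file.path(d, "symbiont_occurrences.csv")),
                   readLines(file.path(d2, "symbiont_occurrences.csv")))
})
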