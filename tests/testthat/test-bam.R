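test_that("identical maps give empty differences and overlap equal to A", {
  A <- binary_from_cells(list(c(1, 1), c(2, 2), c(3, 3)))
  res <- bam_combine(A, A)
  expect_equal(unname(res$counts[c("g_bi", "bi", "overlap")]), c(0, 3, 3)[c(1, 1, 3)])
  expect_equal(res$overlap$values, A$values)
  expect_equal(res$diagnosis, "equal")
})

test_that("the 3x3 toy decomposition matches cell enumeration", {
  A <- binary_from_cells(list(c(1, 1), c(1, 2), c(2, 2)), nr = 3, nc = 3)
  B <- binary_from_cells(list(c(2, 2), c(3, 3)), nr = 3, nc = 3)
  res <- bam_combine(A, B)
  expect_equal(unname(res$counts["g_bi"]), 2)
  expect_equal(unname(res$counts["bi"]), 1)
  expect_equal(unname(res$counts["overlap"]), 1)
  expect_equal(res$counts, bf_bam_counts(A, B))
})

test_that("a strict subset yields an empty complementary part", {
  A <- binary_from_cells(list(c(1, 1), c(1, 2), c(2, 1), c(2, 2), c(3, 3)))
  B <- binary_from_cells(list(c(1, 1), c(2, 2)))
  res <- bam_combine(A, B)
  expect_equal(unname(res$counts["bi"]), 0)
  expect_equal(unname(res$counts["g_bi"]), unname(res$counts["A"] - res$counts["B"]))
  expect_equal(res$diagnosis, "B_subset_A")
})

test_that("partition identities hold on random pairs against the enumeration oracle", {
  set.seed(13)
  for (i in 1:100) {
    p <- random_binary_pair()
    res <- tryCatch(bam_combine(p$A, p$B), error = function(e) NULL)
    if (is.null(res)) next
    expect_equal(res$counts, bf_bam_counts(p$A, p$B))
    m <- res$g_bi$mask
    gb <- res$g_bi$values[m]; bi <- res$bi$values[m]; ov <- res$overlap$values[m]
    expect_true(all(gb * bi == 0))                        # disjoint parts
    expect_equal(pmax(gb, ov), res$A$values[m])           # g_bi | overlap == A
    expect_equal(pmax(bi, ov), res$B$values[m])           # bi | overlap == B
    expect_equal(unname(res$counts["A"]), unname(res$counts["g_bi"] + res$counts["overlap"]))
    expect_equal(unname(res$counts["B"]), unname(res$counts["bi"] + res$counts["overlap"]))
    if (res$counts["union"] > 0)
      expect_equal(sum(res$shares$cell_count), 1)
    # swapping the arguments swaps g_bi and bi exactly
    swp <- bam_combine(p$B, p$A)
    expect_equal(swp$g_bi$values, res$bi$values)
    expect_equal(swp$bi$values, res$g_bi$values)
  }
})

test_that("mismatched lattices and non-binary inputs are rejected", {
  A <- binary_from_cells(list(c(1, 1)), nr = 3, nc = 3)
  B <- binary_from_cells(list(c(1, 1)), nr = 4, nc = 4)
  expect_error(bam_combine(A, B), "lattice")
  P <- bam_grid(matrix(0.5, 3, 3), c(0, 3, 0, 3), 1, kind = "probability")
  expect_error(bam_combine(P, A), "binary")
})

test_that("area proportions follow counts and cosine-latitude weighting", {
  # counts (2, 1, 1) over union 4 -> shares (0.5, 0.25, 0.25)
  A <- binary_from_cells(list(c(1, 1), c(1, 2), c(2, 2)), nr = 3, nc = 3)
  B <- binary_from_cells(list(c(2, 2), c(3, 3)), nr = 3, nc = 3)
  res <- bam_combine(A, B)
  expect_equal(unname(res$shares$cell_count), c(0.5, 0.25, 0.25))

  # two single-cell parts at lat 0 and 60 -> cos weights 1 and 0.5 -> 2/3, 1/3
  ext <- c(0, 1, -0.5, 60.5)  # 61 rows of 1 degree; centers at 60, ..., 0
  mkg <- function(rows) {
    v <- matrix(0, 61, 1); v[rows, 1] <- 1
    bam_grid(v, ext, 1, kind = "binary")
  }
  A2 <- mkg(61)            # center latitude 0
  B2 <- mkg(1)             # center latitude 60
  res2 <- bam_combine(A2, B2)
  expect_equal(unname(res2$shares$cos_latitude[c("g_bi", "bi")]),
               c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(sum(res2$shares$cos_latitude), 1)
})

test_that("diagnosis applies the epsilon rule, including the host-limited symbiont pattern", {
  mk_res <- function(g_bi, bi, overlap) {
    sh <- c(g_bi = g_bi, bi = bi, overlap = overlap)
    list(shares = list(cell_count = sh / sum(sh), cos_latitude = sh / sum(sh)))
  }
  expect_equal(diagnose_bam(mk_res(0.4, 0.3, 0.3)), "partial_overlap")
  # climatically narrow symbiont on a widespread host: tiny g_bi, large bi
  expect_equal(diagnose_bam(mk_res(0.004, 0.25, 0.746)), "A_subset_B")
  expect_equal(diagnose_bam(mk_res(0.3, 0.004, 0.696)), "B_subset_A")
  expect_equal(diagnose_bam(mk_res(0.004, 0.003, 0.993)), "equal")
  expect_equal(diagnose_bam(mk_res(0.6, 0.4, 0)), "disjoint")
})

test_that("diagnosis is invariant to uniform dilation under cell-count weighting", {
  A <- binary_from_cells(list(c(1, 1), c(1, 2), c(2, 2)), nr = 4, nc = 4)
  B <- binary_from_cells(list(c(2, 2), c(3, 3)), nr = 4, nc = 4)
  base <- bam_combine(A, B)
  # dilate each cell into a 3x3 block
  dil <- function(g) {
    v <- g$values[rep(seq_len(nrow(g$values)), each = 3),
                  rep(seq_len(ncol(g$values)), each = 3)]
    bam_grid(v, g$extent, g$resolution / 3, kind = "binary")
  }
  big <- bam_combine(dil(A), dil(B))
  expect_equal(big$shares$cell_count, base$shares$cell_count)
  expect_equal(diagnose_bam(big), diagnose_bam(base))
})

test_that("BAM results round-trip through disk artifacts", {
  A <- binary_from_cells(list(c(1, 1), c(1, 2), c(2, 2)), nr = 3, nc = 3)
  B <- binary_from_cells(list(c(2, 2), c(3, 3)), nr = 3, nc = 3)
  res <- bam_combine(A, B)
  d <- withr::local_tempdir()
  write_bam_result(res, d)
  expect_true(file.exists(file.path(d, "summary.json")))
  js <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_equal(js$diagnosis, res$diagnosis)
  expect_equal(js$counts$g_bi, unname(res$counts["g_bi"]))
  g2 <- read_grid(file.path(d, "g_bi.asc"), kind = "binary")
  expect_equal(g2$values, res$g_bi$values)
})
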