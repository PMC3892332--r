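# Shared fixtures and independent oracles.  Oracles are deliberately
# naive (pair counting, exhaustive scans, cell enumeration) so they stay
# independent of the implementation paths they check.

# Small fully-valid predictor stack with deterministic, position-derived
# layer values (no RNG).  Default: 10 x 10 one-degree cells over 0..10E,
# 40..50N.
tiny_stack <- function(nr = 10L, nc = 10L, res = 1, origin = c(0, 40),
                       nodata_cells = NULL) {
  extent <- c(origin[1], origin[1] + nc * res, origin[2], origin[2] + nr * res)
  row <- matrix(rep(seq_len(nr), nc), nr, nc)
  col <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  mk <- function(v) {
    if (!is.null(nodata_cells)) v[nodata_cells] <- NA_real_
    bam_grid(v, extent, res)
  }
  predictor_stack(list(
    MinT = mk(row + 0.1 * col),
    MaxT = mk(20 + col - 0.3 * row),
    AnPrec = mk(500 + 10 * row * col),
    PrecSeas = mk(30 + ((row * 7 + col * 3) %% 11))))
}

# Binary grid from a set of (row, col) presence cells on an nr x nc lattice.
binary_from_cells <- function(cells, nr = 5L, nc = 5L, res = 1, origin = c(0, 0)) {
  v <- matrix(0, nr, nc)
  for (rc in cells) v[rc[1], rc[2]] <- 1
  bam_grid(v, c(origin[1], origin[1] + nc * res, origin[2], origin[2] + nr * res),
           res, kind = "binary")
}

# Brute-force AUC: count concordant positive-negative pairs, ties 1/2.
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exhaustive threshold scan: candidates re-derived from scratch (sorted
# unique scores, adjacent midpoints, outer sentinels), objective
# sensitivity + specificity with classification score >= t, smallest
# maximiser wins.
bf_best_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- if (length(u) == 1) c(u - 0.5, u + 0.5) else {
    d <- min(diff(u)) / 2
    c(u[1] - d, (u[-length(u)] + u[-1]) / 2, u[length(u)] + d)
  }
  best_t <- NA; best_v <- -Inf
  for (t in cand) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    if (sens + spec > best_v + 1e-12) { best_v <- sens + spec; best_t <- t }
  }
  list(threshold = best_t, value = best_v)
}

# Enumeration oracle for the BAM parts of two binary grids on a shared mask.
bf_bam_counts <- function(A, B) {
  m <- A$mask & B$mask
  g_bi <- 0; bi <- 0; ov <- 0; a <- 0; b <- 0
  for (i in seq_len(nrow(A$values))) for (j in seq_len(ncol(A$values))) {
    if (!m[i, j]) next
    ia <- A$values[i, j] == 1; ib <- B$values[i, j] == 1
    a <- a + ia; b <- b + ib
    if (ia && !ib) g_bi <- g_bi + 1
    if (!ia && ib) bi <- bi + 1
    if (ia && ib) ov <- ov + 1
  }
  c(A = a, B = b, g_bi = g_bi, bi = bi, overlap = ov, union = a + b - ov)
}

# Lag-1 Moran's I with rook neighbours (naive double loop over edges).
bf_moran_i <- function(m) {
  z <- m - mean(m)
  num <- 0; w <- 0
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i < nr) { num <- num + z[i, j] * z[i + 1, j]; w <- w + 1 }
    if (j < nc) { num <- num + z[i, j] * z[i, j + 1]; w <- w + 1 }
  }
  (length(m) / (2 * w)) * (2 * num) / sum(z^2)
}

# Random binary grid pair on a shared lattice (some cells invalid in one
# map only, to exercise mask handling).
random_binary_pair <- function(nr = 8L, nc = 8L) {
  mk <- function() {
    v <- matrix(rbinom(nr * nc, 1, 0.45), nr, nc)
    v[sample.int(nr * nc, 3L)] <- NA_real_
    bam_grid(v, c(0, nc, 0, nr), 1, kind = "binary")
  }
  list(A = mk(), B = mk())
}
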