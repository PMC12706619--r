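# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately use different algorithms from the package
# (label propagation instead of union-find, full enumeration instead of
# dynamic programming) so that agreement is informative.

mk_mask <- function(grid, affine = diag(4)) binary_mask(grid, affine)

rand_mask <- function(dims, p = 0.4, seed = 1) {
  set.seed(seed)
  array(as.integer(stats::runif(prod(dims)) < p), dims)
}

# ball mask on an n^3 grid with unit spacing, centered mid-grid
ball_grid <- function(n, radius, center = rep((n - 1) / 2, 3)) {
  idx <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  d2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
    (idx[, 3] - center[3])^2
  array(as.integer(d2 < radius^2), c(n, n, n))
}

conn_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  m <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = m == 1, "18" = m <= 2, "26" = rep(TRUE, nrow(g)))
  as.matrix(g[keep, ])
}

# value of the neighbour at +o for every voxel (0 outside the grid)
shift_arr <- function(a, o) {
  d <- dim(a)
  out <- array(0L, d)
  xs <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
  ys <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
  zs <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
  if (length(xs) < 1 || length(ys) < 1 || length(zs) < 1) return(out)
  out[xs, ys, zs] <- a[xs + o[1], ys + o[2], zs + o[3]]
  out
}

# connected components by iterated min-label propagation (independent of
# the package's union-find); labels are arbitrary but consistent
oracle_label_components <- function(g, connectivity) {
  d <- dim(g)
  fg <- g != 0
  lab <- array(0L, d)
  lab[fg] <- which(fg)
  offs <- conn_offsets(connectivity)
  repeat {
    new <- lab
    for (r in seq_len(nrow(offs))) {
      nb <- shift_arr(lab, offs[r, ])
      upd <- fg & nb > 0L & (new == 0L | nb < new)
      new[upd] <- nb[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# do two labelings induce the same partition of the foreground?
same_partition <- function(lab_a, lab_b) {
  fg <- lab_a > 0
  if (!identical(fg, lab_b > 0)) return(FALSE)
  tab <- table(lab_a[fg], lab_b[fg])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

oracle_largest_component <- function(g, connectivity) {
  lab <- oracle_label_components(g, connectivity)
  ids <- sort(unique(lab[lab > 0]))
  sizes <- vapply(ids, function(l) sum(lab == l), 0L)
  best <- ids[sizes == max(sizes)]
  if (length(best) > 1) {
    d <- dim(g)
    key <- vapply(best, function(l) {
      v <- which(lab == l, arr.ind = TRUE) - 1L
      min((as.numeric(v[, 1]) * d[2] + v[, 2]) * d[3] + v[, 3])
    }, 0)
    best <- best[which.min(key)]
  }
  array(as.integer(lab == best), dim(g))
}

oracle_fill_holes <- function(g) {
  d <- dim(g)
  lab <- oracle_label_components(array(as.integer(g == 0L), d), 6)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0]
  array(as.integer(g != 0L | (lab > 0 & !(lab %in% border))), d)
}

oracle_dice <- function(ga, gb) {
  a <- which(ga != 0); b <- which(gb != 0)
  if (length(a) + length(b) == 0) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# exact two-sided signed-rank p by full enumeration of sign assignments
oracle_wilcoxon_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  S <- sum(r)
  ws <- vapply(0:(2^n - 1), function(bits) {
    sum(r[bitwAnd(bits, 2^(seq_len(n) - 1)) > 0])
  }, 0)
  hi <- max(W, S - W); lo <- min(W, S - W)
  list(W = W, p = min(1, mean(ws >= hi) + mean(ws <= lo)))
}

# 6-neighbourhood boundary voxels (either phase) by explicit loops
oracle_boundary <- function(g) {
  d <- dim(g)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- g[i, j, k]
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      nb <- if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
                kk < 1 || kk > d[3]) 0L else g[ii, jj, kk]
      if (nb != v) { out[i, j, k] <- TRUE; break }
    }
  }
  out
}
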