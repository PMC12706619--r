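test_that("largest_component keeps a lone sphere and drops a smaller satellite", {
  g <- ball_grid(21, 5)
  m <- mk_mask(g)
  expect_identical(largest_component(m)$grid, g)

  g2 <- g
  g2[20, 20, 20] <- 1L   # isolated voxel far from the sphere
  out <- largest_component(mk_mask(g2))
  expect_identical(out$grid, g)
})

test_that("largest_component breaks size ties lexicographically", {
  # two equal 2x2x2 cubes; cube B's minimum 0-based index (0,0,6) precedes
  # cube A's (0,6,0) in (i, j, k) lexicographic order
  g <- array(0L, c(8, 8, 8))
  g[1:2, 7:8, 1:2] <- 1L  # cube A
  g[1:2, 1:2, 7:8] <- 1L  # cube B
  out <- largest_component(mk_mask(g))
  expected <- array(0L, c(8, 8, 8))
  expected[1:2, 1:2, 7:8] <- 1L
  expect_identical(out$grid, expected)
  # the oracle agrees on sizes and on the tie-break
  expect_identical(oracle_largest_component(g, 26), expected)
  expect_error(largest_component(mk_mask(array(0L, c(3, 3, 3)))), "empty")
})

test_that("connectivity changes which voxels join a component", {
  g <- array(0L, c(4, 4, 4))
  g[1, 1, 1] <- 1L
  g[2, 2, 2] <- 1L  # diagonal neighbour: connected at 26, not at 6
  lab26 <- largest_component(mk_mask(g), connectivity = 26)
  expect_identical(sum(lab26$grid), 2L)
  lab6 <- largest_component(mk_mask(g), connectivity = 6)
  expect_identical(sum(lab6$grid), 1L)
})

test_that("fill_holes fills enclosed voids and leaves open concavities alone", {
  shell <- array(0L, c(11, 11, 11))
  shell[2:10, 2:10, 2:10] <- 1L
  shell[3:9, 3:9, 3:9] <- 0L   # hollow 9^3 shell
  solid <- array(0L, c(11, 11, 11))
  solid[2:10, 2:10, 2:10] <- 1L
  expect_identical(fill_holes(mk_mask(shell))$grid, solid)

  sphere <- ball_grid(15, 5)
  expect_identical(fill_holes(mk_mask(sphere))$grid, sphere)

  # C-shape: concavity open to the border must stay background
  cshape <- array(0L, c(9, 9, 3))
  cshape[2:8, 2:8, 2] <- 1L
  cshape[4:6, 4:8, 2] <- 0L   # slot open towards the j = 9 border
  expect_identical(fill_holes(mk_mask(cshape))$grid, cshape)
})

test_that("drop_small_components keeps both ventricle-like bodies", {
  g <- array(0L, c(30, 20, 10))
  g[3:10, 3:16, 3:8] <- 1L    # left body, 672 voxels
  g[20:27, 3:16, 3:8] <- 1L   # right body, 672 voxels
  g[15, 18, 9] <- 1L          # spurious speck
  out <- drop_small_components(mk_mask(g))
  expect_identical(sum(out$grid), 1344L)
  expect_identical(out$grid[15, 18, 9], 0L)
})

test_that("frontal_horn_mask keeps voxels strictly anterior to the IVF", {
  # bar along y covering world y in [-10, 10] at 1 mm spacing
  g <- array(0L, c(3, 21, 3))
  g[2, , 2] <- 1L
  A <- diag(4); A[2, 4] <- -10
  lv <- mk_mask(g, A)
  out <- frontal_horn_mask(lv, c(0, 0, 0))
  expect_identical(sum(out$grid), 10L)     # y = 1..10 of 21 columns
  ys <- which(apply(out$grid, 2, sum) > 0)
  expect_identical(min(ys), 12L)           # first column with y = 1 > 0

  expect_identical(frontal_horn_mask(lv, c(0, -11, 0))$grid, g)
  expect_error(frontal_horn_mask(lv, c(0, 11, 0)), "anterior to IVF")
})

test_that("frontal mask and posterior remainder partition the input", {
  for (seed in 1:5) {
    g <- rand_mask(c(12, 14, 9), 0.35, seed)
    if (!any(g != 0)) next
    A <- diag(4); A[2, 4] <- -6
    lv <- mk_mask(g, A)
    ivf <- c(0, 1.2, 0)
    front <- tryCatch(frontal_horn_mask(lv, ivf), error = function(e) NULL)
    if (is.null(front)) next
    post <- g
    post[front$grid == 1L] <- 0L
    expect_true(all(front$grid + post == g))          # union, disjoint
    expect_identical(sum(front$grid * post), 0L)
  }
})

test_that("mask_volume_mm3 scales with voxel volume", {
  g <- array(0L, c(5, 5, 5)); g[1:10] <- 1L
  expect_equal(mask_volume_mm3(mk_mask(g)), 10)
  expect_equal(mask_volume_mm3(mk_mask(g, diag(c(2, 2, 2, 1)))), 80)
  expect_equal(mask_volume_mm3(mk_mask(array(0L, c(5, 5, 5)))), 0)
})

test_that("dice matches the set formula and its edge cases", {
  cube <- array(0L, c(6, 6, 6)); cube[2:3, 2:3, 2:3] <- 1L
  shifted <- array(0L, c(6, 6, 6)); shifted[2:3, 2:3, 3:4] <- 1L  # 4 overlap
  expect_equal(dice(mk_mask(cube), mk_mask(cube)), 1)
  expect_equal(dice(mk_mask(cube), mk_mask(shifted)), 0.5)
  disjoint <- array(0L, c(6, 6, 6)); disjoint[5:6, 5:6, 5:6] <- 1L
  expect_equal(dice(mk_mask(cube), mk_mask(disjoint)), 0)
  empty <- mk_mask(array(0L, c(6, 6, 6)))
  expect_equal(dice(empty, empty), 1)
  expect_error(dice(mk_mask(cube), mk_mask(array(0L, c(5, 6, 6)))), "shape")
  expect_error(dice(mk_mask(cube), mk_mask(cube, diag(c(2, 1, 1, 1)))),
               "affine")

  for (seed in 1:20) {
    a <- rand_mask(c(10, 10, 10), 0.3, seed)
    b <- rand_mask(c(10, 10, 10), 0.3, seed + 100)
    expect_equal(dice(mk_mask(a), mk_mask(b)), oracle_dice(a, b))
    expect_equal(dice(mk_mask(a), mk_mask(b)), dice(mk_mask(b), mk_mask(a)))
  }
})

test_that("morphology operators are idempotent and monotone", {
  for (seed in 1:6) {
    g <- rand_mask(c(14, 12, 10), 0.45, seed)
    if (!any(g != 0)) next
    m <- mk_mask(g)
    lc <- largest_component(m)
    expect_identical(largest_component(lc)$grid, lc$grid)
    expect_lte(sum(lc$grid), sum(g))
    fh <- fill_holes(m)
    expect_identical(fill_holes(fh)$grid, fh$grid)
    expect_gte(sum(fh$grid), sum(g))
  }
})

test_that("component labelling and hole filling agree with the propagation oracle", {
  for (seed in 1:12) {
    dims <- c(sample(8:16, 1), sample(8:16, 1), sample(8:16, 1))
    g <- rand_mask(dims, runif(1, 0.25, 0.6), seed)
    if (!any(g != 0)) next
    for (conn in c(6, 26)) {
      impl <- evansindex:::cc_label(g, conn)
      orac <- oracle_label_components(g, conn)
      expect_true(same_partition(impl, orac))
      expect_identical(largest_component(mk_mask(g), conn)$grid,
                       oracle_largest_component(g, conn))
    }
    expect_identical(fill_holes(mk_mask(g))$grid, oracle_fill_holes(g))
  }
})
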