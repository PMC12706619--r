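test_that("slice width follows the edge-to-edge convention", {
  g <- array(0L, c(40, 5, 5))
  g[4:33, 3, 3] <- 1L   # 30 voxels along x, one slice
  m <- mk_mask(g)
  w <- max_lateral_width(m)
  expect_equal(w$width_mm, 30)
  expect_equal(max_lateral_width(m, convention = "center")$width_mm, 29)
  expect_identical(w$z_index, 2L)
  # endpoint invariant: center-to-center extent = width - one x-spacing
  expect_equal(abs(w$endpoint_a[1] - w$endpoint_b[1]), w$width_mm - 1)
  expect_equal(w$endpoint_a[3], w$endpoint_b[3])
  expect_error(max_lateral_width(mk_mask(array(0L, c(4, 4, 4)))), "empty")
})

test_that("two separated spheres measure their outer width within a voxel", {
  # spheres of radius 5 centered at x = +/-12 -> true outer width 34
  g <- array(0L, c(41, 21, 21))
  for (s in c(-1, 1)) {
    cx <- 20 + s * 12
    for (i in 0:40) for (j in 0:20) for (k in 0:20) {
      if ((i - cx)^2 + (j - 10)^2 + (k - 10)^2 < 25) g[i + 1, j + 1, k + 1] <- 1L
    }
  }
  w <- max_lateral_width(mk_mask(g))
  expect_lte(abs(w$width_mm - 34), 1)
})

test_that("the argmax slice wins and ties break towards smaller z", {
  g <- array(0L, c(50, 5, 50))
  g[10:40, 3, 41] <- 1L   # z = 40 (0-based), width 31+1
  g[11:40, 3, 44] <- 1L   # z = 43, one voxel narrower
  w <- max_lateral_width(mk_mask(g))
  expect_identical(w$z_index, 40L)
  g[10:40, 3, 45] <- 1L   # equal-width slice at larger z: tie -> z = 40
  expect_identical(max_lateral_width(mk_mask(g))$z_index, 40L)
})

test_that("inner-skull width at a slice matches an analytic ellipsoid", {
  # ellipsoid with semi-axes (70, 50, 30) on a 0-centered 1 mm grid
  n <- c(150, 110, 70)
  ctr <- (n - 1) / 2
  idx <- as.matrix(expand.grid(0:(n[1] - 1), 0:(n[2] - 1), 0:(n[3] - 1)))
  inside <- ((idx[, 1] - ctr[1]) / 70)^2 + ((idx[, 2] - ctr[2]) / 50)^2 +
    ((idx[, 3] - ctr[3]) / 30)^2 < 1
  g <- array(as.integer(inside), n)
  icv <- mk_mask(g)
  mid_z <- as.integer(round(ctr[3]))
  d <- inner_skull_width_at_slice(icv, mid_z)
  expect_lte(abs(d$width_mm - 140), 1)
  expect_error(inner_skull_width_at_slice(icv, 69L), "does not cover")

  bar <- array(0L, c(120, 5, 5)); bar[6:105, 3, 3] <- 1L
  expect_equal(inner_skull_width_at_slice(mk_mask(bar), 2L)$width_mm, 100)
})

test_that("max-chord diameter is at least the lateral diameter", {
  n <- c(60, 80, 5)
  idx <- as.matrix(expand.grid(0:59, 0:79, 0:4))
  inside <- ((idx[, 1] - 29.5) / 20)^2 + ((idx[, 2] - 39.5) / 35)^2 < 1
  g <- array(as.integer(inside & idx[, 3] == 2), n)
  m <- mk_mask(g)
  lat <- inner_skull_width_at_slice(m, 2L, mode = "lateral")
  chord <- inner_skull_width_at_slice(m, 2L, mode = "max_chord")
  expect_gte(chord$width_mm, lat$width_mm)
  expect_lte(abs(chord$width_mm - 70), 1.5)  # long axis of the ellipse
})

test_that("the full pipeline recovers the default phantom's Evans Index", {
  ph <- make_phantom(phantom_spec())
  res <- compute_evans_index(ph$lv, ph$icv, ph$landmarks)
  expect_lte(abs(res$evans_index - ph$truth$true_ei), 0.012)
  expect_lte(res$frontal_horn_width_mm, res$inner_skull_diameter_mm)
  expect_true(res$ventriculomegaly)  # 0.30 >= 0.30 threshold
  expect_lte(abs(res$frontal_horn_width_mm - 30), 1)
  expect_lte(abs(res$inner_skull_diameter_mm - 100), 1)
})

test_that("Evans Index is exactly invariant under integer-voxel translation", {
  ph <- make_phantom(phantom_spec())
  res0 <- compute_evans_index(ph$lv, ph$icv, ph$landmarks)
  shift <- c(7, -4, 3)
  A <- ph$lv$affine
  A[1:3, 4] <- A[1:3, 4] + shift
  lv2 <- binary_mask(ph$lv$grid, A)
  icv2 <- binary_mask(ph$icv$grid, A)
  lm2 <- landmark_set(ph$landmarks$ac + shift, ph$landmarks$pc + shift,
                      ph$landmarks$ivf + shift)
  res1 <- compute_evans_index(lv2, icv2, lm2)
  expect_identical(res1$evans_index, res0$evans_index)
  expect_identical(res1$frontal_horn_width_mm, res0$frontal_horn_width_mm)
  expect_identical(res1$inner_skull_diameter_mm, res0$inner_skull_diameter_mm)
})

test_that("ventriculomegaly classification uses a >= threshold", {
  expect_true(classify_ventriculomegaly(0.31))
  expect_false(classify_ventriculomegaly(0.29))
  expect_true(classify_ventriculomegaly(0.30))
  expect_true(classify_ventriculomegaly(0.28, threshold = 0.25))
  expect_error(classify_ventriculomegaly(1.2), "out of range")
  expect_error(classify_ventriculomegaly(0), "out of range")
})

test_that("LV/ICV volume ratio matches counts and the analytic phantom ratio", {
  lv <- array(0L, c(12, 12, 12)); lv[1:100] <- 1L
  icv <- array(0L, c(12, 12, 12)); icv[1:1000] <- 1L
  expect_equal(lv_icv_ratio(mk_mask(lv), mk_mask(icv)), 0.1)
  expect_equal(lv_icv_ratio(mk_mask(array(0L, c(12, 12, 12))), mk_mask(icv)), 0)
  expect_error(lv_icv_ratio(mk_mask(lv), mk_mask(array(0L, c(12, 12, 12)))),
               "empty")

  sp <- phantom_spec()
  ph <- make_phantom(sp)
  v_horns <- 2 * 4 / 3 * pi * sp$horn_radius^3
  v_bodies <- 2 * diff(sp$body_x) * diff(sp$body_y) * 2 * sp$body_half_z
  v_icv <- 4 / 3 * pi * prod(sp$skull_semiaxes)
  truth_ratio <- (v_horns + v_bodies) / v_icv
  expect_lte(abs(lv_icv_ratio(ph$lv, ph$icv) / truth_ratio - 1), 0.05)
})

test_that("Evans Index agrees across 1 mm and 0.5 mm phantom resolutions", {
  r1 <- with(make_phantom(phantom_spec(spacing = 1)),
             compute_evans_index(lv, icv, landmarks))
  r05 <- with(make_phantom(phantom_spec(spacing = 0.5)),
              compute_evans_index(lv, icv, landmarks))
  expect_lte(abs(r1$evans_index - r05$evans_index), 0.01)
})

test_that("implausible-geometry guards trigger", {
  ph <- make_phantom(phantom_spec())
  # ventricles wider than the skull are geometrically implausible
  expect_error(compute_evans_index(ph$icv, ph$lv, ph$landmarks),
               "implausible|exceeds")
  lv_off <- binary_mask(ph$lv$grid, ph$lv$affine %*% diag(c(1, 1, 1, 1)) + 0)
  icv_small <- binary_mask(ph$icv$grid[-1, , ],
                           ph$icv$affine)
  expect_error(compute_evans_index(lv_off, icv_small, ph$landmarks),
               "identical grids")
})
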