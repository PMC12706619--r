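#' Synthetic head-phantom specification
#'
#' Defines an analytic head phantom: the inner skull as an ellipsoid, the
#' lateral ventricles as two mirrored frontal-horn spheres joined through
#' para-midline stalks (crossing the IVF plane, as the foramen of Monro
#' does) to posterior body blocks, plus AC/PC/IVF landmarks on the midline.
#' The frontal-horn spheres sit at the skull's equatorial plane z = 0, so
#' the inner-skull diameter at the matched axial slice is exactly `2a` and
#' the ground truth is closed-form: true width `W = 2 (x_h + r)`, true
#' Evans Index `W / (2a)`.
#'
#' Default dimensions scale a typical adult inner vault (about
#' 140 x 170 x 120 mm) to the 100-mm lateral diameter used throughout the
#' validation phantoms.
#'
#' @param skull_semiaxes Ellipsoid semiaxes (a, b, c) in mm along x, y, z.
#' @param horn_radius Frontal-horn sphere radius r, mm.
#' @param horn_center_x Horn sphere center offset x_h from the midline, mm.
#' @param horn_center_y Horn sphere center y, mm; must be anterior to the IVF.
#' @param body_x Posterior ventricle-body block |x|-range (lo, hi), mm,
#'   mirrored about the midline; the outer bound must stay inside the true
#'   frontal-horn width so the horns remain the widest frontal structure.
#' @param body_y Posterior ventricle-body block y-range (lo, hi), mm; the
#'   blocks must lie strictly posterior to the IVF (hi < ivf_y).
#' @param body_half_z Body block half-extent in z, mm.
#' @param ac,pc,ivf Landmark coordinates, world mm.
#' @param spacing Isotropic voxel spacing, mm (default 1).
#' @param padding Grid padding beyond the skull, mm (default 25; at least
#'   20 is required when rotations up to 20 degrees will be applied).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(skull_semiaxes = c(50, 60, 43),
                         horn_radius = 5,
                         horn_center_x = 10,
                         horn_center_y = 32,
                         body_x = c(2, 9),
                         body_y = c(-30, 10),
                         body_half_z = 8,
                         ac = c(0, 18, 0),
                         pc = c(0, -8, 0),
                         ivf = c(0, 16, 0),
                         spacing = 1,
                         padding = 25) {
  a <- skull_semiaxes[1]; b <- skull_semiaxes[2]; c_ <- skull_semiaxes[3]
  r <- horn_radius; x_h <- horn_center_x; y_h <- horn_center_y
  if (any(skull_semiaxes <= 0) || r <= 0 || x_h <= 0 || spacing <= 0 ||
      padding < 0)
    stop("phantom dimensions must be positive")
  W <- 2 * (x_h + r)
  if (W >= 2 * a)
    stop("true width ", W, " must be smaller than the skull diameter ", 2 * a)
  if ((x_h / (a - r))^2 + (y_h / (b - r))^2 >= 1)
    stop("horn spheres are not inside the skull ellipsoid")
  lm <- landmark_set(ac, pc, ivf)   # validates AC anterior to PC
  if (y_h <= lm$ivf[2])
    stop("horn_center_y must be anterior to the IVF (y > ", lm$ivf[2], ")")
  if (body_y[1] >= body_y[2]) stop("body_y must be an increasing range")
  if (body_y[2] >= lm$ivf[2])
    stop("ventricle body blocks must be posterior to the IVF (body_y hi < ivf_y)")
  if (body_x[1] <= 0 || body_x[1] >= body_x[2]) stop("invalid body_x range")
  if (body_x[2] >= x_h + r)
    stop("body blocks may not be wider than the frontal horns")
  structure(list(skull_semiaxes = as.numeric(skull_semiaxes),
                 horn_radius = r, horn_center_x = x_h, horn_center_y = y_h,
                 body_x = as.numeric(body_x), body_y = as.numeric(body_y),
                 body_half_z = body_half_z,
                 landmarks = lm, spacing = spacing, padding = padding),
            class = "phantom_spec")
}

# analytic shape list for a spec, in the unrotated frame. The ventricle
# compartments are deliberately disjoint (horn spheres anterior to the IVF
# plane, body blocks strictly posterior to it): the LV postprocessing rule
# keeps all components above the size floor, so disconnection is handled
# by the pipeline rather than hidden by the fixture.
phantom_shapes <- function(spec) {
  a <- spec$skull_semiaxes
  r <- spec$horn_radius; x_h <- spec$horn_center_x; y_h <- spec$horn_center_y
  lv <- list(
    list(type = "sphere", center = c(x_h, y_h, 0), r = r),
    list(type = "sphere", center = c(-x_h, y_h, 0), r = r),
    list(type = "box", lo = c(spec$body_x[1], spec$body_y[1], -spec$body_half_z),
         hi = c(spec$body_x[2], spec$body_y[2], spec$body_half_z)),
    list(type = "box", lo = c(-spec$body_x[2], spec$body_y[1], -spec$body_half_z),
         hi = c(-spec$body_x[1], spec$body_y[2], spec$body_half_z)))
  icv <- list(list(type = "ellipsoid", center = c(0, 0, 0), semiaxes = a))
  list(lv = lv, icv = icv)
}

shape_bbox <- function(shape) {
  switch(shape$type,
         sphere = rbind(shape$center - shape$r, shape$center + shape$r),
         ellipsoid = rbind(shape$center - shape$semiaxes,
                           shape$center + shape$semiaxes),
         box = rbind(shape$lo, shape$hi))
}

# inclusion test on coordinate vectors. Curved surfaces use strict
# inclusion (<): a surface passing exactly through voxel centers is
# degenerate under closed inclusion (the tangent voxels flip under any
# resampling), and phantom dimensions routinely put surfaces on the grid.
# Boxes keep closed bounds so an N-voxel bar spans exactly N centers.
shape_test <- function(shape, px, py, pz) {
  switch(shape$type,
         sphere = {
           (px - shape$center[1])^2 + (py - shape$center[2])^2 +
             (pz - shape$center[3])^2 < shape$r^2
         },
         ellipsoid = {
           ((px - shape$center[1]) / shape$semiaxes[1])^2 +
             ((py - shape$center[2]) / shape$semiaxes[2])^2 +
             ((pz - shape$center[3]) / shape$semiaxes[3])^2 < 1
         },
         box = {
           px >= shape$lo[1] & px <= shape$hi[1] &
             py >= shape$lo[2] & py <= shape$hi[2] &
             pz >= shape$lo[3] & pz <= shape$hi[3]
         })
}

# rasterize shapes (optionally rotated forward by R about pivot) onto the
# phantom grid by voxel-center inclusion; returns an integer array.
# Curved shapes go through a compiled kernel (spheres are ellipsoids with
# equal semiaxes); boxes have small bounding boxes and stay vectorized R.
rasterize_shapes <- function(shapes, dims, origin, spacing, R = NULL,
                             pivot = c(0, 0, 0)) {
  grid <- array(0L, dims)
  Rm <- if (is.null(R)) diag(3) else R
  for (shape in shapes) {
    bb <- shape_bbox(shape)
    if (!is.null(R)) {
      corners <- as.matrix(expand.grid(bb[, 1], bb[, 2], bb[, 3]))
      fwd <- sweep(sweep(corners, 2, pivot) %*% t(R), 2, pivot, "+")
      bb <- rbind(apply(fwd, 2, min), apply(fwd, 2, max))
    }
    lo <- as.integer(pmax(floor((bb[1, ] - origin) / spacing) - 1, 0))
    hi <- as.integer(pmin(ceiling((bb[2, ] - origin) / spacing) + 1, dims - 1))
    if (any(lo > hi)) next
    if (shape$type %in% c("sphere", "ellipsoid")) {
      semi <- if (shape$type == "sphere") rep(shape$r, 3) else shape$semiaxes
      grid <- .fill_ellipsoid_cpp(grid, dim(grid), lo, hi,
                                  as.numeric(origin), rep(spacing, 3),
                                  Rm, as.numeric(pivot),
                                  as.numeric(shape$center), as.numeric(semi))
      dim(grid) <- dims
    } else {
      ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
      nx <- length(ii); ny <- length(jj); nz <- length(kk)
      px <- rep.int(ii * spacing + origin[1], ny * nz)
      py <- rep.int(rep(jj * spacing + origin[2], each = nx), nz)
      pz <- rep(kk * spacing + origin[3], each = nx * ny)
      if (!is.null(R)) {
        # back-map voxel centers: q = R^T (p - pivot) + pivot
        dx <- px - pivot[1]; dy <- py - pivot[2]; dz <- pz - pivot[3]
        px <- R[1, 1] * dx + R[2, 1] * dy + R[3, 1] * dz + pivot[1]
        py <- R[1, 2] * dx + R[2, 2] * dy + R[3, 2] * dz + pivot[2]
        pz <- R[1, 3] * dx + R[2, 3] * dy + R[3, 3] * dz + pivot[3]
      }
      inside <- shape_test(shape, px, py, pz)
      if (any(inside)) {
        sub <- grid[ii + 1, jj + 1, kk + 1]
        sub[inside] <- 1L
        grid[ii + 1, jj + 1, kk + 1] <- sub
      }
    }
  }
  grid
}

# Cell-centered grid, symmetric about the world origin: voxel centers sit
# at half-integer multiples of the spacing, so phantom surfaces with
# round-number dimensions fall on voxel boundaries rather than through
# voxel centers (center tangency is degenerate: those voxels flip under
# any resampling and bias measurements by a full voxel per side).
phantom_grid_geometry <- function(spec) {
  half <- spec$skull_semiaxes + spec$padding
  dims <- 2L * as.integer(ceiling(half / spec$spacing))
  origin <- -spec$spacing * (dims - 1) / 2
  affine <- diag(c(rep(spec$spacing, 3), 1))
  affine[1:3, 4] <- origin
  list(dims = dims, origin = origin, affine = affine)
}

phantom_truth <- function(spec, applied_rotation = NULL) {
  W <- 2 * (spec$horn_center_x + spec$horn_radius)
  D <- 2 * spec$skull_semiaxes[1]
  list(true_width_mm = W, true_diameter_mm = D, true_ei = W / D,
       true_z_mm = 0, applied_rotation = applied_rotation)
}

#' Generate a synthetic head phantom
#'
#' Voxelizes the analytic phantom of a [phantom_spec] by voxel-center
#' inclusion. The construction is deterministic: no randomness is involved.
#'
#' @param spec A [phantom_spec].
#' @return A list with elements `lv` and `icv` ([binary_mask]s on a common
#'   grid), `landmarks` ([landmark_set]) and `truth` (a list with
#'   `true_width_mm`, `true_diameter_mm`, `true_ei`, `true_z_mm` and
#'   `applied_rotation`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_grid_geometry(spec)
  shapes <- phantom_shapes(spec)
  lv <- rasterize_shapes(shapes$lv, geo$dims, geo$origin, spec$spacing)
  icv <- rasterize_shapes(shapes$icv, geo$dims, geo$origin, spec$spacing)
  list(lv = binary_mask(lv, geo$affine),
       icv = binary_mask(icv, geo$affine),
       landmarks = spec$landmarks,
       truth = phantom_truth(spec))
}

#' Generate a rotated head phantom
#'
#' Voxelizes the phantom directly in the rotated frame: the analytic shapes
#' are rotated about the AC-PC midpoint *before* voxelization and the
#' landmarks are rotated exactly. This separates the pipeline's resampling
#' error from the fixture's, so invariance tolerances are attributable to
#' the pipeline alone. An angle of 0 is voxel-identical to [make_phantom].
#'
#' @param spec A [phantom_spec] with padding >= 20 mm.
#' @param rotation A [rotation_spec] with |angle| <= 25 degrees.
#' @return Same structure as [make_phantom], with
#'   `truth$applied_rotation` recording the rotation.
#' @export
make_rotated_phantom <- function(spec, rotation) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(rotation, "rotation_spec"))
  if (abs(rotation$angle_deg) > 25)
    stop("|angle| must be <= 25 degrees")
  if (abs(rotation$angle_deg) > 0 && spec$padding < 20)
    stop("padding >= 20 mm required for rotated phantoms")
  geo <- phantom_grid_geometry(spec)
  lm <- spec$landmarks
  pivot <- (lm$ac + lm$pc) / 2
  R <- rotation_about(rotation_axis_vector(rotation$axis),
                      rotation$angle_deg * pi / 180)
  # containment: rotated skull bbox must stay inside the grid
  bb <- shape_bbox(phantom_shapes(spec)$icv[[1]])
  corners <- as.matrix(expand.grid(bb[, 1], bb[, 2], bb[, 3]))
  fwd <- sweep(sweep(corners, 2, pivot) %*% t(R), 2, pivot, "+")
  half <- geo$origin * -1
  if (any(apply(abs(fwd), 2, max) > half))
    stop("rotated shapes exit the grid; increase padding")
  shapes <- phantom_shapes(spec)
  Ruse <- if (rotation$angle_deg == 0) NULL else R
  lv <- rasterize_shapes(shapes$lv, geo$dims, geo$origin, spec$spacing,
                         Ruse, pivot)
  icv <- rasterize_shapes(shapes$icv, geo$dims, geo$origin, spec$spacing,
                          Ruse, pivot)
  t <- rigid_transform(R, pivot)
  list(lv = binary_mask(lv, geo$affine),
       icv = binary_mask(icv, geo$affine),
       landmarks = rotate_landmarks(lm, t),
       truth = phantom_truth(spec, rotation))
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Flip boundary voxels of a mask at random
#'
#' Emulates segmentation boundary noise: every boundary voxel (foreground
#' with at least one 6-connected background neighbour, or background with
#' at least one 6-connected foreground neighbour) flips independently with
#' probability `flip_prob`; interior voxels are untouched. Reproducible for
#' a given seed.
#'
#' @param mask A [binary_mask].
#' @param flip_prob Flip probability in \[0, 1\].
#' @param seed Integer RNG seed.
#' @return A [binary_mask].
#' @export
jitter_mask <- function(mask, flip_prob, seed) {
  mask <- as_binary_mask(mask)
  if (!is.finite(flip_prob) || flip_prob < 0 || flip_prob > 1)
    stop("flip_prob must be in [0, 1]")
  if (flip_prob == 0) return(mask)
  g <- mask$grid
  d <- dim(g)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- g
  differs <- array(FALSE, d)
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    nb <- pad[2:(d[1] + 1) + sh[1], 2:(d[2] + 1) + sh[2], 2:(d[3] + 1) + sh[3]]
    differs <- differs | (nb != g)
  }
  boundary <- which(differs)
  flips <- with_seed(seed, stats::runif(length(boundary)) < flip_prob)
  g[boundary[flips]] <- 1L - g[boundary[flips]]
  binary_mask(g, mask$affine)
}

#' Simulate paired automated/manual measurements
#'
#' Draws manual values uniformly over `ei_range` and automated values as
#' manual + `true_bias` + Normal(0, `sd`): the generative model behind the
#' Bland-Altman parameter-recovery checks.
#'
#' @param n Number of pairs (>= 2).
#' @param true_bias Systematic offset of the automated measurement.
#' @param sd SD of the random measurement error (>= 0).
#' @param ei_range Range (lo, hi) of the manual values, 0 < lo < hi < 1.
#' @param seed Integer RNG seed.
#' @return A data frame with columns `auto` and `manual`.
#' @export
simulate_paired_measurements <- function(n, true_bias, sd, ei_range = c(0.2, 0.45),
                                         seed = 1) {
  if (n < 2) stop("need n >= 2")
  if (sd < 0) stop("sd must be >= 0")
  lo <- ei_range[1]; hi <- ei_range[2]
  if (!(lo > 0 && lo < hi && hi < 1)) stop("invalid ei_range: need 0 < lo < hi < 1")
  with_seed(seed, {
    manual <- stats::runif(n, lo, hi)
    auto <- manual + true_bias + stats::rnorm(n, 0, sd)
    data.frame(auto = auto, manual = manual)
  })
}

#' Generate a cohort of phantom specifications
#'
#' Samples `n` true Evans Index values uniformly over `ei_range` (default
#' 0.22-0.42, spanning normal to hydrocephalus-like geometry around the
#' conventional 0.30 threshold) and builds one phantom spec per case by
#' varying the horn offset `x_h = a * EI - r`. Deterministic per seed.
#'
#' @param n Cohort size (>= 1).
#' @param seed Integer RNG seed.
#' @param ei_range True-EI sampling range.
#' @param dir Optional directory: when given, each case's masks (NIfTI),
#'   landmarks (JSON) and truth (JSON) are written there together with a
#'   `manifest.csv`.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return A list with `specs` (named list of [phantom_spec]) and
#'   `manifest` (data frame with `case_id`, `true_ei`, `horn_center_x`, and
#'   file paths when `dir` was given).
#' @export
generate_cohort <- function(n, seed, ei_range = c(0.22, 0.42), dir = NULL, ...) {
  if (n < 1) stop("need n >= 1")
  if (!(ei_range[1] > 0 && ei_range[1] < ei_range[2] && ei_range[2] < 1))
    stop("invalid ei_range")
  base <- phantom_spec(...)
  a <- base$skull_semiaxes[1]; r <- base$horn_radius
  true_ei <- with_seed(seed, stats::runif(n, ei_range[1], ei_range[2]))
  case_id <- sprintf("case%03d", seq_len(n))
  specs <- stats::setNames(lapply(true_ei, function(ei) {
    phantom_spec(skull_semiaxes = base$skull_semiaxes, horn_radius = r,
                 horn_center_x = a * ei - r,
                 horn_center_y = base$horn_center_y,
                 body_x = base$body_x, body_y = base$body_y,
                 body_half_z = base$body_half_z,
                 ac = base$landmarks$ac, pc = base$landmarks$pc,
                 ivf = base$landmarks$ivf,
                 spacing = base$spacing, padding = base$padding)
  }), case_id)
  manifest <- data.frame(case_id = case_id, true_ei = true_ei,
                         horn_center_x = a * true_ei - r)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- lapply(case_id, function(id) {
      ph <- make_phantom(specs[[id]])
      lv_p <- file.path(dir, paste0(id, "_lv.nii.gz"))
      icv_p <- file.path(dir, paste0(id, "_icv.nii.gz"))
      lm_p <- file.path(dir, paste0(id, "_landmarks.json"))
      tr_p <- file.path(dir, paste0(id, "_truth.json"))
      write_mask_volume(ph$lv, lv_p)
      write_mask_volume(ph$icv, icv_p)
      write_landmarks(ph$landmarks, lm_p)
      jsonlite::write_json(ph$truth[c("true_width_mm", "true_diameter_mm",
                                      "true_ei", "true_z_mm")],
                           tr_p, digits = NA, auto_unbox = TRUE)
      c(lv = lv_p, icv = icv_p, landmarks = lm_p, truth = tr_p)
    })
    pm <- do.call(rbind, paths)
    manifest <- cbind(manifest, as.data.frame(pm))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(specs = specs, manifest = manifest)
}

#' Run the rotational-perturbation protocol on phantom specs
#'
#' For each phantom spec, measures the baseline Evans Index on the neutral
#' phantom and then re-measures under controlled rotations, generated
#' analytically in the rotated frame. Two modes mirror the two readings of
#' a robustness protocol: `"blind"` measures in the acquisition frame
#' without AC-PC re-alignment; `"corrected"` runs the full pipeline, which
#' re-aligns from the (rotated) landmarks.
#'
#' @param specs A named list of [phantom_spec] (e.g. from
#'   [generate_cohort()]), or a single spec.
#' @param axes Character vector of rotation axes (default all three).
#' @param angles Numeric rotation angles in degrees
#'   (default +/-5, 10, 15, 20).
#' @param modes Character vector from `"blind"`, `"corrected"`.
#' @param ... Further arguments passed to [compute_evans_index()].
#' @return A long data frame with columns `case_id`, `axis`, `angle_deg`,
#'   `mode`, `ei`, `ei_baseline`, suitable for [perturbation_report()].
#' @export
perturbation_study <- function(specs,
                               axes = c("pitch", "yaw", "roll"),
                               angles = c(-20, -15, -10, -5, 5, 10, 15, 20),
                               modes = c("blind", "corrected"),
                               ...) {
  if (inherits(specs, "phantom_spec")) specs <- list(case001 = specs)
  modes <- match.arg(modes, several.ok = TRUE)
  rows <- list()
  for (id in names(specs)) {
    spec <- specs[[id]]
    ph0 <- make_phantom(spec)
    base <- compute_evans_index(ph0$lv, ph0$icv, ph0$landmarks, ...)$evans_index
    for (ax in axes) for (ang in angles) {
      ph <- make_rotated_phantom(spec, rotation_spec(ax, ang))
      for (mode in modes) {
        ei <- compute_evans_index(ph$lv, ph$icv, ph$landmarks,
                                  align = (mode == "corrected"), ...)$evans_index
        rows[[length(rows) + 1L]] <-
          data.frame(case_id = id, axis = ax, angle_deg = ang,
                     mode = mode, ei = ei, ei_baseline = base)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
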