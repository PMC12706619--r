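# internal: foreground voxel table with world coordinates (canonical RAS)
fg_world <- function(mask) {
  A <- mask$affine
  if (max(abs(A[1:3, 1:3] - diag(diag(A[1:3, 1:3])))) > 1e-9)
    stop("measurement requires a canonical RAS volume")
  idx <- which(mask$grid != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  list(idx0 = idx - 1L,
       x = A[1, 1] * (idx[, 1] - 1) + A[1, 4],
       y = A[2, 2] * (idx[, 2] - 1) + A[2, 4],
       z = A[3, 3] * (idx[, 3] - 1) + A[3, 4])
}

width_measurement <- function(width_mm, z_index, endpoint_a, endpoint_b) {
  structure(list(width_mm = width_mm, z_index = as.integer(z_index),
                 endpoint_a = endpoint_a, endpoint_b = endpoint_b),
            class = "width_measurement")
}

#' @export
print.width_measurement <- function(x, ...) {
  cat("<width_measurement> ", sprintf("%.2f", x$width_mm), " mm at slice z = ",
      x$z_index, "\n", sep = "")
  invisible(x)
}

#' Maximal left-right extent of a mask across axial slices
#'
#' For each axial slice with foreground, the width is the left-right extent
#' of the foreground voxel centers plus one x-spacing (edge-to-edge
#' convention: calipers measure between structure walls, not voxel centers;
#' `convention = "center"` gives the bare center-to-center extent for
#' sensitivity analysis). Returns the slice maximizing the width, ties
#' broken by the smallest slice index.
#'
#' @param mask A nonempty [binary_mask] in aligned canonical RAS space.
#' @param convention `"edge"` (default) or `"center"`.
#' @return A `width_measurement` with fields `width_mm`, `z_index` (0-based
#'   axial slice) and endpoint voxel-center world coordinates `endpoint_a`
#'   (leftmost) and `endpoint_b` (rightmost).
#' @export
max_lateral_width <- function(mask, convention = c("edge", "center")) {
  convention <- match.arg(convention)
  mask <- as_binary_mask(mask)
  fw <- fg_world(mask)
  if (is.null(fw)) stop("empty mask")
  sx <- mask$spacing[1]
  ks <- fw$idx0[, 3]
  xmin <- tapply(fw$x, ks, min)
  xmax <- tapply(fw$x, ks, max)
  w <- xmax - xmin + if (convention == "edge") sx else 0
  kvals <- as.integer(names(xmin))
  best <- kvals[w == max(w)]
  z <- min(best)           # tie-break: smallest slice index
  sel <- ks == z
  .endpoint <- function(target_x) {
    cand <- which(sel & abs(fw$x - target_x) < 1e-9)
    cand <- cand[order(fw$idx0[cand, 2], fw$idx0[cand, 1])][1]
    c(fw$x[cand], fw$y[cand], fw$z[cand])
  }
  width <- max(fw$x[sel]) - min(fw$x[sel]) + if (convention == "edge") sx else 0
  width_measurement(width, z,
                    .endpoint(min(fw$x[sel])), .endpoint(max(fw$x[sel])))
}

#' Inner-skull width at a given axial slice
#'
#' Measures the left-right extent of the intracranial mask at the slice
#' matched to the frontal-horn measurement (same z-coordinate), using the
#' same edge-to-edge convention. `mode = "max_chord"` instead returns the
#' maximal any-direction in-plane chord (plus one x-spacing), available for
#' sensitivity analysis; the default keeps the diameter parallel to the
#' frontal-horn width.
#'
#' @param icv Intracranial-volume [binary_mask] in aligned space.
#' @param z_index 0-based axial slice index.
#' @param mode `"lateral"` (default) or `"max_chord"`.
#' @param convention `"edge"` (default) or `"center"`.
#' @return A `width_measurement`.
#' @export
inner_skull_width_at_slice <- function(icv, z_index,
                                       mode = c("lateral", "max_chord"),
                                       convention = c("edge", "center")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  icv <- as_binary_mask(icv)
  d <- dim(icv$grid)
  if (z_index < 0 || z_index > d[3] - 1 ||
      !any(icv$grid[, , z_index + 1] != 0L))
    stop("ICV does not cover measurement slice z = ", z_index)
  slice <- icv$grid[, , z_index + 1, drop = FALSE]
  # single-slice subvolume whose slice 0 sits at the world z of z_index
  A <- icv$affine
  A[, 4] <- A %*% c(0, 0, z_index, 1)
  sub <- binary_mask(array(slice, c(d[1], d[2], 1L)), A)
  extra <- if (convention == "edge") icv$spacing[1] else 0
  if (mode == "lateral") {
    m <- max_lateral_width(sub, convention)
    return(width_measurement(m$width_mm, z_index, m$endpoint_a, m$endpoint_b))
  }
  fw <- fg_world(sub)
  pts <- cbind(fw$x, fw$y)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  dd <- as.matrix(stats::dist(hp))
  best <- which(dd == max(dd), arr.ind = TRUE)[1, ]
  a <- hull[best[1]]; b <- hull[best[2]]
  if (fw$x[a] > fw$x[b]) { tmp <- a; a <- b; b <- tmp }
  width_measurement(max(dd) + extra, z_index,
                    c(fw$x[a], fw$y[a], fw$z[a]),
                    c(fw$x[b], fw$y[b], fw$z[b]))
}

#' Classify ventriculomegaly from an Evans Index value
#'
#' @param ei Evans Index in (0, 1).
#' @param threshold Decision threshold (default 0.30). Values exactly at the
#'   threshold are classified positive (>= convention).
#' @return Logical.
#' @export
classify_ventriculomegaly <- function(ei, threshold = 0.30) {
  if (!is.finite(ei) || ei <= 0 || ei >= 1)
    stop("Evans Index out of range (0, 1): ", ei)
  ei >= threshold
}

#' Ratio of lateral-ventricle to intracranial volume
#'
#' @param lv,icv [binary_mask] objects on the same grid.
#' @return LV volume / ICV volume (dimensionless).
#' @export
lv_icv_ratio <- function(lv, icv) {
  lv <- as_binary_mask(lv); icv <- as_binary_mask(icv)
  if (!identical(dim(lv$grid), dim(icv$grid))) stop("grid shape mismatch")
  v_icv <- mask_volume_mm3(icv)
  if (v_icv == 0) stop("ICV mask is empty")
  mask_volume_mm3(lv) / v_icv
}

#' Compute the Evans Index from ventricle and skull masks
#'
#' Runs the full measurement pipeline on a lateral-ventricle mask, an
#' intracranial-volume mask and AC/PC/IVF landmarks:
#' AC-PC realignment (rotating masks and landmarks so the AC-PC line runs
#' along the anterior axis), mask postprocessing (largest component plus
#' void filling for the ICV; small-cluster removal for the LV), frontal-horn
#' extraction anterior to the IVF, maximal frontal-horn width, inner-skull
#' width at the matched axial slice, and their ratio.
#'
#' @param lv Lateral-ventricle mask ([binary_mask] or [label_volume]).
#' @param icv Intracranial-volume mask on the identical grid.
#' @param landmarks A [landmark_set].
#' @param threshold Ventriculomegaly threshold on the EI (default 0.30).
#' @param connectivity Foreground connectivity for component analysis
#'   (default 26).
#' @param width_convention `"edge"` (default) or `"center"`.
#' @param diameter_mode `"lateral"` (default) or `"max_chord"`.
#' @param align If `TRUE` (default) apply the AC-PC realignment; `FALSE`
#'   measures in the acquisition frame ("blind" mode, used by the
#'   rotational-robustness protocol).
#' @param min_lv_cluster_frac Minimum LV component size fraction
#'   (default 0.01).
#' @return An object of class `ei_result`: `evans_index`,
#'   `frontal_horn_width_mm`, `inner_skull_diameter_mm`, `z_index`,
#'   `lv_endpoints`, `icv_endpoints`, `ventriculomegaly`, `rotation_applied_deg`
#'   and `config_echo`.
#' @export
compute_evans_index <- function(lv, icv, landmarks,
                                threshold = 0.30,
                                connectivity = 26,
                                width_convention = c("edge", "center"),
                                diameter_mode = c("lateral", "max_chord"),
                                align = TRUE,
                                min_lv_cluster_frac = 0.01) {
  width_convention <- match.arg(width_convention)
  diameter_mode <- match.arg(diameter_mode)
  lv <- as_binary_mask(lv); icv <- as_binary_mask(icv)
  stopifnot(inherits(landmarks, "landmark_set"))
  if (!identical(dim(lv$grid), dim(icv$grid)))
    stop("LV and ICV must be on identical grids")
  if (max(abs(lv$affine - icv$affine)) > 1e-9)
    stop("LV and ICV affines differ")

  rotation_applied <- 0
  if (align) {
    t <- acpc_rotation(landmarks)
    rotation_applied <- rotation_angle_deg(t$rotation)
    lv <- apply_rigid(lv, t)
    icv <- apply_rigid(icv, t)
    landmarks <- rotate_landmarks(landmarks, t)
  }

  icv <- fill_holes(largest_component(icv, connectivity))
  lv <- drop_small_components(lv, min_lv_cluster_frac, connectivity)

  horns <- frontal_horn_mask(lv, landmarks$ivf)
  wm <- max_lateral_width(horns, width_convention)
  dm <- inner_skull_width_at_slice(icv, wm$z_index, diameter_mode,
                                   width_convention)
  ei <- wm$width_mm / dm$width_mm
  if (!is.finite(ei) || ei <= 0 || ei >= 1)
    stop("implausible geometry: Evans Index ", signif(ei, 4), " outside (0, 1)")
  if (wm$width_mm > dm$width_mm)
    stop("implausible geometry: frontal-horn width exceeds inner-skull diameter")

  structure(list(
    evans_index = ei,
    frontal_horn_width_mm = wm$width_mm,
    inner_skull_diameter_mm = dm$width_mm,
    z_index = wm$z_index,
    lv_endpoints = list(wm$endpoint_a, wm$endpoint_b),
    icv_endpoints = list(dm$endpoint_a, dm$endpoint_b),
    ventriculomegaly = classify_ventriculomegaly(ei, threshold),
    rotation_applied_deg = rotation_applied,
    config_echo = list(threshold = threshold, connectivity = connectivity,
                       width_convention = width_convention,
                       diameter_mode = diameter_mode, align = align,
                       min_lv_cluster_frac = min_lv_cluster_frac)
  ), class = "ei_result")
}

#' @export
print.ei_result <- function(x, ...) {
  cat("<ei_result>\n",
      "  Evans Index:          ", sprintf("%.4f", x$evans_index), "\n",
      "  frontal-horn width:   ", sprintf("%.2f mm", x$frontal_horn_width_mm), "\n",
      "  inner-skull diameter: ", sprintf("%.2f mm", x$inner_skull_diameter_mm), "\n",
      "  measurement slice z:  ", x$z_index, "\n",
      "  ventriculomegaly (>= ", x$config_echo$threshold, "): ",
      x$ventriculomegaly, "\n", sep = "")
  invisible(x)
}
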