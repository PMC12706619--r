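#' Binary mask container
#'
#' A [label_volume] whose grid values are restricted to 0/1.
#'
#' @param grid 3D array of 0/1 values (logical accepted).
#' @param affine 4x4 voxel-to-world affine.
#' @return An object of classes `binary_mask` and `label_volume`.
#' @export
binary_mask <- function(grid, affine) {
  if (is.logical(grid)) {
    g <- array(as.integer(grid), dim(grid))
  } else {
    g <- grid
  }
  vol <- label_volume(g, affine)
  if (any(vol$grid > 1L)) stop("binary mask values must be 0 or 1")
  class(vol) <- c("binary_mask", "label_volume")
  vol
}

#' Coerce a label volume to a binary mask
#'
#' Any nonzero label becomes foreground.
#'
#' @param vol A [label_volume].
#' @return A [binary_mask].
#' @export
as_binary_mask <- function(vol) {
  if (inherits(vol, "binary_mask")) return(vol)
  stopifnot(inherits(vol, "label_volume"))
  binary_mask(vol$grid != 0L, vol$affine)
}


# internal: wrap a trusted integer grid with the geometry of `template`,
# skipping re-validation (used on outputs constructed by the ops below)
new_mask <- function(grid, template) {
  structure(list(grid = grid, affine = template$affine,
                 spacing = template$spacing),
            class = c("binary_mask", "label_volume"))
}

# internal: labelled components of an integer/logical grid
cc_label <- function(grid, connectivity) {
  lab <- .cc_label_cpp(as.integer(grid), dim(grid), as.integer(connectivity))
  array(lab, dim(grid))
}

# internal: 1-based foreground bounding box (list of per-axis index ranges),
# or NULL for an empty grid; single cheap pass per axis
fg_bbox <- function(g) {
  px <- rowSums(g)                 # collapse over j, k
  if (all(px == 0)) return(NULL)
  py <- colSums(rowSums(g, dims = 2))  # collapse over k then i
  pz <- colSums(g, dims = 2)       # collapse over i, j
  list(x = range(which(px > 0)), y = range(which(py > 0)),
       z = range(which(pz > 0)))
}

# run f on the foreground-cropped subgrid and paste the result back into a
# zero grid of the original shape; component structure is unaffected since
# everything outside the foreground bounding box is background
with_fg_crop <- function(g, f) {
  bb <- fg_bbox(g)
  ix <- bb$x[1]:bb$x[2]; iy <- bb$y[1]:bb$y[2]; iz <- bb$z[1]:bb$z[2]
  sub <- f(g[ix, iy, iz, drop = FALSE])
  out <- array(0L, dim(g))
  out[ix, iy, iz] <- sub
  out
}

#' Keep only the largest connected component
#'
#' Removes small spurious clusters disconnected from the primary structure,
#' the standard cleanup applied to intracranial-volume masks. Ties on
#' component size are broken by keeping the component containing the
#' lexicographically smallest voxel index (i, then j, then k; 0-based).
#'
#' @param mask A [binary_mask], nonempty.
#' @param connectivity Foreground connectivity: 6, 18 or 26 (default 26).
#' @return A [binary_mask] containing one connected component.
#' @export
largest_component <- function(mask, connectivity = 26) {
  mask <- as_binary_mask(mask)
  if (!any(mask$grid != 0L)) stop("empty mask")
  out <- with_fg_crop(mask$grid, function(sub) {
    lab <- cc_label(sub, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      # lexicographic tie-break on 0-based (i, j, k): i-major ordering
      d <- dim(sub)
      fg <- which(array(lab %in% best & lab > 0L, d), arr.ind = TRUE)
      key <- (as.numeric(fg[, 1] - 1) * d[2] + (fg[, 2] - 1)) * d[3] + (fg[, 3] - 1)
      labs <- lab[fg]
      best <- labs[which.min(key)]
    }
    array(as.integer(lab == best), dim(sub))
  })
  new_mask(out, mask)
}

#' Remove foreground components below a size fraction
#'
#' Lateral-ventricle masks may legitimately contain two disconnected
#' components (one per hemisphere), so a single-largest-component rule would
#' delete a ventricle. Instead, components smaller than `min_frac` of the
#' total foreground are discarded.
#'
#' @param mask A [binary_mask], nonempty.
#' @param min_frac Minimum component size as a fraction of total foreground
#'   (default 0.01).
#' @param connectivity Foreground connectivity (default 26).
#' @return A [binary_mask].
#' @export
drop_small_components <- function(mask, min_frac = 0.01, connectivity = 26) {
  mask <- as_binary_mask(mask)
  total <- sum(mask$grid != 0L)
  if (total == 0L) stop("empty mask")
  out <- with_fg_crop(mask$grid, function(sub) {
    lab <- cc_label(sub, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_frac * total)
    array(as.integer(lab %in% keep & lab > 0L), dim(sub))
  })
  new_mask(out, mask)
}

#' Fill internal voids in a binary mask
#'
#' Background components (6-connectivity) that cannot be reached from the
#' grid border are enclosed voids and are set to foreground; border-reachable
#' background is left unchanged. Together with 26-connected foreground this
#' is the standard dual-connectivity choice that avoids topological
#' paradoxes.
#'
#' @param mask A [binary_mask], nonempty.
#' @return A [binary_mask] with internal voids filled.
#' @export
fill_holes <- function(mask) {
  mask <- as_binary_mask(mask)
  if (!any(mask$grid != 0L)) stop("empty mask")
  if (!any(mask$grid == 0L)) return(mask)
  # enclosed voids lie inside the foreground bounding box; background
  # touching the (cropped) border is connected to the grid border
  out <- with_fg_crop(mask$grid, function(sub) {
    bg <- sub == 0L
    if (!any(bg)) return(sub)
    lab <- cc_label(bg, 6)
    d <- dim(lab)
    border_labels <- unique(c(lab[1, , ], lab[d[1], , ],
                              lab[, 1, ], lab[, d[2], ],
                              lab[, , 1], lab[, , d[3]]))
    border_labels <- border_labels[border_labels > 0L]
    hole <- bg & !array(lab %in% border_labels, d)
    array(as.integer(sub != 0L | hole), d)
  })
  new_mask(out, mask)
}

#' Extract the frontal-horn compartment of a ventricle mask
#'
#' In AC-PC-aligned space the frontal horns are the ventricular voxels
#' anterior to the interventricular foramen (IVF): those whose voxel-center
#' world y-coordinate is strictly greater than the IVF's y.
#'
#' @param lv Lateral-ventricle [binary_mask] in aligned (post-AC-PC) space.
#' @param ivf World-mm IVF coordinate (length 3) or a [landmark_set].
#' @return A [binary_mask] of the frontal horns.
#' @export
frontal_horn_mask <- function(lv, ivf) {
  lv <- as_binary_mask(lv)
  if (inherits(ivf, "landmark_set")) ivf <- ivf$ivf
  ivf <- as.numeric(ivf)
  if (length(ivf) != 3L || !all(is.finite(ivf))) stop("IVF must be a finite 3-vector")
  A <- lv$affine
  if (max(abs(A[2, c(1, 3)])) > 1e-9)
    stop("frontal_horn_mask requires a canonical RAS volume")
  d <- dim(lv$grid)
  yj <- A[2, 2] * (seq_len(d[2]) - 1) + A[2, 4]   # world y per voxel column
  anterior <- yj > ivf[2]
  out <- lv$grid
  out[, !anterior, ] <- 0L
  if (!any(out != 0L)) stop("no frontal-horn voxels anterior to IVF")
  new_mask(out, lv)
}

#' Foreground volume in cubic millimetres
#'
#' @param mask A [binary_mask] (or any [label_volume]; nonzero = foreground).
#' @return Foreground voxel count times the voxel volume from the affine.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "label_volume"))
  sum(mask$grid != 0L) * abs(det(mask$affine[1:3, 1:3]))
}

#' Dice similarity coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty. The masks must share grid shape and affine.
#'
#' @param a,b [binary_mask] objects on identical grids.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  if (!identical(dim(a$grid), dim(b$grid)))
    stop("grid shape mismatch")
  if (max(abs(a$affine - b$affine)) > 1e-9)
    stop("affine mismatch")
  na <- sum(a$grid != 0L); nb <- sum(b$grid != 0L)
  if (na + nb == 0L) return(1.0)
  inter <- sum(a$grid != 0L & b$grid != 0L)
  2 * inter / (na + nb)
}
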