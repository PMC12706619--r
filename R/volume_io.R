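#' Label volume container
#'
#' A `label_volume` couples a 3D integer voxel grid with a 4x4 voxel-to-world
#' affine. World space is RAS millimetres (x = right, y = anterior,
#' z = superior) and the affine maps 0-based voxel *centers* to world
#' coordinates, following the NIfTI convention.
#'
#' @param grid 3D array of non-negative integers (0 = background).
#' @param affine 4x4 numeric matrix mapping homogeneous 0-based voxel indices
#'   to world millimetres; the upper-left 3x3 block must be invertible.
#' @return An object of class `label_volume` with elements `grid`, `affine`
#'   and `spacing` (mm per voxel along each voxel axis, derived from the
#'   affine column norms).
#' @export
label_volume <- function(grid, affine) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("expected 3D volume, got ", length(dim(grid)), " dimensions")
  if (any(dim(grid) < 1L)) stop("all grid dimensions must be >= 1")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine upper-left 3x3 block is singular")
  if (is.double(grid)) {
    if (any(abs(grid - round(grid)) > 1e-6))
      stop("grid contains non-integer voxel values beyond tolerance 1e-6")
    grid <- array(as.integer(round(grid)), dim(grid))
  } else if (!is.integer(grid)) {
    storage.mode(grid) <- "integer"
  }
  if (any(grid < 0L)) stop("grid values must be non-negative")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(grid = grid, affine = affine, spacing = spacing),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$grid), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, ", sum(x$grid != 0L), " foreground voxels\n", sep = "")
  invisible(x)
}

#' Landmark set (AC, PC, IVF)
#'
#' Anterior commissure, posterior commissure and interventricular foramen
#' positions in world RAS millimetres. The AC must lie anterior to the PC
#' (positive y difference), which is what makes the AC-PC direction usable
#' as the anterior axis reference.
#'
#' @param ac,pc,ivf Numeric length-3 world-mm coordinates.
#' @return An object of class `landmark_set` with fields `ac`, `pc`, `ivf`
#'   and `space_tag = "world_ras"`.
#' @export
landmark_set <- function(ac, pc, ivf) {
  pts <- list(ac = ac, pc = pc, ivf = ivf)
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 3L || !all(is.finite(p)))
      stop("landmark '", toupper(nm), "' must be a finite length-3 vector")
    pts[[nm]] <- p
  }
  if (sqrt(sum((pts$ac - pts$pc)^2)) < 1e-12)
    stop("AC and PC coincide")
  if (pts$ac[2] - pts$pc[2] <= 0)
    stop("AC must be anterior to PC (ac_y - pc_y > 0); landmarks reversed or implausible")
  structure(c(pts, list(space_tag = "world_ras")), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> (world RAS mm)\n")
  for (nm in c("ac", "pc", "ivf"))
    cat(" ", toupper(nm), ": ", paste(sprintf("%.2f", x[[nm]]), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a NIfTI label volume
#'
#' Reads a 3D NIfTI (.nii or .nii.gz) file into a [label_volume]. Voxel
#' values within 1e-6 of integers are cast to integer with a warning when
#' the stored data were floating point; values further from an integer are
#' an error, since label masks must be integral.
#'
#' @param path Path to a 3D NIfTI file.
#' @return A [label_volume].
#' @export
read_mask_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    dim(img) <- d[1:3]
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("expected 3D volume, got ", length(d), " dimensions")
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  arr <- as.array(img)
  attributes(arr) <- list(dim = d)
  if (is.double(arr)) {
    dev <- max(abs(arr - round(arr)))
    if (dev > 1e-6)
      stop("non-integer voxel values (max deviation ", signif(dev, 3),
           "); expected a label volume")
    if (dev > 0)
      warning("floating-point voxel values within 1e-6 of integers; cast to integer")
  }
  label_volume(arr, affine)
}

#' Write a label volume to NIfTI
#'
#' @param vol A [label_volume].
#' @param path Output path ending in .nii or .nii.gz.
#' @return `path`, invisibly.
#' @export
write_mask_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$grid, datatype = "int16")
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Reorient a label volume to canonical RAS
#'
#' Permutes and flips the voxel axes so that voxel axis 1 increases to the
#' Right, axis 2 to the Anterior and axis 3 to the Superior, leaving the
#' world coordinate of every voxel unchanged. Only near-axis-aligned grids
#' are accepted: if any normalized direction cosine off the dominant axis
#' exceeds 0.2 the affine is considered oblique and an error is raised
#' (upstream rigid registration is expected to have removed obliquity).
#'
#' @param vol A [label_volume].
#' @return A [label_volume] in canonical RAS orientation.
#' @export
reorient_to_ras <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  A <- vol$affine
  R3 <- A[1:3, 1:3]
  cols <- sweep(R3, 2, sqrt(colSums(R3^2)), "/")
  perm <- integer(3)   # perm[j] = world axis dominated by voxel axis j
  sign_ <- integer(3)
  for (j in 1:3) {
    i <- which.max(abs(cols[, j]))
    if (any(abs(cols[-i, j]) > 0.2))
      stop("oblique affine: off-axis direction cosine ",
           signif(max(abs(cols[-i, j])), 3), " > 0.2; axis-aligned grids only")
    perm[j] <- i
    sign_[j] <- sign(cols[i, j])
  }
  if (length(unique(perm)) != 3L)
    stop("degenerate affine: voxel axes do not map to distinct world axes")
  if (all(perm == 1:3) && all(sign_ > 0)) return(vol)

  d <- dim(vol$grid)
  # new voxel axis i takes data from old axis j where perm[j] == i
  ord <- match(1:3, perm)          # ord[i] = old axis feeding new axis i
  grid <- aperm(vol$grid, ord)
  # old_index_j = new_index_i (if sign>0) or dim_j - 1 - new_index_i
  P <- diag(4)
  P[1:3, 1:3] <- 0
  for (i in 1:3) {
    j <- ord[i]
    if (sign_[j] > 0) {
      P[j, i] <- 1
    } else {
      idx <- rep(list(quote(expr = )), 3)
      idx[[i]] <- rev(seq_len(dim(grid)[i]))
      grid <- do.call(`[`, c(list(grid), idx, list(drop = FALSE)))
      P[j, i] <- -1
      P[j, 4] <- d[j] - 1
    }
  }
  out <- label_volume(grid, A %*% P)
  # canonical check: each column dominated by its own world axis, positive
  stopifnot(all(diag(out$affine)[1:3] > 0))
  out
}

#' Convert a voxel index to world coordinates
#'
#' @param vol A [label_volume].
#' @param index 0-based integer voxel index (length 3), in bounds.
#' @return World-mm coordinate of the voxel center (length-3 numeric).
#' @export
voxel_to_world <- function(vol, index) {
  index <- as.numeric(index)
  d <- dim(vol$grid)
  for (ax in 1:3)
    if (index[ax] < 0 || index[ax] > d[ax] - 1)
      stop("voxel index out of bounds on axis ", ax, ": ", index[ax],
           " not in [0, ", d[ax] - 1, "]")
  as.numeric(vol$affine %*% c(index, 1))[1:3]
}

#' Convert a world coordinate to the nearest voxel index
#'
#' Rounding is half-up per axis so that endpoint reporting is deterministic.
#'
#' @param vol A [label_volume].
#' @param point World-mm coordinate mapping inside the grid.
#' @return 0-based integer voxel index (length 3).
#' @export
world_to_voxel <- function(vol, point) {
  cont <- as.numeric(solve(vol$affine, c(as.numeric(point), 1)))[1:3]
  idx <- floor(cont + 0.5)  # round half up
  d <- dim(vol$grid)
  for (ax in 1:3)
    if (idx[ax] < 0 || idx[ax] > d[ax] - 1)
      stop("world point maps outside the grid on axis ", ax,
           ": index ", idx[ax], " not in [0, ", d[ax] - 1, "]")
  as.integer(idx)
}

#' Read an AC/PC/IVF landmark file
#'
#' Landmark files are JSON objects of the form
#' `{"AC":[x,y,z],"PC":[x,y,z],"IVF":[x,y,z],"space":"world_ras"}` with
#' coordinates in millimetres; keys are case-sensitive.
#'
#' @param path Path to a landmark JSON file.
#' @return A [landmark_set].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path)
  for (k in c("AC", "PC", "IVF"))
    if (is.null(obj[[k]])) stop("landmark file missing key '", k, "'")
  if (is.null(obj$space) || !identical(obj$space, "world_ras"))
    stop("landmark file must declare \"space\": \"world_ras\"")
  landmark_set(obj$AC, obj$PC, obj$IVF)
}

#' Write an AC/PC/IVF landmark file
#'
#' @param landmarks A [landmark_set].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  jsonlite::write_json(
    list(AC = landmarks$ac, PC = landmarks$pc, IVF = landmarks$ivf,
         space = "world_ras"),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
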