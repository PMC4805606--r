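#' Voxel grid geometry
#'
#' A voxel grid couples an array shape with a 4x4 affine mapping 0-based voxel
#' indices to world coordinates in millimetres (RAS by NIfTI convention). All
#' geometric computation in the package happens in world mm; voxel indices are
#' only ever an addressing scheme.
#'
#' @param shape integer vector of length 3, voxels per axis (all > 0).
#' @param affine numeric 4x4 matrix, voxel index (0-based) to world mm. The
#'   last row must be (0, 0, 0, 1) and the upper-left 3x3 block invertible.
#' @return An object of class `voxel_grid` with elements `shape`, `affine`
#'   and `voxel_dims_mm` (column norms of the linear block).
#' @examples
#' g <- voxel_grid(c(96, 96, 72), diag(c(0.86, 0.86, 3, 1)))
#' voxel_volume_mm3(g)  # 0.86 * 0.86 * 3
#' @export
voxel_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape <= 0L))
    stop("`shape` must be 3 positive integers")
  affine <- as.matrix(affine)
  if (!is.numeric(affine) || !identical(dim(affine), c(4L, 4L)) ||
      any(!is.finite(affine)))
    stop("`affine` must be a finite numeric 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-10)
    stop("`affine` last row must be (0, 0, 0, 1)")
  d <- det(affine[1:3, 1:3])
  if (abs(d) < 1e-12)
    stop("`affine` linear block is singular")
  structure(
    list(shape = shape, affine = affine,
         voxel_dims_mm = sqrt(colSums(affine[1:3, 1:3]^2))),
    class = "voxel_grid")
}

#' Physical volume of one voxel
#'
#' Uses the determinant of the affine's linear block, so sheared grids are
#' measured correctly (the product of the voxel dimensions would overcount).
#'
#' @param grid a [voxel_grid()].
#' @return Voxel volume in cubic millimetres.
#' @export
voxel_volume_mm3 <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  abs(det(grid$affine[1:3, 1:3]))
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, dims %s mm, voxel %.4f mm^3\n",
              paste(x$shape, collapse = "x"),
              paste(sprintf("%.3g", x$voxel_dims_mm), collapse = "x"),
              voxel_volume_mm3(x)))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-5) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

stop_grid_mismatch <- function(a, b, what = "masks") {
  stop(sprintf(
    "%s are on different grids: %s voxels / affine rms %.3g vs %s voxels",
    what, paste(a$shape, collapse = "x"),
    sqrt(mean((a$affine - b$affine)^2)), paste(b$shape, collapse = "x")),
    call. = FALSE)
}

# world coordinates of the grid's centre (continuous index (shape-1)/2)
grid_center_world <- function(grid) {
  cv <- (grid$shape - 1) / 2
  as.numeric(grid$affine %*% c(cv, 1))[1:3]
}

# world coordinates of every voxel axis-marginal: returns list of index->mm
# helper used by the phantom generator
grid_world_coords <- function(grid) {
  n <- grid$shape
  idx <- cbind(
    rep.int(0:(n[1] - 1L), n[2] * n[3]),
    rep.int(rep(0:(n[2] - 1L), each = n[1]), n[3]),
    rep(0:(n[3] - 1L), each = n[1] * n[2]))
  w <- idx %*% t(grid$affine[1:3, 1:3])
  w <- sweep(w, 2, grid$affine[1:3, 4], "+")
  list(x = array(w[, 1], n), y = array(w[, 2], n), z = array(w[, 3], n))
}
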