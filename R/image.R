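#' Volumetric image on a voxel grid
#'
#' @param grid a [voxel_grid()].
#' @param values numeric 3D array matching `grid$shape`; all values finite.
#' @return An object of class `volumetric_image`.
#' @export
volumetric_image <- function(grid, values) {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- check_values(values, grid)
  if (any(!is.finite(values)))
    stop("image values must all be finite")
  structure(list(grid = grid, values = values), class = "volumetric_image")
}

#' Binary label mask on a voxel grid
#'
#' Masks are stored as strict 0/1 integer-valued arrays. Segmentation files
#' in the wild encode foreground as 255 or tissue label codes; pass
#' `binarize = TRUE` to map any nonzero value to 1 (a warning reports how
#' many voxels were recoded).
#'
#' @param grid a [voxel_grid()].
#' @param values 3D array matching `grid$shape`, values in `{0, 1}` (or any
#'   values with `binarize = TRUE`).
#' @param label tissue class, one of `"WMH"`, `"vCSF"`, `"sCSF"`, `"GM"`,
#'   `"WM"`, `"BH"`, `"brain"`.
#' @param binarize logical; recode any nonzero value to 1.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(grid, values, label = "WMH", binarize = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"))
  label <- match.arg(label, c("WMH", "vCSF", "sCSF", "GM", "WM", "BH", "brain"))
  values <- check_values(values, grid)
  if (is.logical(values)) values[] <- as.numeric(values)
  nonbinary <- values != 0 & values != 1
  if (any(nonbinary)) {
    if (!binarize)
      stop(sprintf("mask has %d non-binary voxels (e.g. value %g); %s",
                   sum(nonbinary), values[which(nonbinary)[1]],
                   "pass binarize = TRUE to recode nonzero as 1"))
    warning(sprintf("binarized %d non-{0,1} voxels to 1", sum(nonbinary)))
    values[] <- as.numeric(values != 0)
  }
  if (any(!is.finite(values))) stop("mask values must be finite")
  structure(list(grid = grid, values = values, label = label),
            class = "label_mask")
}

check_values <- function(values, grid) {
  if (is.null(dim(values)) && length(values) == prod(grid$shape))
    dim(values) <- grid$shape
  if (length(dim(values)) != 3L)
    stop(sprintf("values must be a 3D array, got %d dimensions",
                 length(dim(values))))
  if (!identical(as.integer(dim(values)), grid$shape))
    stop(sprintf("values dim %s does not match grid shape %s",
                 paste(dim(values), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  storage.mode(values) <- "double"
  values
}

#' Physical mask volume in cubic centimetres
#'
#' Counts foreground voxels and multiplies by the voxel volume from the
#' affine determinant. All volumes in this package are reported in cc.
#'
#' @param mask a [label_mask()].
#' @return Non-negative volume in cc.
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  sum(mask$values) * voxel_volume_mm3(mask$grid) / 1000
}

#' Mask set algebra
#'
#' Voxelwise logical operations on masks sharing one grid. `mask_and` is the
#' intersection, `mask_subtract` is A and-not B, `mask_union` the union.
#' The output keeps `a`'s tissue label unless overridden.
#'
#' @param a,b [label_mask()] objects on identical grids.
#' @param label optional tissue label for the result.
#' @return A [label_mask()] on the shared grid.
#' @export
mask_and <- function(a, b, label = a$label) {
  check_same_grid(a, b)
  label_mask(a$grid, a$values * b$values, label = label)
}

#' @rdname mask_and
#' @export
mask_subtract <- function(a, b, label = a$label) {
  check_same_grid(a, b)
  label_mask(a$grid, a$values * (1 - b$values), label = label)
}

#' @rdname mask_and
#' @export
mask_union <- function(a, b, label = a$label) {
  check_same_grid(a, b)
  label_mask(a$grid, pmax(a$values, b$values), label = label)
}

check_same_grid <- function(a, b) {
  stopifnot(inherits(a, "label_mask") || inherits(a, "volumetric_image"),
            inherits(b, "label_mask") || inherits(b, "volumetric_image"))
  if (!grids_equal(a$grid, b$grid)) stop_grid_mismatch(a$grid, b$grid)
  invisible(TRUE)
}

#' @export
print.volumetric_image <- function(x, ...) {
  cat(sprintf("<volumetric_image> %s voxels, range [%.3g, %.3g]\n",
              paste(x$grid$shape, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask:%s> %s voxels, %d set (%.4f cc)\n", x$label,
              paste(x$grid$shape, collapse = "x"), sum(x$values),
              volume_cc(x)))
  invisible(x)
}
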