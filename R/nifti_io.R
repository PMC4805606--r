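#' Read a NIfTI-1 volume
#'
#' Reads a 3D volume with its voxel-to-world affine (s-form preferred,
#' q-form fallback, per the format standard). With `as = "mask"` the data
#' are validated as binary, optionally binarizing nonzero values first.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as `"image"` for a [volumetric_image()], `"mask"` for a
#'   [label_mask()].
#' @param label tissue label when `as = "mask"`.
#' @param binarize recode nonzero voxels to 1 when `as = "mask"`.
#' @return A [volumetric_image()] or [label_mask()].
#' @export
read_volume <- function(path, as = c("image", "mask"), label = "WMH",
                        binarize = FALSE) {
  as <- match.arg(as)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "cannot read '%s' as NIfTI: %s", path,
                    conditionMessage(e)), call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("'%s' is %dD; only 3D volumes are supported", path,
                 length(d)))
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  grid <- voxel_grid(d, affine)
  values <- array(as.numeric(img), d)
  if (as == "image") volumetric_image(grid, values)
  else label_mask(grid, values, label = label, binarize = binarize)
}

#' Write a volume or mask as NIfTI-1
#'
#' Masks are written as 8-bit unsigned integers, images as 32-bit floats.
#' Both the s-form and q-form carry the grid affine, so the round trip
#' preserves geometry to single precision.
#'
#' @param obj a [volumetric_image()] or [label_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(obj, path) {
  stopifnot(inherits(obj, "volumetric_image") || inherits(obj, "label_mask"))
  datatype <- if (inherits(obj, "label_mask")) "uint8" else "float"
  img <- RNifti::asNifti(obj$values)
  RNifti::pixdim(img) <- obj$grid$voxel_dims_mm
  RNifti::sform(img) <- structure(obj$grid$affine, code = 2L)
  RNifti::qform(img) <- structure(obj$grid$affine, code = 2L)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
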