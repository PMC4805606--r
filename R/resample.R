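#' Resample a volume or mask through a rigid transform
#'
#' `transform` maps source world coordinates to target world coordinates;
#' the output is sampled on `target_grid`. Images default to trilinear
#' interpolation; label masks are always resampled nearest-neighbour so the
#' output stays strictly binary and downstream set-algebra conservation laws
#' hold. Voxels that fall outside the source field of view are 0.
#'
#' @param source a [volumetric_image()] or [label_mask()].
#' @param transform a [rigid_transform()], source world to target world.
#' @param target_grid a [voxel_grid()].
#' @param mode `"trilinear"` or `"nearest"`. Masks ignore a request for
#'   trilinear and use nearest.
#' @return An object of the same class as `source` on `target_grid`.
#' @export
resample <- function(source, transform, target_grid,
                     mode = c("auto", "trilinear", "nearest")) {
  stopifnot(inherits(source, "volumetric_image") ||
              inherits(source, "label_mask"),
            inherits(transform, "rigid_transform"),
            inherits(target_grid, "voxel_grid"))
  mode <- match.arg(mode)
  is_mask <- inherits(source, "label_mask")
  nearest <- is_mask || mode == "nearest"
  M <- index_map(source$grid, transform, target_grid)
  vals <- resample_affine_cpp(as.numeric(source$values),
                              source$grid$shape, M, target_grid$shape,
                              nearest, 0)
  dim(vals) <- target_grid$shape
  if (is_mask) label_mask(target_grid, vals, label = source$label)
  else volumetric_image(target_grid, vals)
}

# 4x4 matrix sending 0-based target voxel indices to continuous 0-based
# source indices: A_src^-1 T^-1 A_tgt
index_map <- function(source_grid, transform, target_grid) {
  solve(source_grid$affine) %*% solve(transform$matrix) %*% target_grid$affine
}

#' Block-average downsampling
#'
#' Averages `factor^3` blocks, adjusting the affine so block centres keep
#' their world position. Used to build the registration pyramid; block
#' averaging doubles as the anti-aliasing filter.
#'
#' @param img a [volumetric_image()].
#' @param factor positive integer decimation factor.
#' @return A [volumetric_image()] on the coarse grid.
#' @export
downsample_image <- function(img, factor) {
  stopifnot(inherits(img, "volumetric_image"))
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(img)
  n <- img$grid$shape
  nc <- pmax(1L, n %/% factor)
  x <- img$values[seq_len(nc[1] * factor), seq_len(nc[2] * factor),
                  seq_len(nc[3] * factor), drop = FALSE]
  for (ax in 1:3) {
    d <- dim(x)
    dim(x) <- c(factor, d[1] %/% factor, d[2], d[3])
    x <- colMeans(x)          # collapse leading factor
    x <- aperm(x, c(2, 3, 1)) # rotate axes so next axis leads
  }
  A <- img$grid$affine
  Ac <- diag(4)
  Ac[1:3, 1:3] <- A[1:3, 1:3] * factor
  Ac[1:3, 4] <- A[1:3, 4] + A[1:3, 1:3] %*% rep((factor - 1) / 2, 3)
  volumetric_image(voxel_grid(nc, Ac), x)
}

#' Intermediate (halfway) sampling grid
#'
#' The intermediate space is sampled on the baseline lattice carried by the
#' forward half-transform: same shape and voxel dimensions as baseline, with
#' the affine composed with the forward half. Because the forward half is
#' half of the full between-scan motion, this grid sits midway between the
#' two native fields of view, and baseline-space voxels map onto it
#' identically (zero interpolation error on the baseline path).
#'
#' @param baseline_grid the baseline [voxel_grid()].
#' @param pair a [halfway_decompose()] result.
#' @return A [voxel_grid()].
#' @export
intermediate_grid <- function(baseline_grid, pair) {
  stopifnot(inherits(baseline_grid, "voxel_grid"),
            inherits(pair, "halfway_pair"))
  voxel_grid(baseline_grid$shape,
             pair$forward_half$matrix %*% baseline_grid$affine)
}

#' Intermediate-space mean image
#'
#' Carries the baseline image through the forward half-transform and the
#' follow-up image through the backward half-transform onto one grid and
#' averages them voxelwise, yielding a template that represents both
#' timepoints with the interpolation burden shared equally.
#'
#' @param baseline,followup [volumetric_image()] objects in native space.
#' @param pair a [halfway_decompose()] result for baseline to follow-up.
#' @param target_grid optional [voxel_grid()]; defaults to
#'   [intermediate_grid()] of the baseline grid.
#' @return A [volumetric_image()] on `target_grid`.
#' @export
make_intermediate <- function(baseline, followup, pair, target_grid = NULL) {
  stopifnot(inherits(baseline, "volumetric_image"),
            inherits(followup, "volumetric_image"),
            inherits(pair, "halfway_pair"))
  if (is.null(target_grid)) target_grid <- intermediate_grid(baseline$grid, pair)
  b <- resample(baseline, pair$forward_half, target_grid, mode = "trilinear")
  f <- resample(followup, pair$backward_half, target_grid, mode = "trilinear")
  if (!grids_equal(b$grid, f$grid))
    stop("internal error: half-transformed images landed on different grids")
  volumetric_image(target_grid, (b$values + f$values) / 2)
}
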