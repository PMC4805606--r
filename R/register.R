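#' Registration options
#'
#' Settings for intensity-based rigid registration. The default similarity
#' metric is the correlation ratio, the standard choice for within-modality
#' (T1-to-T1) alignment; normalised mutual information is available for
#' robustness to intensity non-correspondence. Optimisation is multi-
#' resolution (coarse-to-fine pyramid by block averaging) and derivative
#' free (Nelder-Mead), so no image gradients are needed and the procedure
#' is deterministic given the seed.
#'
#' @param metric `"correlation-ratio"` or `"normalized-mutual-information"`.
#' @param pyramid_levels number of resolution levels (level L decimates by
#'   `2^(L-1)`).
#' @param max_iter maximum optimiser iterations per level.
#' @param tol relative convergence tolerance of the optimiser (> 0).
#' @param nbins intensity histogram bins for the metric.
#' @param seed integer seed recorded with the run (the default procedure is
#'   fully deterministic; the seed guards any stochastic extension).
#' @return An object of class `registration_options`.
#' @export
registration_options <- function(metric = c("correlation-ratio",
                                            "normalized-mutual-information"),
                                 pyramid_levels = 3L,
                                 max_iter = 3000L,
                                 tol = 1e-10,
                                 nbins = 64L,
                                 seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(pyramid_levels >= 1L, max_iter >= 1L, tol > 0, nbins >= 8L)
  structure(list(metric = metric, pyramid_levels = as.integer(pyramid_levels),
                 max_iter = as.integer(max_iter), tol = tol,
                 nbins = as.integer(nbins), seed = as.integer(seed)),
            class = "registration_options")
}

#' Rigid 6-DOF image registration
#'
#' Estimates the rigid world-space transform mapping `moving` onto `fixed`
#' by maximising the similarity metric over rotations and translations.
#' Rotation is parameterised about the fixed image's field-of-view centre;
#' the translation is initialised from the intensity centroids. The final
#' metric value and per-level trace are attached as the `"qc"` attribute.
#'
#' @param moving,fixed [volumetric_image()] objects with overlapping fields
#'   of view.
#' @param opts a [registration_options()].
#' @return A [rigid_transform()] mapping moving world to fixed world, with
#'   attribute `qc` (list: `metric`, `value`, `converged`).
#' @export
register_rigid <- function(moving, fixed, opts = registration_options()) {
  stopifnot(inherits(moving, "volumetric_image"),
            inherits(fixed, "volumetric_image"))
  set.seed(opts$seed)
  cc <- grid_center_world(fixed$grid)
  t0 <- intensity_centroid(fixed) - intensity_centroid(moving)
  factors <- 2^((opts$pyramid_levels:1) - 1)
  par <- c(0, 0, 0, t0)
  value <- NA_real_
  converged <- TRUE
  for (f in factors) {
    fx <- downsample_image(fixed, f)
    mv <- downsample_image(moving, f)
    fb <- fixed_bins(fx$values, opts$nbins)
    neg <- function(p) {
      tr <- centered_rigid(p, cc)
      M <- index_map(mv$grid, tr, fx$grid)
      v <- if (opts$metric == "correlation-ratio")
        corr_ratio_cpp(fb$bin, fx$grid$shape, as.numeric(mv$values),
                       mv$grid$shape, M, opts$nbins)
      else
        nmi_cpp(fb$bin, fx$grid$shape, as.numeric(mv$values),
                mv$grid$shape, M, opts$nbins, fb$mv_range[1], fb$mv_range[2])
      if (is.na(v)) 1e6 else -v
    }
    fb$mv_range <- range(mv$values)
    # restart with a fresh simplex if Nelder-Mead degenerates before reltol
    for (attempt in 1:3) {
      fit <- optim(par, neg, method = "Nelder-Mead",
                   control = list(maxit = opts$max_iter, reltol = opts$tol))
      par <- fit$par
      value <- -fit$value
      if (fit$convergence == 0) break
    }
    if (f == 1 && fit$convergence != 0) converged <- FALSE
  }
  result <- rigid_transform(centered_rigid(par, cc)$matrix)
  attr(result, "qc") <- list(metric = opts$metric, value = value,
                             converged = converged)
  if (!converged) {
    cond <- structure(
      class = c("wmhdyn_registration_error", "error", "condition"),
      list(message = sprintf(
        "registration did not converge within %d iterations (final %s = %.6f)",
        opts$max_iter, opts$metric, value),
        call = sys.call(-1), transform = result, value = value))
    stop(cond)
  }
  result
}

# rotation about a fixed world centre cc plus translation
centered_rigid <- function(p, cc) {
  m <- diag(4)
  R <- rot3(p[1:3])
  m[1:3, 1:3] <- R
  m[1:3, 4] <- p[4:6] + cc - R %*% cc
  rigid_transform(m)
}

intensity_centroid <- function(img) {
  v <- img$values - min(img$values)
  s <- sum(v)
  if (s <= 0) return(grid_center_world(img$grid))
  m1 <- apply(v, 1, sum); m2 <- apply(v, 2, sum); m3 <- apply(v, 3, sum)
  ci <- c(sum(m1 * (seq_along(m1) - 1)) / s,
          sum(m2 * (seq_along(m2) - 1)) / s,
          sum(m3 * (seq_along(m3) - 1)) / s)
  as.numeric(img$grid$affine %*% c(ci, 1))[1:3]
}

# linear intensity bins over the robust range; -1 flags ignored voxels
fixed_bins <- function(values, nbins) {
  rng <- range(values)
  if (rng[2] <= rng[1])
    return(list(bin = array(-1L, dim(values)), mv_range = c(0, 1)))
  b <- as.integer((values - rng[1]) / (rng[2] - rng[1]) * nbins)
  b[b >= nbins] <- nbins - 1L
  list(bin = b, mv_range = rng)
}
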