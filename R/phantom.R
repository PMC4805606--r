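#' Synthetic longitudinal brain phantom specification
#'
#' Describes a paired baseline/follow-up scan scene: an ellipsoidal brain
#' with a GM shell and WM core, two ellipsoidal lateral ventricles that may
#' enlarge between timepoints, and a set of spherical white-matter lesions
#' that shrink, grow, or persist. Follow-up acquisition is displaced by a
#' small rigid inter-scan motion. Every quantity the pipeline estimates is
#' known exactly on the generating lattice, so phantoms are the package's
#' validation substrate.
#'
#' Lesions are given as a list of `list(center = c(x, y, z) mm,
#' baseline_cc =, followup_cc =, class = "stable"|"shrinking"|"growing")`;
#' the class is descriptive, volumes drive the realisation. World
#' coordinates are mm with the origin at the lattice centre.
#'
#' @param shape lattice size in voxels.
#' @param voxel_dims_mm voxel dimensions in mm.
#' @param brain_semiaxes_mm brain ellipsoid semi-axes.
#' @param wm_fraction WM core ellipsoid as a fraction of the brain
#'   semi-axes (the shell outside it is GM).
#' @param ventricle_centers_mm 2x3 matrix of ventricle centres.
#' @param ventricle_semiaxes_mm semi-axes shared by both ventricles.
#' @param expansion_factor follow-up ventricle semi-axis scale (>= 1);
#'   1.10 enlarges ventricular volume by ~33%, matching the few-cc vCSF
#'   increase seen over ~2-year serial scans.
#' @param lesions list of lesion descriptors (see Details).
#' @param rotations_deg,translations_mm true inter-scan rigid motion
#'   (follow-up head position relative to baseline), within +/-10 deg/mm.
#' @param intensities named list of T1 tissue means (`csf`, `gm`, `wm`,
#'   `wmh`); WMH are rendered hyperintense to WM.
#' @param noise_sd additive Gaussian noise SD in intensity units.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 72L),
                         voxel_dims_mm = c(1, 1, 1),
                         brain_semiaxes_mm = c(40, 44, 30),
                         wm_fraction = 0.85,
                         ventricle_centers_mm = rbind(c(-11, 8, 2),
                                                      c(11, 8, 2)),
                         ventricle_semiaxes_mm = c(8, 18, 10),
                         expansion_factor = 1.10,
                         lesions = default_lesions(),
                         rotations_deg = c(1.5, -1.0, 2.0),
                         translations_mm = c(2.0, -1.5, 1.0),
                         intensities = list(csf = 40, gm = 100, wm = 140,
                                            wmh = 180),
                         noise_sd = 2.8,
                         seed = 42L) {
  spec <- structure(list(
    shape = as.integer(shape), voxel_dims_mm = as.numeric(voxel_dims_mm),
    brain_semiaxes_mm = brain_semiaxes_mm, wm_fraction = wm_fraction,
    ventricle_centers_mm = ventricle_centers_mm,
    ventricle_semiaxes_mm = ventricle_semiaxes_mm,
    expansion_factor = expansion_factor, lesions = lesions,
    rotations_deg = as.numeric(rotations_deg),
    translations_mm = as.numeric(translations_mm),
    intensities = intensities, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @export
default_lesions <- function() {
  list(
    list(center = c(16, 28, 2), baseline_cc = 4.0, followup_cc = 4.0,
         class = "stable"),       # periventricular; partly engulfed
    list(center = c(-24, -6, 8), baseline_cc = 3.0, followup_cc = 3.0,
         class = "stable"),
    list(center = c(22, -16, -6), baseline_cc = 2.5, followup_cc = 1.0,
         class = "shrinking"),
    list(center = c(-18, 14, -9), baseline_cc = 1.0, followup_cc = 2.8,
         class = "growing"))
}

#' Study-like acquisition preset
#'
#' Same scene as [phantom_spec()] on an anisotropic lattice echoing a 1.5T
#' axial 3D SPGR T1 acquisition (0.86 x 0.86 mm in-plane, 1.4 mm slices).
#'
#' @param ... overrides passed to [phantom_spec()].
#' @export
phantom_spec_study <- function(...) {
  phantom_spec(shape = c(112L, 112L, 52L),
               voxel_dims_mm = c(0.86, 0.86, 1.4), ...)
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$shape) == 3, all(spec$shape > 0),
            length(spec$voxel_dims_mm) == 3, all(spec$voxel_dims_mm > 0),
            spec$expansion_factor >= 1, spec$noise_sd >= 0,
            spec$wm_fraction > 0, spec$wm_fraction < 1)
  if (any(abs(spec$rotations_deg) > 10) || any(abs(spec$translations_mm) > 10))
    stop("inter-scan motion exceeds the +/-10 deg / +/-10 mm sanity bound")
  for (i in seq_along(spec$lesions)) {
    L <- spec$lesions[[i]]
    if (L$baseline_cc < 0 || L$followup_cc < 0)
      stop(sprintf("lesion %d has a negative target volume", i))
    u <- sum((L$center / spec$brain_semiaxes_mm)^2)
    if (u >= 1)
      stop(sprintf("lesion %d centre lies outside the brain", i))
    for (v in 1:nrow(spec$ventricle_centers_mm)) {
      d <- sum(((L$center - spec$ventricle_centers_mm[v, ]) /
                  spec$ventricle_semiaxes_mm)^2)
      if (d <= 1)
        stop(sprintf("lesion %d centre lies inside a baseline ventricle", i))
    }
  }
  invisible(spec)
}

ellipsoid_mask <- function(coords, center, semiaxes) {
  ((coords$x - center[1]) / semiaxes[1])^2 +
    ((coords$y - center[2]) / semiaxes[2])^2 +
    ((coords$z - center[3]) / semiaxes[3])^2 <= 1
}

#' Generate a longitudinal phantom with exact ground truth
#'
#' Renders baseline and follow-up scenes on one generating lattice, then
#' moves the follow-up scene into its own native space through the true
#' rigid transform (trilinear for the T1, nearest-neighbour for masks).
#' Lesions are realised as the target number of lattice voxels nearest
#' each lesion centre within eligible white matter, so realised volumes hit
#' their targets to within one voxel. Follow-up ventricles are enlarged by
#' scaling their semi-axes; baseline WMH voxels newly inside the enlarged
#' ventricles are relabelled vCSF at follow-up and tallied as
#' `engulfed_cc` — the ventricular-expansion confound by construction.
#' Truth volumes are always measured on the undistorted generating lattice.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth`: native-space images/masks
#'   (`baseline_t1`, `followup_t1`, `baseline_wmh`, `followup_wmh`,
#'   `baseline_vcsf`, `followup_vcsf`), `true_transform` (baseline world to
#'   follow-up world), and exact `truth` volumes (`shrink_cc`, `grow_cc`,
#'   `stable_cc`, `engulfed_cc`, timepoint WMH and vCSF volumes, all cc).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  n <- spec$shape
  A <- diag(c(spec$voxel_dims_mm, 1))
  A[1:3, 4] <- -(n - 1) / 2 * spec$voxel_dims_mm
  grid <- voxel_grid(n, A)
  vx <- voxel_volume_mm3(grid)
  co <- grid_world_coords(grid)

  brain <- ellipsoid_mask(co, c(0, 0, 0), spec$brain_semiaxes_mm)
  wm_core <- ellipsoid_mask(co, c(0, 0, 0),
                            spec$brain_semiaxes_mm * spec$wm_fraction)
  vb <- array(FALSE, n); vf <- array(FALSE, n)
  for (v in 1:nrow(spec$ventricle_centers_mm)) {
    ctr <- spec$ventricle_centers_mm[v, ]
    vb <- vb | ellipsoid_mask(co, ctr, spec$ventricle_semiaxes_mm)
    vf <- vf | ellipsoid_mask(co, ctr,
                              spec$ventricle_semiaxes_mm * spec$expansion_factor)
  }
  vf <- vf & brain

  eligible <- wm_core & !vb
  B <- array(FALSE, n); F0 <- array(FALSE, n)
  for (i in seq_along(spec$lesions)) {
    L <- spec$lesions[[i]]
    kb <- round(L$baseline_cc * 1000 / vx)
    kf <- round(L$followup_cc * 1000 / vx)
    kmax <- max(kb, kf)
    if (kmax == 0) next
    d2 <- (co$x - L$center[1])^2 + (co$y - L$center[2])^2 +
      (co$z - L$center[3])^2
    cand <- which(eligible)
    if (length(cand) < kmax)
      stop(sprintf("lesion %d (%s) overflows the eligible white matter",
                   i, L$class))
    ord <- cand[order(d2[cand])[seq_len(kmax)]]
    # realised as nested distance-ranked voxel sets -> exact target volumes
    if (kb > 0) B[ord[seq_len(kb)]] <- TRUE
    if (kf > 0) F0[ord[seq_len(kf)]] <- TRUE
  }
  Fm <- F0 & !vf   # expanded ventricles relabel engulfed WMH as vCSF

  growth <- vf & !vb
  engulfed <- B & growth
  stable <- B & Fm
  shrink <- B & !Fm & !growth
  grow <- Fm & !B

  truth <- list(
    shrink_cc = sum(shrink) * vx / 1000,
    grow_cc = sum(grow) * vx / 1000,
    stable_cc = sum(stable) * vx / 1000,
    engulfed_cc = sum(engulfed) * vx / 1000,
    baseline_wmh_cc = sum(B) * vx / 1000,
    followup_wmh_cc = sum(Fm) * vx / 1000,
    baseline_vcsf_cc = sum(vb) * vx / 1000,
    followup_vcsf_cc = sum(vf) * vx / 1000)

  render_t1 <- function(vent, wmh) {
    t1 <- array(0, n)
    t1[brain] <- spec$intensities$gm
    t1[wm_core] <- spec$intensities$wm
    t1[vent] <- spec$intensities$csf
    t1[wmh] <- spec$intensities$wmh
    t1
  }
  base_t1 <- render_t1(vb, B)
  fup_t1 <- render_t1(vf, Fm)

  tt <- rigid_from_params(spec$rotations_deg, spec$translations_mm)
  is_identity <- max(abs(tt$matrix - diag(4))) < 1e-12
  as_mask <- function(vals, label)
    label_mask(grid, array(as.numeric(vals), n), label = label)
  if (is_identity) {
    fup_t1_nat <- volumetric_image(grid, fup_t1)
    f_wmh_nat <- as_mask(Fm, "WMH")
    f_vcsf_nat <- as_mask(vf, "vCSF")
  } else {
    fup_t1_nat <- resample(volumetric_image(grid, fup_t1), tt, grid,
                           mode = "trilinear")
    f_wmh_nat <- resample(as_mask(Fm, "WMH"), tt, grid)
    f_vcsf_nat <- resample(as_mask(vf, "vCSF"), tt, grid)
  }
  noise <- function(x) x + rnorm(length(x), 0, spec$noise_sd)
  base_img <- volumetric_image(grid, array(noise(base_t1), n))
  fup_img <- volumetric_image(grid, array(noise(fup_t1_nat$values), n))

  structure(list(
    spec = spec,
    baseline_t1 = base_img, followup_t1 = fup_img,
    baseline_wmh = as_mask(B, "WMH"), followup_wmh = f_wmh_nat,
    baseline_vcsf = as_mask(vb, "vCSF"), followup_vcsf = f_vcsf_nat,
    true_transform = tt, truth = truth), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  tr <- x$truth
  cat(sprintf(
    "<phantom_truth> %s voxels; WMH %.3f -> %.3f cc (%s)\n",
    paste(x$spec$shape, collapse = "x"), tr$baseline_wmh_cc,
    tr$followup_wmh_cc,
    sprintf("shrink %.3f, grow %.3f, stable %.3f, engulfed %.3f",
            tr$shrink_cc, tr$grow_cc, tr$stable_cc, tr$engulfed_cc)))
  invisible(x)
}

#' Default oracle-validation phantom suite
#'
#' Four phantoms exercising the pipeline's set algebra end to end: mixed
#' lesion dynamics, ventricular engulfment, large confluent lesions, and an
#' incident-lesion case with empty baseline WMH. Inter-scan motion in this
#' suite is purely translational: on the integer lattice a rounded
#' translation is an exact bijection, so nearest-neighbour mask transport
#' conserves voxel counts exactly and any volume discrepancy in an
#' injected-transform (oracle) run isolates a logic defect rather than
#' interpolation noise. Rotational motion, where nearest-neighbour
#' transport fluctuates at mask boundaries, is assessed separately with
#' relative tolerances (see [truth_table()]).
#'
#' @return Named list of [phantom_spec()]s.
#' @export
default_phantom_suite <- function() {
  list(
    mixed = phantom_spec(rotations_deg = c(0, 0, 0),
                         translations_mm = c(2.3, -1.4, 0.8), seed = 101L),
    engulfment = phantom_spec(rotations_deg = c(0, 0, 0),
                              translations_mm = c(1.7, 2.2, -1.1),
                              expansion_factor = 1.15, seed = 102L),
    high_burden = phantom_spec(
      rotations_deg = c(0, 0, 0), translations_mm = c(-2.6, 1.3, 1.9),
      lesions = list(
        list(center = c(18, 26, 2), baseline_cc = 7.0, followup_cc = 7.5,
             class = "stable"),
        list(center = c(-20, -10, 6), baseline_cc = 5.0, followup_cc = 3.0,
             class = "shrinking"),
        list(center = c(24, -14, -4), baseline_cc = 2.0, followup_cc = 4.5,
             class = "growing")),
      seed = 103L),
    incident = phantom_spec(
      rotations_deg = c(0, 0, 0), translations_mm = c(0.9, -0.6, 1.2),
      lesions = list(
        list(center = c(20, -18, -5), baseline_cc = 0, followup_cc = 1.5,
             class = "growing")),
      expansion_factor = 1.0, seed = 104L))
}

#' Recovery report: pipeline estimates against phantom ground truth
#'
#' @param truths list of [generate_phantom()] results.
#' @param results list of [run_subject()] results with matching subject
#'   ids (in `names(truths)` order).
#' @return List of class `truth_table`: `per_subject` (absolute and
#'   relative volume errors per dynamic category plus transform errors) and
#'   `aggregate` (median relative error per category; fraction of runs with
#'   rotation error <= 0.5 deg and translation error <= 0.5 mm).
#' @export
truth_table <- function(truths, results) {
  stopifnot(length(truths) == length(results), length(truths) >= 1)
  ids_t <- names(truths)
  if (is.null(ids_t)) ids_t <- as.character(seq_along(truths))
  ids_r <- vapply(results, function(r) r$subject_id, "")
  if (!identical(unname(ids_t), unname(ids_r)))
    stop(sprintf("subject id mismatch between truths (%s) and results (%s)",
                 paste(ids_t, collapse = ","), paste(ids_r, collapse = ",")))
  cats <- c(shrink = "shrink_cc", grow = "grow_cc", stable = "stable_cc",
            engulfed = "engulfed_cc")
  res_field <- c(shrink = "shrink_cc", grow = "grow_cc",
                 stable = "stable_cc", engulfed = "vcsf_removed_cc")
  per <- do.call(rbind, lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]$truth
    rs <- results[[i]]
    delta <- rigid_compose(rigid_invert(truths[[i]]$true_transform),
                           rs$transform)
    aa <- axis_angle(delta$matrix[1:3, 1:3])
    row <- data.frame(subject_id = ids_t[i], stringsAsFactors = FALSE)
    for (k in names(cats)) {
      err <- rs[[res_field[k]]] - tr[[cats[k]]]
      row[[paste0(k, "_true_cc")]] <- tr[[cats[k]]]
      row[[paste0(k, "_est_cc")]] <- rs[[res_field[k]]]
      row[[paste0(k, "_abs_err_cc")]] <- abs(err)
      row[[paste0(k, "_rel_err")]] <-
        if (tr[[cats[k]]] > 0) abs(err) / tr[[cats[k]]] else NA_real_
    }
    row$rot_err_deg <- aa$angle * 180 / pi
    row$trans_err_mm <- sqrt(sum(delta$matrix[1:3, 4]^2))
    row
  }))
  med <- vapply(names(cats), function(k)
    stats::median(per[[paste0(k, "_rel_err")]], na.rm = TRUE), 0)
  agg <- data.frame(
    category = names(cats), median_rel_err = med,
    max_abs_err_cc = vapply(names(cats), function(k)
      max(per[[paste0(k, "_abs_err_cc")]]), 0), row.names = NULL)
  structure(list(
    per_subject = per, aggregate = agg,
    frac_rot_within_half_deg = mean(per$rot_err_deg <= 0.5),
    frac_trans_within_half_mm = mean(per$trans_err_mm <= 0.5)),
    class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("<truth_table> aggregate recovery:\n")
  print(x$aggregate, row.names = FALSE)
  cat(sprintf("registration within 0.5 deg: %.0f%%, within 0.5 mm: %.0f%%\n",
              100 * x$frac_rot_within_half_deg,
              100 * x$frac_trans_within_half_mm))
  invisible(x)
}

#' Write phantom volumes, masks, transform and truth to disk
#'
#' @param truth a [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_phantom <- function(truth, dir) {
  stopifnot(inherits(truth, "phantom_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    baseline_t1 = "baseline_t1.nii.gz", followup_t1 = "followup_t1.nii.gz",
    baseline_wmh = "baseline_wmh.nii.gz",
    followup_wmh = "followup_wmh.nii.gz",
    baseline_vcsf = "baseline_vcsf.nii.gz",
    followup_vcsf = "followup_vcsf.nii.gz")
  out <- character(0)
  for (k in names(paths)) {
    p <- file.path(dir, paths[k])
    write_volume(truth[[k]], p)
    out[k] <- p
  }
  out["true_transform"] <- file.path(dir, "true_transform.txt")
  write_transform(truth$true_transform, out["true_transform"])
  out["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(truth$truth, out["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(out)
}
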