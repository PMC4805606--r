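#' Shrink / grow / stable overlap masks
#'
#' Decomposes baseline and follow-up WMH masks, both already resampled to
#' the shared intermediate grid, into three disjoint spatial compartments:
#' shrinking WMH (present at baseline but not follow-up), growing WMH
#' (present at follow-up but not baseline), and stable WMH (present at
#' both). By construction stable + shrink partitions the baseline mask and
#' stable + grow partitions the follow-up mask, exactly.
#'
#' @param baseline_wmh_int,followup_wmh_int [label_mask()] objects on one
#'   intermediate grid.
#' @return An object of class `overlap_masks`: list with `shrink`, `grow`,
#'   `stable`, `baseline_int`, `followup_int`.
#' @export
compute_overlap <- function(baseline_wmh_int, followup_wmh_int) {
  check_same_grid(baseline_wmh_int, followup_wmh_int)
  structure(list(
    shrink = mask_subtract(baseline_wmh_int, followup_wmh_int),
    grow = mask_subtract(followup_wmh_int, baseline_wmh_int),
    stable = mask_and(baseline_wmh_int, followup_wmh_int),
    baseline_int = baseline_wmh_int,
    followup_int = followup_wmh_int), class = "overlap_masks")
}

#' Ventricular-expansion correction
#'
#' Ventricular enlargement between scans can engulf periventricular WMH:
#' voxels that were lesion at baseline are ventricular CSF at follow-up and
#' would otherwise be scored as lesion shrinkage. The correction region is
#' the set of voxels whose ventricular membership changed between the two
#' timepoints (the symmetric difference of the intermediate-space vCSF
#' masks); when ventricles only enlarge this is exactly the vCSF growth
#' region, follow-up minus baseline. Every WMH voxel falling inside it is
#' masked out of all compartments (shrink, grow, stable, and both timepoint
#' masks). Because the region is direction-free, swapping baseline and
#' follow-up leaves the correction invariant, so shrink and grow exchange
#' exactly under scan-order reversal. The removed voxels are returned so
#' the correction can be audited and reported separately.
#'
#' @param masks an [compute_overlap()] result.
#' @param vcsf_baseline_int,vcsf_followup_int ventricular-CSF
#'   [label_mask()]s on the same intermediate grid.
#' @return List with `masks` (corrected `overlap_masks`) and `removed`
#'   (a [label_mask()] of the masked-out WMH voxels).
#' @export
ventricular_correction <- function(masks, vcsf_baseline_int,
                                   vcsf_followup_int) {
  stopifnot(inherits(masks, "overlap_masks"))
  check_same_grid(masks$baseline_int, vcsf_baseline_int)
  check_same_grid(masks$baseline_int, vcsf_followup_int)
  growth <- mask_union(
    mask_subtract(vcsf_followup_int, vcsf_baseline_int),
    mask_subtract(vcsf_baseline_int, vcsf_followup_int), label = "vCSF")
  wmh_any <- mask_union(masks$baseline_int, masks$followup_int)
  removed <- mask_and(wmh_any, growth, label = "WMH")
  corrected <- structure(
    lapply(masks, function(m) mask_subtract(m, removed)),
    class = "overlap_masks")
  list(masks = corrected, removed = removed)
}

#' Net WMH volume change
#'
#' The conventional serial-MRI measure: follow-up volume minus baseline
#' volume, in cc. Positive values are net growth.
#'
#' @param baseline_wmh_cc,followup_wmh_cc non-negative volumes in cc.
#' @return Signed difference in cc.
#' @examples
#' net_change(14.0, 15.7)  # +1.7
#' net_change(9.2, 4.5)    # -4.7
#' @export
net_change <- function(baseline_wmh_cc, followup_wmh_cc) {
  stopifnot(baseline_wmh_cc >= 0, followup_wmh_cc >= 0)
  followup_wmh_cc - baseline_wmh_cc
}

#' Full per-subject dynamic progression pipeline
#'
#' Runs the complete procedure for one scan pair: rigid registration of
#' baseline T1 to follow-up T1, halfway decomposition of the transform,
#' nearest-neighbour transfer of the WMH and vCSF masks into the
#' intermediate space, overlap decomposition, ventricular-expansion
#' correction, and volumetrics. All stages are deterministic given
#' `opts$seed`.
#'
#' @param baseline_t1,followup_t1 native-space [volumetric_image()]s.
#' @param baseline_wmh,followup_wmh native-space WMH [label_mask()]s.
#' @param baseline_vcsf,followup_vcsf native-space vCSF [label_mask()]s.
#' @param opts a [registration_options()].
#' @param subject_id identifier carried into the result.
#' @param isi_years interscan interval in years (metadata).
#' @param inject_transform optional [rigid_transform()]; when supplied,
#'   registration is bypassed and this baseline-to-follow-up transform is
#'   used (oracle runs against phantoms with known motion).
#' @param keep_masks keep the intermediate-space masks and template in the
#'   result (`$masks`).
#' @return An object of class `progression_result`: subject id, ISI,
#'   `shrink_cc`, `grow_cc`, `stable_cc` (after ventricular correction),
#'   `vcsf_removed_cc`, native `baseline_wmh_cc` / `followup_wmh_cc`,
#'   `net_change_cc` (native follow-up minus baseline),
#'   `net_change_intermediate_cc` (grow minus shrink), intermediate-space
#'   timepoint volumes, and `qc` (registration metric and parameters).
#' @export
run_subject <- function(baseline_t1, followup_t1, baseline_wmh, followup_wmh,
                        baseline_vcsf, followup_vcsf,
                        opts = registration_options(), subject_id = "subject",
                        isi_years = NA_real_, inject_transform = NULL,
                        keep_masks = FALSE) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) stop(sprintf(
      "[%s] stage '%s' failed: %s", subject_id, what,
      conditionMessage(e)), call. = FALSE))
  }
  stage("validate inputs", {
    check_same_grid(baseline_t1, baseline_wmh)
    check_same_grid(baseline_t1, baseline_vcsf)
    check_same_grid(followup_t1, followup_wmh)
    check_same_grid(followup_t1, followup_vcsf)
  })
  full <- if (is.null(inject_transform)) {
    stage("registration", register_rigid(baseline_t1, followup_t1, opts))
  } else {
    stopifnot(inherits(inject_transform, "rigid_transform"))
    inject_transform
  }
  pair <- stage("halfway decomposition", halfway_decompose(full))
  tgrid <- intermediate_grid(baseline_t1$grid, pair)
  b_wmh <- stage("mask resampling",
                 resample(baseline_wmh, pair$forward_half, tgrid))
  f_wmh <- resample(followup_wmh, pair$backward_half, tgrid)
  b_vcsf <- resample(baseline_vcsf, pair$forward_half, tgrid)
  f_vcsf <- resample(followup_vcsf, pair$backward_half, tgrid)
  ov <- stage("overlap", compute_overlap(b_wmh, f_wmh))
  vc <- stage("ventricular correction",
              ventricular_correction(ov, b_vcsf, f_vcsf))
  m <- vc$masks
  qc <- attr(full, "qc")
  if (is.null(qc))
    qc <- list(metric = "injected", value = NA_real_, converged = NA)
  qc$parameters <- rigid_params(full)
  res <- structure(list(
    subject_id = subject_id,
    isi_years = isi_years,
    shrink_cc = volume_cc(m$shrink),
    grow_cc = volume_cc(m$grow),
    stable_cc = volume_cc(m$stable),
    vcsf_removed_cc = volume_cc(vc$removed),
    baseline_wmh_cc = volume_cc(baseline_wmh),
    followup_wmh_cc = volume_cc(followup_wmh),
    baseline_int_cc = volume_cc(m$baseline_int),
    followup_int_cc = volume_cc(m$followup_int),
    net_change_cc = net_change(volume_cc(baseline_wmh),
                               volume_cc(followup_wmh)),
    net_change_intermediate_cc = NA_real_,
    transform = full,
    qc = qc), class = "progression_result")
  res$net_change_intermediate_cc <- res$grow_cc - res$shrink_cc
  if (keep_masks) {
    res$masks <- c(m, list(removed = vc$removed, vcsf_baseline_int = b_vcsf,
                           vcsf_followup_int = f_vcsf))
    res$intermediate_t1 <- stage("intermediate template",
                                 make_intermediate(baseline_t1, followup_t1,
                                                   pair, tgrid))
  }
  res
}

#' @export
print.progression_result <- function(x, ...) {
  cat(sprintf("<progression_result> %s\n", x$subject_id))
  cat(sprintf("  WMH baseline %.4f cc, follow-up %.4f cc, net %+.4f cc\n",
              x$baseline_wmh_cc, x$followup_wmh_cc, x$net_change_cc))
  cat(sprintf("  shrink %.4f, grow %.4f, stable %.4f, engulfed %.4f cc\n",
              x$shrink_cc, x$grow_cc, x$stable_cc, x$vcsf_removed_cc))
  invisible(x)
}

#' @export
as.data.frame.progression_result <- function(x, ...) {
  p <- x$qc$parameters
  data.frame(subject_id = x$subject_id, isi_years = x$isi_years,
             baseline_wmh_cc = x$baseline_wmh_cc,
             followup_wmh_cc = x$followup_wmh_cc,
             net_change_cc = x$net_change_cc,
             shrink_cc = x$shrink_cc, grow_cc = x$grow_cc,
             stable_cc = x$stable_cc, vcsf_removed_cc = x$vcsf_removed_cc,
             net_change_intermediate_cc = x$net_change_intermediate_cc,
             baseline_int_cc = x$baseline_int_cc,
             followup_int_cc = x$followup_int_cc,
             reg_metric = x$qc$metric, reg_value = x$qc$value,
             rx_deg = p[1], ry_deg = p[2], rz_deg = p[3],
             tx_mm = p[4], ty_mm = p[5], tz_mm = p[6],
             row.names = NULL, stringsAsFactors = FALSE)
}
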