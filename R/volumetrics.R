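#' Total intracranial capacity
#'
#' TIC is the volume of the union of all supplied supratentorial tissue and
#' CSF masks (GM, WM, WMH, sCSF, vCSF, lacunar black holes). Overlapping
#' voxels are counted once.
#'
#' @param masks list of [label_mask()] objects sharing one grid.
#' @return Volume in cc.
#' @export
compute_tic <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1,
            all(vapply(masks, inherits, TRUE, "label_mask")))
  u <- masks[[1]]
  for (m in masks[-1]) u <- mask_union(u, m, label = "brain")
  volume_cc(u)
}

#' Brain parenchymal fraction
#'
#' BPF = (GM + WM + WMH) / TIC: the fraction of the intracranial capacity
#' occupied by parenchyma, a global atrophy index (reported as a percentage
#' in cohort tables).
#'
#' @param gm_cc,wm_cc,wmh_cc,tic_cc volumes in cc; `tic_cc` must be > 0.
#' @return Fraction in `[0, 1]`.
#' @examples
#' compute_bpf(500, 400, 5, 1216.6)  # 0.7439
#' @export
compute_bpf <- function(gm_cc, wm_cc, wmh_cc, tic_cc) {
  stopifnot(gm_cc >= 0, wm_cc >= 0, wmh_cc >= 0)
  if (tic_cc <= 0) stop("`tic_cc` must be positive")
  bpf <- (gm_cc + wm_cc + wmh_cc) / tic_cc
  if (bpf > 1 + 1e-9)
    stop("GM + WM + WMH exceeds TIC; check mask provenance")
  min(bpf, 1)
}

#' Tissue-volume profile for one timepoint
#'
#' @param gm,wm,wmh,scsf,vcsf [label_mask()]s on one grid; `bh` (black
#'   holes) optional.
#' @return List of class `tissue_volumes` with per-class volumes (cc),
#'   `tic_cc`, and `bpf`.
#' @export
tissue_volumes <- function(gm, wm, wmh, scsf, vcsf, bh = NULL) {
  masks <- list(gm = gm, wm = wm, wmh = wmh, scsf = scsf, vcsf = vcsf)
  if (!is.null(bh)) masks$bh <- bh
  for (m in masks[-1]) check_same_grid(masks[[1]], m)
  v <- lapply(masks, volume_cc)
  tic <- compute_tic(masks)
  structure(c(setNames(v, paste0(names(v), "_cc")),
              list(tic_cc = tic,
                   bpf = compute_bpf(v$gm, v$wm, v$wmh, tic))),
            class = "tissue_volumes")
}

#' Small vessel disease burden classification
#'
#' Dichotomises baseline WMH load at the conventional 3.5 cc cut
#' (low burden strictly below the threshold, high otherwise). The cut is a
#' cohort-derived median split, so it is exposed as a parameter.
#'
#' @param baseline_wmh_cc baseline WMH volume in cc (>= 0).
#' @param threshold_cc split point in cc.
#' @return `"low"` or `"high"` (vectorised over input).
#' @examples
#' classify_svd(c(1.3, 14.0))  # "low" "high"
#' @export
classify_svd <- function(baseline_wmh_cc, threshold_cc = 3.5) {
  if (any(is.na(baseline_wmh_cc)) || any(baseline_wmh_cc < 0))
    stop("baseline WMH volume must be non-negative")
  ifelse(baseline_wmh_cc < threshold_cc, "low", "high")
}

#' Cohort summary table
#'
#' Per-group mean (SD) of every numeric column, mirroring the layout of
#' demographic/volumetric cohort tables, plus log-transformed change
#' variables: WMH change volumes are heavily right-skewed, so shrink, grow
#' and stable volumes get `log(v + offset)` columns (the offset admits
#' zero-change subjects) and the signed net change gets a log-modulus
#' transform `sign(v) * log(1 + |v|/offset)`, which is continuous and odd.
#' SDs use the population (n) convention so that duplicating the cohort
#' leaves the table unchanged; the convention and offset are recorded in
#' the result.
#'
#' @param rows data.frame with one row per subject, a `group` column, and
#'   numeric measurement columns (e.g. the output of
#'   [as.data.frame.progression_result()] plus metadata).
#' @param group_col name of the grouping column.
#' @param log_offset_cc additive offset in cc for the log transforms.
#' @return List of class `cohort_summary`: `table` (long data.frame with
#'   group, variable, n, mean, sd), `log_offset_cc`, `sd_convention`.
#' @export
summarize_cohort <- function(rows, group_col = "group",
                             log_offset_cc = 0.01) {
  if (!is.data.frame(rows) || nrow(rows) == 0)
    stop("cohort is empty")
  if (!group_col %in% names(rows))
    stop(sprintf("no '%s' column in cohort", group_col))
  stopifnot(log_offset_cc > 0)
  rows <- as.data.frame(rows)
  for (v in intersect(c("shrink_cc", "grow_cc", "stable_cc"), names(rows)))
    rows[[paste0("log_", v)]] <- ifelse(rows[[v]] >= 0,
                                        log(rows[[v]] + log_offset_cc),
                                        NA_real_)
  for (v in intersect(c("net_change_cc", "net_change_intermediate_cc"),
                      names(rows)))
    rows[[paste0("log_", v)]] <-
      sign(rows[[v]]) * log(1 + abs(rows[[v]]) / log_offset_cc)
  num <- names(rows)[vapply(rows, is.numeric, TRUE)]
  pop_sd <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    sqrt(mean((x - mean(x))^2))
  }
  groups <- unique(as.character(rows[[group_col]]))
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- rows[rows[[group_col]] == g, , drop = FALSE]
    do.call(rbind, lapply(num, function(v) data.frame(
      group = g, variable = v, n = sum(!is.na(sub[[v]])),
      mean = mean(sub[[v]], na.rm = TRUE), sd = pop_sd(sub[[v]]),
      stringsAsFactors = FALSE)))
  }))
  structure(list(table = out, log_offset_cc = log_offset_cc,
                 sd_convention = "population"),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 1, ...) {
  tab <- x$table
  cat(sprintf("<cohort_summary> mean (SD), population-SD convention, %s\n",
              sprintf("log offset %.3g cc", x$log_offset_cc)))
  wide <- unique(tab$variable)
  groups <- unique(tab$group)
  for (v in wide) {
    cells <- vapply(groups, function(g) {
      r <- tab[tab$group == g & tab$variable == v, ]
      sprintf("%.*f (%.*f)", digits, r$mean, digits, r$sd)
    }, "")
    cat(sprintf("  %-28s %s\n", v,
                paste(sprintf("%s: %s", groups, cells), collapse = "  ")))
  }
  invisible(x)
}

#' Write a cohort summary as CSV
#'
#' @param x a [summarize_cohort()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(x, path) {
  stopifnot(inherits(x, "cohort_summary"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}
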