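# Synthetic phantom cohort: a spherical-shell GM density template, an
# 8-lobe octant parcellation, spherical lesion masks with exact
# ground-truth displacement bookkeeping, and seizure labels drawn from a
# stated logistic model on the displaced-GM proportion.

#' Synthetic cohort configuration
#'
#' The phantom places a cortical GM shell (density `gm_peak`) between
#' radii `shell_inner_mm` and `shell_outer_mm` around the grid centre,
#' over a WM core (`wm_density`) and CSF/background exterior
#' (`csf_density`). Lesions are spheres with radii uniform in
#' `lesion_radius_mm`, centred uniformly in the brain (optionally biased
#' toward GM-rich or GM-poor tissue per group). Seizure labels are drawn
#' Bernoulli with `logit p = beta0 + beta1 * proportion_pct`, where
#' `proportion_pct` is the true displaced-GM proportion in percent.
#'
#' Defaults mirror the study conditions: a 181 x 217 x 181 grid at 1 mm
#' isotropic voxels and a 12 / 99 two-group cohort.
#'
#' @param grid_shape integer(3) grid dimensions.
#' @param voxel_size_mm numeric(3) voxel size in mm.
#' @param shell_outer_mm,shell_inner_mm outer/inner radius of the GM shell.
#' @param gm_peak GM shell density (in \[0, 1\]).
#' @param wm_density,csf_density core and exterior densities.
#' @param smooth_sigma_mm Gaussian smoothing sigma in mm (0 = none; the
#'   default, which keeps the shell geometry analytic).
#' @param n_per_group named integer vector of lesion counts per placement
#'   group.
#' @param lesion_radius_mm numeric(2) radius range in mm.
#' @param placement_bias per-group placement: `"none"` (uniform in brain),
#'   `"gm"` (centres where template density > 0.5) or `"wm"` (<= 0.5).
#'   Recycled across groups.
#' @param beta0,beta1 outcome-model intercept and slope (per % displaced
#'   GM).
#' @param seed integer seed (mandatory).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(181L, 217L, 181L),
                         voxel_size_mm = c(1, 1, 1),
                         shell_outer_mm = 75, shell_inner_mm = 62,
                         gm_peak = 0.95, wm_density = 0.25,
                         csf_density = 0.02, smooth_sigma_mm = 0,
                         n_per_group = c(seizure_like = 12L,
                                         nonseizure_like = 99L),
                         lesion_radius_mm = c(3, 12),
                         placement_bias = "none",
                         beta0 = -4, beta1 = 0.06,
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  grid_shape <- as.integer(grid_shape)
  voxel_size_mm <- check_voxel_size(voxel_size_mm)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            shell_inner_mm > 0, shell_outer_mm > shell_inner_mm,
            all(c(gm_peak, wm_density, csf_density) >= 0),
            all(c(gm_peak, wm_density, csf_density) <= 1),
            smooth_sigma_mm >= 0,
            all(n_per_group >= 1), length(lesion_radius_mm) == 2L,
            all(lesion_radius_mm > 0),
            lesion_radius_mm[1] <= lesion_radius_mm[2])
  half_extent <- grid_shape * voxel_size_mm / 2
  if (shell_outer_mm >= min(half_extent))
    stop("shell_outer_mm exceeds the grid: need < ",
         round(min(half_extent), 1), " mm for this grid")
  placement_bias <- match.arg(rep(placement_bias,
                                  length.out = length(n_per_group)),
                              c("none", "gm", "wm"), several.ok = TRUE)
  if (is.null(names(n_per_group)))
    names(n_per_group) <- paste0("group_", seq_along(n_per_group))
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 shell_outer_mm = shell_outer_mm,
                 shell_inner_mm = shell_inner_mm,
                 gm_peak = gm_peak, wm_density = wm_density,
                 csf_density = csf_density,
                 smooth_sigma_mm = smooth_sigma_mm,
                 n_per_group = n_per_group,
                 lesion_radius_mm = lesion_radius_mm,
                 placement_bias = placement_bias,
                 beta0 = beta0, beta1 = beta1, seed = as.integer(seed)),
            class = "synth_config")
}

# squared distance (mm^2) of every voxel to the grid centre, plus the
# per-axis world coordinates; voxel world position = 0-based index * size
grid_geometry <- function(cfg) {
  ax <- lapply(1:3, function(k) {
    (seq_len(cfg$grid_shape[k]) - 1) * cfg$voxel_size_mm[k] -
      (cfg$grid_shape[k] - 1) * cfg$voxel_size_mm[k] / 2
  })
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  list(axes = ax, r2 = r2)
}

gauss_smooth <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    rad <- max(1L, ceiling(3 * s))
    k <- exp(-((-rad):rad)^2 / (2 * s^2))
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, ax)
  }
  arr
}

# 1D convolution along one axis with edge replication
convolve_axis <- function(arr, k, ax) {
  d <- dim(arr)
  rad <- (length(k) - 1L) / 2L
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[ax])
  n <- nrow(m)
  padded <- rbind(m[rep(1L, rad), , drop = FALSE], m,
                  m[rep(n, rad), , drop = FALSE])
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * padded[i:(i + n - 1L), , drop = FALSE]
  a <- array(out, dim = d[perm])
  aperm(a, order(perm))
}

#' Synthetic GM density template
#'
#' Deterministic shell phantom: density is a pure function of distance to
#' the grid centre (WM core, GM shell, CSF exterior), optionally Gaussian
#' smoothed, clamped to \[0, 1\].
#'
#' @param cfg a [synth_config()].
#' @return A [density_volume()].
#' @export
make_template <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  geo <- grid_geometry(cfg)
  r <- sqrt(geo$r2)
  dat <- array(cfg$csf_density, dim = cfg$grid_shape)
  dat[r <= cfg$shell_outer_mm] <- cfg$gm_peak
  dat[r <= cfg$shell_inner_mm] <- cfg$wm_density
  if (cfg$smooth_sigma_mm > 0)
    dat <- pmin(pmax(gauss_smooth(dat, cfg$smooth_sigma_mm /
                                         cfg$voxel_size_mm), 0), 1)
  density_volume(dat, cfg$voxel_size_mm, space_tag = "synthetic-phantom")
}

#' Default raw-region to merged-lobe table
#'
#' The mergers used for the eight-lobe analysis: anterior/posterior
#' cerebellum into cerebellum; frontal lobe and the frontal-temporal
#' space into frontal; medulla, midbrain and pons into brainstem; the
#' remaining lobes map to themselves.
#'
#' @return A [lobe_merge_table()].
#' @export
default_merge_table <- function() {
  lobe_merge_table(c(
    "cerebellum anterior lobe" = "cerebellum",
    "cerebellum posterior lobe" = "cerebellum",
    "frontal lobe" = "frontal",
    "frontal-temporal space" = "frontal",
    "limbic lobe" = "limbic",
    "medulla" = "brainstem",
    "midbrain" = "brainstem",
    "pons" = "brainstem",
    "occipital lobe" = "occipital",
    "parietal lobe" = "parietal",
    "temporal lobe" = "temporal",
    "sublobar" = "sublobar"))
}

# raw region used for each synthetic octant, one per merged lobe
SYNTH_OCTANT_REGIONS <- c("frontal lobe", "temporal lobe",
                          "parietal lobe", "occipital lobe",
                          "limbic lobe", "sublobar",
                          "cerebellum anterior lobe", "pons")

#' Synthetic 8-lobe parcellation
#'
#' Splits the brain sphere into octants around the grid centre and labels
#' them with one raw region per merged lobe: the four upper octants get
#' cortical lobes (frontal, temporal, parietal, occipital), the lower
#' octants limbic, sublobar, cerebellum and brainstem. A geometric test
#' fixture, not an anatomical atlas.
#'
#' @param cfg a [synth_config()].
#' @return A [label_volume()] with codes 1..8.
#' @export
make_parcellation <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  geo <- grid_geometry(cfg)
  brain <- sqrt(geo$r2) <= cfg$shell_outer_mm
  sx <- geo$axes[[1]] >= 0
  sy <- geo$axes[[2]] >= 0
  sz <- geo$axes[[3]] >= 0
  d <- cfg$grid_shape
  oct <- array(0L, dim = d)
  for (k in seq_len(d[3])) {
    base <- outer(sx, sy, function(x, y) x + 2L * y)  # 0..3 quadrant
    oct[, , k] <- base + if (sz[k]) 1L else 5L        # 1..4 top, 5..8 bottom
  }
  lab <- array(0L, dim = d)
  lab[brain] <- oct[brain]
  label_volume(lab, cfg$voxel_size_mm,
               label_names = stats::setNames(SYNTH_OCTANT_REGIONS,
                                             as.character(1:8)))
}

# rasterize one spherical lesion; returns linear voxel indices or NULL
# when the sphere would leave the grid
rasterize_sphere <- function(center_mm, radius_mm, cfg) {
  d <- cfg$grid_shape; vs <- cfg$voxel_size_mm
  lo <- floor((center_mm - radius_mm) / vs)
  hi <- ceiling((center_mm + radius_mm) / vs)
  if (any(lo < 0) || any(hi > d - 1L)) return(NULL)
  ix <- lapply(1:3, function(k) lo[k]:hi[k])
  dist2 <- outer(outer((ix[[1]] * vs[1] - center_mm[1])^2,
                       (ix[[2]] * vs[2] - center_mm[2])^2, `+`),
                 (ix[[3]] * vs[3] - center_mm[3])^2, `+`)
  inside <- which(dist2 <= radius_mm^2, arr.ind = TRUE)
  if (nrow(inside) == 0L) return(NULL)
  i <- ix[[1]][inside[, 1]] + 1L
  j <- ix[[2]][inside[, 2]] + 1L
  k <- ix[[3]][inside[, 3]] + 1L
  i + (j - 1L) * d[1] + (k - 1L) * as.double(d[1]) * d[2]
}

sample_center <- function(cfg, template, bias) {
  ctr <- (cfg$grid_shape - 1L) * cfg$voxel_size_mm / 2
  repeat {
    u <- stats::runif(3, -1, 1)
    if (sum(u^2) > 1) next
    w <- ctr + u * cfg$shell_outer_mm
    if (bias == "none") return(w)
    idx <- pmin(pmax(round(w / cfg$voxel_size_mm) + 1, 1), cfg$grid_shape)
    dens <- template$data[idx[1], idx[2], idx[3]]
    if (bias == "gm" && dens > 0.5) return(w)
    if (bias == "wm" && dens <= 0.5) return(w)
  }
}

#' Synthetic lesions with ground-truth displacement
#'
#' Draws spherical lesion masks and records ground-truth displaced-GM
#' bookkeeping (`nd_ccm`, `n_ccm`, `sum_density`, volume, proportion)
#' directly from the template values at the rasterized voxels. Lesions
#' that would leave the grid are re-placed, with the retry count logged.
#'
#' @param cfg a [synth_config()].
#' @param template the [make_template()] output (rebuilt if missing).
#' @param n number of lesions (default `sum(cfg$n_per_group)` split by
#'   group).
#' @param keep_masks return full-grid [lesion_mask()] objects (memory:
#'   one full grid per lesion; keep `FALSE` for large grids).
#' @return list with `truth` (data.frame: patient_id, group, radius_mm,
#'   center, nd_ccm, n_ccm, sum_density, volume_ml, proportion_pct,
#'   retries), `masks` (named list or NULL), `voxel_indices` (list of
#'   linear index vectors).
#' @export
make_lesions <- function(cfg, template = NULL, n = NULL,
                         keep_masks = TRUE) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(template)) template <- make_template(cfg)
  groups <- if (is.null(n)) {
    rep(names(cfg$n_per_group), cfg$n_per_group)
  } else rep(names(cfg$n_per_group)[1], n)
  bias_of <- stats::setNames(cfg$placement_bias, names(cfg$n_per_group))
  vs <- prod(cfg$voxel_size_mm)
  nles <- length(groups)
  ids <- sprintf("patient_%03d", seq_len(nles))
  rows <- vector("list", nles)
  masks <- if (keep_masks) vector("list", nles) else NULL
  vox <- vector("list", nles)
  for (i in seq_len(nles)) {
    retries <- 0L
    repeat {
      ctr <- sample_center(cfg, template, bias_of[[groups[i]]])
      rad <- stats::runif(1, cfg$lesion_radius_mm[1],
                          cfg$lesion_radius_mm[2])
      lin <- rasterize_sphere(ctr, rad, cfg)
      if (!is.null(lin)) break
      retries <- retries + 1L
      if (retries > 1000L) stop("lesion placement failed repeatedly")
    }
    dens <- template$data[lin]
    nd <- sum(dens > 0.5)
    rows[[i]] <- data.frame(
      patient_id = ids[i], group = groups[i], radius_mm = rad,
      cx_mm = ctr[1], cy_mm = ctr[2], cz_mm = ctr[3],
      nd_ccm = nd, n_ccm = length(lin), sum_density = sum(dens),
      volume_ml = nd * vs / 1000,
      proportion_pct = 100 * sum(dens) / length(lin),
      retries = retries, stringsAsFactors = FALSE)
    vox[[i]] <- lin
    if (keep_masks) {
      m <- array(0L, dim = cfg$grid_shape)
      m[lin] <- 1L
      masks[[i]] <- lesion_mask(m, cfg$voxel_size_mm)
    }
  }
  if (keep_masks) names(masks) <- ids
  names(vox) <- ids
  list(truth = do.call(rbind, rows), masks = masks, voxel_indices = vox)
}

#' Generate a full synthetic cohort
#'
#' Builds the template and parcellation, draws lesions, computes true
#' displaced-GM proportions, and draws seizure labels from
#' `Bernoulli(plogis(beta0 + beta1 * proportion_pct))`. The dominant lobe
#' is recorded from the generator's own voxel bookkeeping. With `dir`
#' set, writes `template.nii.gz`, `atlas_labels.nii.gz`, `merge.json`,
#' per-patient masks under `masks/`, `cohort.csv` and
#' `ground_truth.json`.
#'
#' @param cfg a [synth_config()].
#' @param dir optional output directory.
#' @param keep_masks keep full-grid masks in the return value.
#' @return list with `cohort` (data.frame incl. `label`, `true_prob`,
#'   `dominant_lobe`, `tentorial`), `truth`, `template`, `parcellation`,
#'   `merge`, `masks`, `voxel_indices`, `cfg`.
#' @export
make_cohort <- function(cfg, dir = NULL, keep_masks = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  with_local_seed(cfg$seed, {
    template <- make_template(cfg)
    parc <- make_parcellation(cfg)
    merge <- default_merge_table()
    keep <- keep_masks || !is.null(dir)
    les <- make_lesions(cfg, template, keep_masks = keep)
    truth <- les$truth
    # dominant lobe from generator bookkeeping (independent of
    # lobe_proportions, which the pipeline uses)
    dom <- vapply(les$voxel_indices, function(lin) {
      codes <- parc$data[lin]
      codes <- codes[codes > 0L]
      if (!length(codes)) return(NA_character_)
      lobes <- unname(merge[parc$label_names[as.character(codes)]])
      tab <- table(factor(lobes, levels = MERGED_LOBES))
      MERGED_LOBES[which.max(tab)]
    }, character(1))
    truth$dominant_lobe <- dom
    truth$tentorial <- ifelse(is.na(dom), "unclassified",
                              ifelse(dom %in% INFRATENTORIAL,
                                     "infratentorial", "supratentorial"))
    truth$true_prob <- stats::plogis(cfg$beta0 +
                                       cfg$beta1 * truth$proportion_pct)
    truth$label <- stats::rbinom(nrow(truth), 1L, truth$true_prob)
    if (length(unique(truth$label)) < 2L)
      stop("all drawn labels identical; increase n_per_group or adjust ",
           "beta0/beta1")
    cohort <- truth[, c("patient_id", "group", "volume_ml",
                        "proportion_pct", "true_prob", "label",
                        "dominant_lobe", "tentorial")]
    out <- list(cohort = cohort, truth = truth, template = template,
                parcellation = parc, merge = merge,
                masks = if (keep_masks) les$masks else NULL,
                voxel_indices = les$voxel_indices, cfg = cfg)
    if (!is.null(dir)) write_cohort_bundle(out, les$masks, dir)
    out
  })
}

write_cohort_bundle <- function(out, masks, dir) {
  dir.create(file.path(dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  write_volume(out$template, file.path(dir, "template.nii.gz"))
  write_volume(out$parcellation, file.path(dir, "atlas_labels.nii.gz"))
  jsonlite::write_json(as.list(unclass(out$merge)),
                       file.path(dir, "merge.json"), auto_unbox = TRUE)
  jsonlite::write_json(as.list(out$parcellation$label_names),
                       file.path(dir, "atlas_label_names.json"),
                       auto_unbox = TRUE)
  paths <- character(length(masks))
  for (i in seq_along(masks)) {
    paths[i] <- file.path(dir, "masks",
                          paste0(names(masks)[i], ".nii.gz"))
    write_volume(masks[[i]], paths[i])
  }
  manifest <- out$cohort
  manifest$mask_path <- paths
  utils::write.csv(manifest, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  jsonlite::write_json(out$truth, file.path(dir, "ground_truth.json"),
                       digits = NA)
  invisible(dir)
}
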