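# Population GM density template: voxel-wise mean of control GM maps, and
# the GM / non-GM designation at the 0.5 density cut.

#' Build a GM density template by voxel-wise averaging
#'
#' Averages control-subject GM density maps voxel by voxel, producing the
#' population template against which lesion masks are quantified. No
#' smoothing or modulation is applied before averaging.
#'
#' @param maps list of [density_volume()] objects on one common grid.
#' @return A [density_volume()] whose voxel `v` is the arithmetic mean of
#'   the input maps at `v`.
#' @export
build_template <- function(maps) {
  if (!is.list(maps) || length(maps) == 0L)
    stop("need at least one density map")
  lapply(maps, function(m)
    if (!inherits(m, "density_volume"))
      stop("all inputs must be density volumes"))
  for (m in maps[-1]) assert_same_grid(maps[[1]], m)
  acc <- Reduce(`+`, lapply(maps, `[[`, "data"))
  density_volume(acc / length(maps),
                 maps[[1]]$voxel_size_mm,
                 space_tag = maps[[1]]$space_tag)
}

#' Designate gray matter by density threshold
#'
#' Voxels with template density strictly greater than `threshold` are
#' designated gray matter; everything else (white matter, CSF, background)
#' is non-GM. Density exactly at the threshold is non-GM: the strict
#' inequality mirrors the definition of the displaced-GM voxel count,
#' which counts voxels with density > 0.5.
#'
#' @param template a [density_volume()].
#' @param threshold GM density cut, default 0.5.
#' @return A [lesion_mask()]-shaped binary volume (1 = GM).
#' @export
gm_mask <- function(template, threshold = 0.5) {
  stopifnot(inherits(template, "density_volume"))
  lesion_mask((template$data > threshold) + 0L, template$voxel_size_mm)
}

#' Template build report
#'
#' Builds the template and summarises it: number of contributing subjects
#' and the fraction of voxels designated GM at the density cut.
#'
#' @inheritParams build_template
#' @param threshold GM density cut, default 0.5.
#' @return A list with `n_subjects`, `template` (a [density_volume()]) and
#'   `fraction_gm_voxels`.
#' @export
template_report <- function(maps, threshold = 0.5) {
  tpl <- build_template(maps)
  list(n_subjects = length(maps),
       template = tpl,
       fraction_gm_voxels = mean(tpl$data > threshold))
}
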