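# Volumetric data model: density maps, lesion masks, parcellation labels.
# All grids are axis-aligned with a shared origin; world coordinate =
# 0-based voxel index * voxel size. Rotated or sheared affines are rejected.

#' Gray-matter density volume
#'
#' A 3D scalar grid of per-voxel GM density in \[0, 1\], with voxel
#' dimensions in mm. This is the container for both individual GM density
#' maps and the population template; its voxel volume is the `Vs` that
#' converts displaced-GM voxel counts to millilitres.
#'
#' @param data 3D numeric array with finite values in \[0, 1\].
#' @param voxel_size_mm numeric(3), voxel edge lengths in mm (positive).
#' @param space_tag free-text label of the common space.
#' @return An object of class `density_volume` with fields `data`,
#'   `voxel_size_mm`, `voxel_volume_mm3` and `space_tag`.
#' @export
density_volume <- function(data, voxel_size_mm = c(1, 1, 1),
                           space_tag = "MNI-like") {
  data <- check_array3d(data)
  voxel_size_mm <- check_voxel_size(voxel_size_mm)
  if (anyNA(data) || any(!is.finite(data)))
    stop("density values must be finite")
  rng <- range(data)
  if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
    stop(sprintf("density values outside [0,1]: range %.6g..%.6g",
                 rng[1], rng[2]))
  # clamp tiny float excursions from resampling / file round-trips
  data[data < 0] <- 0
  data[data > 1] <- 1
  structure(
    list(data = data,
         voxel_size_mm = voxel_size_mm,
         voxel_volume_mm3 = prod(voxel_size_mm),
         space_tag = space_tag),
    class = c("density_volume", "brain_volume"))
}

#' Binary lesion mask
#'
#' A binary 3D grid marking the voxels occupied by a lesion (the CCM
#' label), on the same lattice as the density template. `n_voxels` is the
#' total in-lesion voxel count `N_ccm`.
#'
#' @param data 3D array of exactly 0/1 values.
#' @param voxel_size_mm numeric(3), voxel edge lengths in mm.
#' @return An object of class `lesion_mask` with fields `data`,
#'   `voxel_size_mm`, `voxel_volume_mm3` and `n_voxels`.
#' @export
lesion_mask <- function(data, voxel_size_mm = c(1, 1, 1)) {
  data <- check_array3d(data)
  voxel_size_mm <- check_voxel_size(voxel_size_mm)
  if (anyNA(data) || !all(data == 0 | data == 1))
    stop("mask values must be exactly 0 or 1")
  storage.mode(data) <- "integer"
  structure(
    list(data = data,
         voxel_size_mm = voxel_size_mm,
         voxel_volume_mm3 = prod(voxel_size_mm),
         n_voxels = sum(data)),
    class = c("lesion_mask", "brain_volume"))
}

#' Parcellation label volume
#'
#' A 3D integer grid of atlas region codes (0 = outside the atlas) plus a
#' code-to-name mapping.
#'
#' @param data 3D array of nonnegative integer codes.
#' @param voxel_size_mm numeric(3), voxel edge lengths in mm.
#' @param label_names named character vector mapping code (name) to region
#'   name (value); every nonzero code present in `data` must have an entry.
#'   If `NULL`, codes are auto-named `region_<code>`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, voxel_size_mm = c(1, 1, 1),
                         label_names = NULL) {
  data <- check_array3d(data)
  voxel_size_mm <- check_voxel_size(voxel_size_mm)
  if (anyNA(data) || any(data < 0) || any(data != round(data)))
    stop("label values must be nonnegative integers")
  storage.mode(data) <- "integer"
  codes <- sort(unique(data[data > 0L]))
  if (is.null(label_names)) {
    label_names <- stats::setNames(paste0("region_", codes),
                                   as.character(codes))
  }
  missing <- setdiff(as.character(codes), names(label_names))
  if (length(missing))
    stop("labels present in data but absent from label_names: ",
         paste(missing, collapse = ", "))
  structure(
    list(data = data,
         voxel_size_mm = voxel_size_mm,
         voxel_volume_mm3 = prod(voxel_size_mm),
         label_names = label_names),
    class = c("label_volume", "brain_volume"))
}

check_array3d <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected a 3D array")
  if (any(dim(data) < 1L)) stop("all dimensions must be positive")
  data
}

check_voxel_size <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 3L || anyNA(v) || any(v <= 0))
    stop("voxel_size_mm must be 3 positive reals")
  v
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels @ %s mm (%.4g mm^3/voxel)\n",
              class(x)[1],
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x"),
              x$voxel_volume_mm3))
  if (inherits(x, "lesion_mask"))
    cat(sprintf("  n_voxels = %d\n", x$n_voxels))
  if (inherits(x, "density_volume"))
    cat(sprintf("  density range %.3f..%.3f, space '%s'\n",
                min(x$data), max(x$data), x$space_tag))
  if (inherits(x, "label_volume"))
    cat(sprintf("  %d labelled regions\n", length(x$label_names)))
  invisible(x)
}

#' Read a volume from a NIfTI-1 file
#'
#' Reads `.nii`/`.nii.gz` and validates it as a density map, binary lesion
#' mask, or integer label volume. Mask files containing values other than
#' {0, 1} are binarized at > 0.5 with a warning. Files whose stored affine
#' contains rotation or shear are rejected: the package operates on
#' axis-aligned grids in one common space.
#'
#' @param path path to a NIfTI-1 file.
#' @param expected_kind one of `"density"`, `"mask"`, `"labels"`.
#' @param label_names optional code-to-name mapping for label volumes.
#' @param space_tag space label attached to density volumes.
#' @return A [density_volume()], [lesion_mask()] or [label_volume()].
#' @export
read_volume <- function(path,
                        expected_kind = c("density", "mask", "labels"),
                        label_names = NULL, space_tag = "MNI-like") {
  expected_kind <- match.arg(expected_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("unreadable NIfTI file '", path, "': ",
                         conditionMessage(e)))
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim = dim(arr))  # drop image attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got ", length(dim(arr)), "D: ", path)
  vs <- abs(RNifti::pixdim(img))[1:3]
  check_axis_aligned(img, path)
  switch(expected_kind,
    density = {
      rng <- range(arr)
      if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
        stop(sprintf(
          "density file '%s' has values outside [0,1] (range %.6g..%.6g)",
          path, rng[1], rng[2]))
      density_volume(arr, vs, space_tag = space_tag)
    },
    mask = {
      if (!all(arr == 0 | arr == 1)) {
        warning("mask '", path,
                "' contains non-binary values; binarized at > 0.5")
        arr <- (arr > 0.5) + 0L
      }
      lesion_mask(array(as.integer(arr), dim = dim(arr)), vs)
    },
    labels = label_volume(array(as.integer(round(arr)), dim = dim(arr)),
                          vs, label_names = label_names))
}

check_axis_aligned <- function(img, path = "<image>") {
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(xf, "try-error") || is.null(xf)) return(invisible(TRUE))
  R <- xf[1:3, 1:3]
  for (j in 1:3) {
    col <- R[, j]
    off <- abs(col[-j])
    if (any(off > 1e-4 * max(abs(col), 1)))
      stop("'", path, "': image affine contains rotation or shear; ",
           "only axis-aligned grids in a common space are supported")
  }
  invisible(TRUE)
}

#' Write a volume to a NIfTI-1 file
#'
#' Densities are stored as 32-bit float, masks and labels as integers.
#'
#' @param vol a `density_volume`, `lesion_mask` or `label_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "brain_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  dtype <- if (inherits(vol, "density_volume")) "float" else "int16"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Grid compatibility
#'
#' Two volumes share a grid when their shapes are identical and voxel sizes
#' agree within `tol_mm`. `same_grid()` is a pure predicate;
#' `assert_same_grid()` raises a grid error when it is false. This is the
#' package's stand-in for upstream voxel-to-voxel co-registration: it can
#' only verify lattice agreement, not anatomical alignment.
#'
#' @param a,b brain volumes.
#' @param tol_mm absolute tolerance on voxel size, in mm.
#' @return `same_grid()`: logical. `assert_same_grid()`: `TRUE` invisibly,
#'   or an error.
#' @export
same_grid <- function(a, b, tol_mm = 1e-6) {
  stopifnot(inherits(a, "brain_volume"), inherits(b, "brain_volume"))
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) <= tol_mm)
}

#' @rdname same_grid
#' @export
assert_same_grid <- function(a, b, tol_mm = 1e-6) {
  if (!same_grid(a, b, tol_mm))
    stop(sprintf(
      "grid mismatch: %s @ (%s) mm vs %s @ (%s) mm",
      paste(dim(a$data), collapse = "x"),
      paste(format(a$voxel_size_mm), collapse = ","),
      paste(dim(b$data), collapse = "x"),
      paste(format(b$voxel_size_mm), collapse = ",")))
  invisible(TRUE)
}

#' Resample a volume onto a target grid
#'
#' Axis-aligned resampling with a shared origin: output voxel index `i`
#' (0-based) maps to world coordinate `i * voxel_size`, which is converted
#' to a source index and interpolated. Masks and label volumes must use
#' nearest-neighbour; densities may use trilinear interpolation (which
#' cannot leave the source value range).
#'
#' @param src volume to resample.
#' @param shape integer(3), target grid shape.
#' @param voxel_size_mm numeric(3), target voxel size in mm.
#' @param method `"nearest"` or `"trilinear"`.
#' @return A volume of the same class as `src` on the target grid.
#' @export
resample_to_grid <- function(src, shape, voxel_size_mm,
                             method = c("nearest", "trilinear")) {
  stopifnot(inherits(src, "brain_volume"))
  method <- match.arg(method)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size_mm <- check_voxel_size(voxel_size_mm)
  if (method == "trilinear" && !inherits(src, "density_volume"))
    stop("trilinear resampling is only valid for density volumes; ",
         "use method = 'nearest' for masks and label volumes")

  sdim <- dim(src$data)
  # source index (0-based, fractional) of each target voxel, per axis
  coord <- lapply(1:3, function(ax) {
    (seq_len(shape[ax]) - 1) * voxel_size_mm[ax] / src$voxel_size_mm[ax]
  })

  if (method == "nearest") {
    idx <- lapply(1:3, function(ax)
      pmin(pmax(round(coord[[ax]]) + 1, 1), sdim[ax]))
    out <- src$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dim(out) <- shape
  } else {
    lo <- lapply(1:3, function(ax)
      pmin(pmax(floor(coord[[ax]]), 0), sdim[ax] - 1))
    fr <- lapply(1:3, function(ax) {
      f <- coord[[ax]] - lo[[ax]]
      pmin(pmax(f, 0), 1)
    })
    hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1, sdim[ax] - 1))
    out <- array(0, dim = shape)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ix <- (if (cx) hi[[1]] else lo[[1]]) + 1
      iy <- (if (cy) hi[[2]] else lo[[2]]) + 1
      iz <- (if (cz) hi[[3]] else lo[[3]]) + 1
      wx <- if (cx) fr[[1]] else 1 - fr[[1]]
      wy <- if (cy) fr[[2]] else 1 - fr[[2]]
      wz <- if (cz) fr[[3]] else 1 - fr[[3]]
      w <- outer(outer(wx, wy), wz)
      dim(w) <- shape
      block <- src$data[ix, iy, iz, drop = FALSE]
      dim(block) <- shape
      out <- out + w * block
    }
  }

  if (inherits(src, "density_volume"))
    density_volume(out, voxel_size_mm, space_tag = src$space_tag)
  else if (inherits(src, "lesion_mask"))
    lesion_mask(out, voxel_size_mm)
  else
    label_volume(out, voxel_size_mm, label_names = src$label_names)
}
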