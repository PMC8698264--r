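# shared fixture builders (all in-code; no files shipped)

random_density <- function(dim = c(8, 8, 8), voxel = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  density_volume(array(runif(prod(dim)), dim = dim), voxel)
}

random_mask <- function(dim = c(8, 8, 8), voxel = c(1, 1, 1),
                        p = 0.3, seed = 2) {
  set.seed(seed)
  lesion_mask(array(rbinom(prod(dim), 1, p), dim = dim), voxel)
}

# small phantom configuration used across generator tests
small_cfg <- function(seed = 11, ...) {
  args <- list(grid_shape = c(48, 48, 48), voxel_size_mm = c(2, 2, 2),
               shell_outer_mm = 40, shell_inner_mm = 32,
               n_per_group = c(seizure_like = 6, nonseizure_like = 20),
               lesion_radius_mm = c(3, 9), seed = seed)
  extra <- list(...)
  do.call(synth_config, c(extra, args[setdiff(names(args), names(extra))]))
}

# box-shaped mask over inclusive 1-based index ranges
box_mask <- function(dim, xr, yr, zr, voxel = c(1, 1, 1)) {
  m <- array(0L, dim = dim)
  m[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- 1L
  lesion_mask(m, voxel)
}
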