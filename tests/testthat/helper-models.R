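## Shared builders for small test objects. Everything is generated in code;
## sizes are kept small so the whole suite stays fast.

## default-geometry spec with a configurable length / protofilament count
quick_spec <- function(n_pf = 5, tube_length_nm = 35.2, ...) {
  tube_lattice_spec(n_pf = n_pf, tube_length_nm = tube_length_nm, ...)
}

## a short wedge-filtered tube chunk in the lab frame (axis along y),
## used as ground truth by the subtomogram tests
tube_chunk_volume <- function(voxel_size_nm = 0.8, box_nm = 20,
                              wedge_half_angle_deg = 60,
                              tube_length_nm = 8.8) {
  spec <- quick_spec(tube_length_nm = tube_length_nm)
  model <- orient_model(build_tube(spec), tilt_geometry())
  map <- rasterize(model, voxel_size_nm, box_nm = rep(box_nm, 3))
  wedge_tomogram(map, wedge_half_angle_deg)$data
}

## wrap a list of equal-size cubic volumes as a subvolume_set
as_subvolume_set <- function(volumes, voxel_size_nm = 0.8) {
  structure(list(volumes = volumes,
                 centers = matrix(0, length(volumes), 3),
                 box_voxels = dim(volumes[[1]])[1],
                 voxel_size_nm = voxel_size_nm,
                 axis_direction = c(0, 1, 0)),
            class = "subvolume_set")
}

## n noisy copies of a volume under a fixed seed
with_seed_list <- function(n, truth, sd_noise, seed = 123) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    truth + array(stats::rnorm(length(truth), 0, sd_noise), dim(truth)))
}

## isotropic Gaussian blob phantom
blob_map <- function(n = 32, voxel_size_nm = 0.5, sigma_nm = 1.5) {
  ax <- (seq_len(n) - (n + 1) / 2) * voxel_size_nm
  g <- exp(-ax^2 / (2 * sigma_nm^2))
  density_map(outer(outer(g, g), g), voxel_size_nm)
}

## continuous cylindrical shell along y (annulus in every x-z section)
annulus_map <- function(n = 48, voxel_size_nm = 0.5, radius_nm = 3.9,
                        sigma_wall_nm = 0.8) {
  ax <- (seq_len(n) - (n + 1) / 2) * voxel_size_nm
  r <- sqrt(outer(ax^2, ax^2, `+`))
  ring <- exp(-((r - radius_nm)^2) / (2 * sigma_wall_nm^2))
  arr <- array(0, c(n, n, n))
  for (j in seq_len(n)) arr[, j, ] <- ring
  density_map(arr, voxel_size_nm)
}

## 0-degree projection image of a tube model (tube axis along image y)
tube_projection <- function(spec, voxel_size_nm = 0.4, ...) {
  model <- orient_model(build_tube(spec, ...), tilt_geometry())
  map <- rasterize(model, voxel_size_nm)
  project_tilt_series(map, tilt_geometry(-1, 1, 1))$images[, , 2]
}
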