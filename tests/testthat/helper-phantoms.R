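# Shared synthetic fixtures, built in code at test time.

sphere_mask <- function(shape = c(32, 32, 32), r = 8, center = c(0, 0, 0),
                        affine = growthtrack:::center_affine(shape)) {
  pts <- growthtrack:::voxel_centers_world(shape, affine)
  d2 <- rowSums(sweep(pts, 2, center, `-`)^2)
  mask_volume(array(as.double(d2 <= r^2), shape), affine)
}

uniform_dirs_field <- function(shape, direction = c(1, 0, 0),
                               affine = growthtrack:::center_affine(shape)) {
  principal_direction_map(
    generate_fiber_field(shape, fiber_pattern("uniform", direction = direction),
                         affine))
}
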