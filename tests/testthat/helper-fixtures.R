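# Shared fixtures, generated in code at test time.

# A small rasterized scene with a single vessel tree (uniform sO2).
make_test_scene <- function(seed = 3, field = c(96, 96), n_roots = 1,
                            background_level = 0) {
  tree <- generate_vessel_tree(seed = seed, n_roots = n_roots,
                               max_depth = 4, field_size = field)
  rasterize_scene(tree, background_level = background_level)
}

# A horizontal bright ridge of the given width on a black background.
make_ridge <- function(n = 64, width = 3, amplitude = 1) {
  img <- matrix(0, n, n)
  mid <- n %/% 2
  rows <- (mid - width %/% 2):(mid + width %/% 2)
  img[rows, ] <- amplitude
  img
}

# A tiny subnetwork profile so shape/gradient tests stay fast.
tiny_config <- function(scale = 2L, in_channels = 1L) {
  rdn_config(D = 2L, C = 2L, G = 3L, G0 = 4L, scale = scale,
             in_channels = in_channels)
}
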