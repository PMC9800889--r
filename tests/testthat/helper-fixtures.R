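# Shared fixtures. Phantoms are deterministic, so expensive ones are built
# once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Full-size phantom (256 px, the networks' input contract) with analytic flows.
default_phantom <- function(amplitude = 0.15, mode = "contraction",
                            n_frames = 16, translation = c(0, 0), n_points = 180) {
  key <- paste("ph", amplitude, mode, n_frames, paste(translation, collapse = "_"), n_points)
  cached(key, function() {
    geo <- phantom_geometry()
    mot <- phantom_motion(amplitude = amplitude, n_frames = n_frames, mode = mode,
                          translation = translation)
    make_phantom(geo, mot, speckle_seed = 7, n_points = n_points)
  })
}

# Tiny phantom (32 px) for network training smoke tests.
tiny_phantom <- function(amplitude = 0.2, n_frames = 10, speckle_seed = 5) {
  key <- paste("tiny", amplitude, n_frames, speckle_seed)
  cached(key, function() {
    geo <- phantom_geometry(image_size = c(32, 32), center = c(16, 16),
                            r_endo = 7, r_epi = 13, opening_half_angle = pi / 4,
                            pixel_spacing = 1)
    mot <- phantom_motion(amplitude = amplitude, n_frames = n_frames,
                          period_frames = n_frames)
    make_phantom(geo, mot, speckle_seed = speckle_seed, n_points = 20)
  })
}

tiny_flow_config <- function(iterations = 4) {
  flow_config(encoder_filters = c(8, 8, 12, 12, 16, 16), lookup_radius = 3,
              iterations = iterations, hidden_dim = 16, context_dim = 16,
              motion_dim = 16)
}

# Half-annulus band mask with analytically known mid-circle (radius 50).
half_annulus_mask <- function() {
  cached("half_annulus", function() {
    g <- expand.grid(y = 0:127, x = 0:127)
    r <- sqrt((g$x - 64)^2 + (g$y - 64)^2)
    matrix(as.integer(r >= 40 & r <= 60 & (g$y - 64) <= 0), 128, 128, byrow = FALSE)
  })
}

# Strain result from the oracle-flow pipeline on a default phantom.
oracle_strain <- function(amplitude = 0.15, mode = "contraction",
                          translation = c(0, 0), n_frames = 16) {
  ph <- default_phantom(amplitude, mode, n_frames, translation)
  cl <- extract_centerline(ph$masks[, , 1], pixel_spacing = ph$geometry$pixel_spacing)
  traj <- track_centerline(cl, oracle_estimator(ph))
  compute_strain(traj, divide_segments(cl, "A4C"))
}

as_hw2 <- function(flow_chw) {
  array(c(flow_chw[1, , ], flow_chw[2, , ]),
        c(dim(flow_chw)[2], dim(flow_chw)[3], 2))
}
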