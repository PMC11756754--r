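# Small scene fixtures shared across test files; everything is generated
# in code, nothing is read from disk.

# one capsule with the cyst at exact focus of plane z = 0
quiet_spherical <- function(seed = 1, ...) {
  spherical_scene(cyst_z = 0, noise_sd = 0, seed = seed, ...)
}

# a frame plus the matching truth row at one time
spherical_frame_at <- function(scene, time, z = scene$capsules$cyst_z[1]) {
  list(
    frame = render_frame(scene, z = z, time = time, noise = FALSE),
    truth = scene_truth(scene, time)
  )
}

# 90-degree rotation of an image matrix (top-left origin)
rotate90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
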