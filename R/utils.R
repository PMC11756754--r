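# Run code with a locally set RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  force(code)
}

# Deterministic per-frame sub-seed below 2^31, derived from a scene seed and
# the frame's (z, time) coordinates.
derive_seed <- function(seed, z, time) {
  as.integer((abs(seed) + 7919 * round(time * 240) + 104729 * round(z * 4) +
                1) %% 2147483647L)
}

# Physical x (column) and y (row) coordinates of pixel centres, um.
# Convention: origin top-left, 0-based indices, coord = index * pixel_equiv.
frame_coords <- function(width_px, height_px, pixel_equiv) {
  list(
    x = (seq_len(width_px) - 1) * pixel_equiv,
    y = (seq_len(height_px) - 1) * pixel_equiv
  )
}

# Gaussian blur that tolerates tiny sigmas and plain matrices.
blur_px <- function(img, sigma_px) {
  if (sigma_px < 0.05) return(img)
  EBImage::gblur(img, sigma = sigma_px)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
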