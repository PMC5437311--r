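# Small rasterized shapes used across the imaging tests. Coordinates are
# pixel centers, 0-based, matching the package convention.

disk_mask <- function(radius, size = 2 * radius + 16) {
  c0 <- (size - 1) / 2
  yy <- matrix(rep(0:(size - 1), size), nrow = size)
  xx <- t(yy)
  ((yy - c0)^2 + (xx - c0)^2 <= radius^2) * 1L
}

square_mask <- function(side, size = side + 16) {
  m <- matrix(0L, size, size)
  o <- floor((size - side) / 2)
  m[o + seq_len(side), o + seq_len(side)] <- 1L
  m
}

as_series <- function(frame) array(frame, dim = c(1, nrow(frame), ncol(frame)))

# default feature parameters for analytic shapes: no core opening so the
# core/invasive split does not interfere with pure-shape checks
shape_params <- segmentation_params(core_opening_radius = 0)
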