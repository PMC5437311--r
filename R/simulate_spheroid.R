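# Spheroid phantom generator: a bright core plus radial branches growing
# linearly over time, rasterized into a (t, z, y, x) stack with z-structured
# foreground so that the z-standard-deviation projection separates it from a
# flat background. Ground truth (area, invasive radius, branch count,
# invasive area) is analytic.

#' Specification of a spheroid phantom
#'
#' Describes the geometry, intensities and noise of a synthetic 3D spheroid
#' time-lapse. Frames are 1-based; at frame `t` each branch ray extends
#' `branch_growth_rate * t` pixels beyond the core boundary, so the true
#' invasive radius at frame `t` is `core_radius + branch_growth_rate * t`
#' (or `core_radius` when `n_branches = 0`).
#'
#' @param image_shape integer vector `c(T, Z, Y, X)`: number of frames,
#'   z-planes, rows and columns.
#' @param core_radius radius of the central core disk, px (>= 1).
#' @param n_branches number of radial branches (>= 0). Branch angles are
#'   evenly spaced with a small random jitter, so they are always distinct.
#' @param branch_growth_rate elongation of each branch per frame, px/frame.
#' @param branch_width branch thickness, px.
#' @param fg_intensity,bg_intensity mean foreground/background intensity,
#'   arbitrary units; `fg_intensity > bg_intensity` is required.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed; required, the generator keeps no global state.
#' @param pixel_size optional spatial calibration, micrometres per pixel.
#' @param frame_interval optional time between frames, minutes.
#' @return An object of class `spheroid_phantom_spec`.
#' @seealso [simulate_spheroid_stack()]
#' @export
spheroid_phantom_spec <- function(image_shape = c(8, 4, 192, 192),
                                  core_radius = 16,
                                  n_branches = 5,
                                  branch_growth_rate = 8,
                                  branch_width = 5,
                                  fg_intensity = 100,
                                  bg_intensity = 10,
                                  noise_sd = 4,
                                  seed,
                                  pixel_size = NULL,
                                  frame_interval = NULL) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (length(image_shape) != 4 || any(image_shape < 1)) {
    stop("`image_shape` must be c(T, Z, Y, X) with positive entries",
         call. = FALSE)
  }
  check_number(core_radius, "core_radius", min = 1)
  check_number(n_branches, "n_branches", min = 0, integer = TRUE)
  check_number(branch_growth_rate, "branch_growth_rate", min = 0)
  check_number(branch_width, "branch_width", min = 1)
  check_number(fg_intensity, "fg_intensity")
  check_number(bg_intensity, "bg_intensity")
  if (fg_intensity <= bg_intensity) {
    stop("`fg_intensity` must exceed `bg_intensity`", call. = FALSE)
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(seed, "seed", integer = TRUE)

  spec <- structure(
    list(image_shape = as.integer(image_shape),
         core_radius = core_radius, n_branches = as.integer(n_branches),
         branch_growth_rate = branch_growth_rate,
         branch_width = branch_width,
         fg_intensity = fg_intensity, bg_intensity = bg_intensity,
         noise_sd = noise_sd, seed = as.integer(seed),
         pixel_size = pixel_size, frame_interval = frame_interval),
    class = "spheroid_phantom_spec")

  # All geometry must fit inside the (Y, X) frame at every time point.
  bad <- phantom_out_of_bounds_frame(spec)
  if (!is.na(bad)) {
    stop(sprintf(
      "phantom geometry exceeds image bounds at frame %d (tip radius %.1f px)",
      bad, spec$core_radius + spec$branch_growth_rate * bad +
        spec$branch_width / 2), call. = FALSE)
  }
  spec
}

# First frame whose geometry spills outside the image, or NA if none.
phantom_out_of_bounds_frame <- function(spec) {
  Tn <- spec$image_shape[1]; Y <- spec$image_shape[3]; X <- spec$image_shape[4]
  cy <- (Y - 1) / 2; cx <- (X - 1) / 2
  margin <- min(cy, cx, Y - 1 - cy, X - 1 - cx)
  len <- if (spec$n_branches > 0) spec$branch_growth_rate * seq_len(Tn) else 0
  tip <- spec$core_radius + len + if (spec$n_branches > 0) spec$branch_width / 2 else 0
  bad <- which(tip > margin)
  if (length(bad)) bad[1] else NA_integer_
}

#' Simulate a 4D spheroid phantom stack with analytic ground truth
#'
#' Rasterizes a central core disk plus `n_branches` radial rays into every
#' frame. Foreground voxels carry a linear intensity ramp across z (from
#' 0.5x to 1.5x the foreground contrast), so that the z-standard deviation
#' of a foreground column is strictly positive while background columns are
#' constant in z; additive Gaussian noise is applied everywhere. A ray at
#' frame `t` is the rectangle of width `branch_width` reaching from the core
#' boundary to `core_radius + branch_growth_rate * t`, capped by a half-disk
#' at the tip, so the true invasive area has the closed form
#' `n_branches * (rate * t * width + pi * (width/2)^2 / 2)`.
#'
#' @param spec a [spheroid_phantom_spec()].
#' @return A list with components:
#' \describe{
#'   \item{stack}{numeric array `(T, Z, Y, X)` of intensities, with
#'     `pixel_size` / `frame_interval` attributes when supplied.}
#'   \item{truth}{data frame with one row per frame: `frame`, `true_area`,
#'     `true_invasive_radius`, `true_branch_count`, `true_invasive_area`
#'     (analytic values, px units).}
#'   \item{truth_mask}{binary array `(T, Y, X)`: the rasterized foreground.}
#'   \item{branch_angles}{branch directions, radians.}
#'   \item{core_center}{`c(y, x)` image-center coordinates (0-based px).}
#'   \item{spec}{the input spec.}
#' }
#' @examples
#' ph <- simulate_spheroid_stack(spheroid_phantom_spec(
#'   image_shape = c(3, 3, 96, 96), core_radius = 12, n_branches = 3,
#'   branch_growth_rate = 6, noise_sd = 0, seed = 1))
#' ph$truth
#' @export
simulate_spheroid_stack <- function(spec) {
  stopifnot(inherits(spec, "spheroid_phantom_spec"))
  Tn <- spec$image_shape[1]; Z <- spec$image_shape[2]
  Y <- spec$image_shape[3]; X <- spec$image_shape[4]
  if (Z < 2) stop("phantom needs >= 2 z-planes", call. = FALSE)
  cy <- (Y - 1) / 2; cx <- (X - 1) / 2

  with_seed(spec$seed, {
    angles <- phantom_branch_angles(spec$n_branches)

    # pixel-center coordinates, 0-based
    yy <- matrix(rep(0:(Y - 1), X), nrow = Y)
    xx <- matrix(rep(0:(X - 1), each = Y), nrow = Y)
    dy <- yy - cy; dx <- xx - cx
    rr <- sqrt(dy^2 + dx^2)
    core <- rr <= spec$core_radius

    ramp <- if (Z > 1) 0.5 + (seq_len(Z) - 1) / (Z - 1) else 1
    contrast <- spec$fg_intensity - spec$bg_intensity

    stack <- array(0, dim = c(Tn, Z, Y, X))
    truth_mask <- array(0L, dim = c(Tn, Y, X))
    truth <- data.frame(frame = seq_len(Tn), true_area = NA_real_,
                        true_invasive_radius = NA_real_,
                        true_branch_count = spec$n_branches,
                        true_invasive_area = NA_real_)

    for (t in seq_len(Tn)) {
      len <- spec$branch_growth_rate * t
      mask <- core
      if (spec$n_branches > 0 && len > 0) {
        w2 <- spec$branch_width / 2
        # the half-disk cap sits at core_radius + len - w2, so the ray's
        # furthest extent is exactly core_radius + len
        rl <- max(len - w2, 0)
        for (a in angles) {
          u <- c(cos(a), sin(a))            # (x, y) direction
          s <- dx * u[1] + dy * u[2]        # along-ray coordinate
          d <- abs(-dx * u[2] + dy * u[1])  # perpendicular distance
          capx <- cx + (spec$core_radius + rl) * u[1]
          capy <- cy + (spec$core_radius + rl) * u[2]
          ray <- (s >= spec$core_radius & s <= spec$core_radius + rl & d <= w2) |
            ((xx - capx)^2 + (yy - capy)^2 <= w2^2 & s > spec$core_radius)
          mask <- mask | ray
        }
      }
      truth_mask[t, , ] <- mask * 1L
      w2 <- spec$branch_width / 2
      inv_area <- if (spec$n_branches > 0 && len > 0) {
        spec$n_branches *
          (max(len - w2, 0) * spec$branch_width + pi * w2^2 / 2)
      } else 0
      truth$true_area[t] <- pi * spec$core_radius^2 + inv_area
      truth$true_invasive_area[t] <- inv_area
      truth$true_invasive_radius[t] <- spec$core_radius +
        if (spec$n_branches > 0 && len > 0) max(len, w2) else 0

      for (z in seq_len(Z)) {
        plane <- spec$bg_intensity + contrast * ramp[z] * mask
        stack[t, z, , ] <- plane
      }
    }
    if (spec$noise_sd > 0) {
      stack <- stack + array(rnorm(length(stack), sd = spec$noise_sd),
                             dim = dim(stack))
    }
    attr(stack, "pixel_size") <- spec$pixel_size
    attr(stack, "frame_interval") <- spec$frame_interval
    list(stack = stack, truth = truth, truth_mask = truth_mask,
         branch_angles = angles, core_center = c(y = cy, x = cx),
         spec = spec)
  })
}

# Evenly spaced angles with a random global rotation: always distinct,
# never touching at the core for realistic widths, and rotationally
# balanced so the phantom's centroid stays at the core centre at every
# frame (the truth invasive radius core_radius + rate*t is measured from
# the centroid).
phantom_branch_angles <- function(n) {
  if (n == 0) return(numeric(0))
  gap <- 2 * pi / n
  (gap * (seq_len(n) - 1) + runif(1, 0, 2 * pi)) %% (2 * pi)
}
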