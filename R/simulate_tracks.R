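# Persistent-random-walk simulator for invasive-chain tracks, with an
# optional leader-detachment event that changes the step speed.

#' Specification of simulated chain tracks
#'
#' Tracks are persistent random walks sampled once per frame: the heading
#' turns by a Gaussian angle with standard deviation `(1 - persistence) * pi`
#' between frames, and the step length is exactly `speed_pre` px/frame up to
#' and including the step into `detachment_frame`, and `speed_post`
#' afterwards. Positions are then jittered by isotropic Gaussian noise of
#' standard deviation `noise_sd` (localization error).
#'
#' @param n_tracks number of tracks to simulate.
#' @param n_frames samples per track (frames 1..n_frames).
#' @param frame_interval minutes between frames.
#' @param speed_pre,speed_post step length before/after the detachment
#'   event, px/frame. `speed_post` is ignored when `detachment_frame` is
#'   `NULL`.
#' @param detachment_frame frame of the leader-detachment event
#'   (`1 < detachment_frame < n_frames`), or `NULL` for no event.
#' @param persistence directional correlation in `[0, 1]`; 1 gives a
#'   straight track, 0 an uncorrelated random walk.
#' @param noise_sd positional jitter, px.
#' @param seed integer seed; required.
#' @return Object of class `track_sim_spec`.
#' @export
track_sim_spec <- function(n_tracks = 1, n_frames = 100, frame_interval = 10,
                           speed_pre = 2, speed_post = 0.5,
                           detachment_frame = NULL, persistence = 0.9,
                           noise_sd = 0, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  check_number(n_tracks, "n_tracks", min = 1, integer = TRUE)
  check_number(n_frames, "n_frames", min = 2, integer = TRUE)
  check_number(frame_interval, "frame_interval", min = 0)
  check_number(speed_pre, "speed_pre", min = 0)
  check_number(speed_post, "speed_post", min = 0)
  check_number(persistence, "persistence", min = 0, max = 1)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(seed, "seed", integer = TRUE)
  if (!is.null(detachment_frame)) {
    check_number(detachment_frame, "detachment_frame", min = 2,
                 max = n_frames - 1, integer = TRUE)
    detachment_frame <- as.integer(detachment_frame)
  }
  structure(
    list(n_tracks = as.integer(n_tracks), n_frames = as.integer(n_frames),
         frame_interval = frame_interval, speed_pre = speed_pre,
         speed_post = speed_post, detachment_frame = detachment_frame,
         persistence = persistence, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "track_sim_spec")
}

#' Simulate persistent-random-walk chain tracks
#'
#' @param spec a [track_sim_spec()].
#' @return A data frame of class `track_set` with columns `track_id`,
#'   `frame`, `x`, `y` (px, 0-based origin at each track start before
#'   jitter), carrying attributes `frame_interval` (minutes) and `truth`
#'   (a data frame of the per-track simulated `speed_pre`, `speed_post` and
#'   `detachment_frame`).
#' @examples
#' trk <- simulate_tracks(track_sim_spec(
#'   n_frames = 10, speed_pre = 1, persistence = 1, noise_sd = 0, seed = 7))
#' head(trk)
#' @export
simulate_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_sim_spec"))
  with_seed(spec$seed, {
    out <- vector("list", spec$n_tracks)
    for (k in seq_len(spec$n_tracks)) {
      n <- spec$n_frames
      theta <- numeric(n - 1)
      theta[1] <- runif(1, 0, 2 * pi)
      if (n > 2) {
        turns <- rnorm(n - 2, sd = (1 - spec$persistence) * pi)
        theta[-1] <- theta[1] + cumsum(turns)
      }
      speeds <- rep(spec$speed_pre, n - 1)
      if (!is.null(spec$detachment_frame)) {
        post <- seq_len(n - 1) + 1 > spec$detachment_frame
        speeds[post] <- spec$speed_post
      }
      x <- c(0, cumsum(speeds * cos(theta)))
      y <- c(0, cumsum(speeds * sin(theta)))
      if (spec$noise_sd > 0) {
        x <- x + rnorm(n, sd = spec$noise_sd)
        y <- y + rnorm(n, sd = spec$noise_sd)
      }
      out[[k]] <- data.frame(track_id = k, frame = seq_len(n), x = x, y = y)
    }
    tracks <- do.call(rbind, out)
    attr(tracks, "frame_interval") <- spec$frame_interval
    attr(tracks, "truth") <- data.frame(
      track_id = seq_len(spec$n_tracks),
      speed_pre = spec$speed_pre, speed_post = spec$speed_post,
      detachment_frame = if (is.null(spec$detachment_frame)) NA_integer_
                         else spec$detachment_frame)
    class(tracks) <- c("track_set", "data.frame")
    tracks
  })
}
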