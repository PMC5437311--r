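# Invasive-chain track metrics: path length, net displacement, velocity,
# pre/post leader-detachment splits, cumulative distance profiles and
# chain-relative positions.

# validate and extract one track (data frame with frame, x, y)
check_track <- function(track) {
  need <- c("frame", "x", "y")
  if (!all(need %in% names(track))) {
    stop("a track needs columns frame, x, y", call. = FALSE)
  }
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) < 2) stop("a track needs >= 2 samples", call. = FALSE)
  if (any(diff(track$frame) <= 0)) {
    stop("track frames must be strictly increasing", call. = FALSE)
  }
  track
}

track_metrics_one <- function(track, frame_interval) {
  track <- check_track(track)
  steps <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  path <- sum(steps)
  disp <- sqrt((track$x[nrow(track)] - track$x[1])^2 +
                 (track$y[nrow(track)] - track$y[1])^2)
  n_intervals <- track$frame[nrow(track)] - track$frame[1]
  duration_h <- if (is.null(frame_interval)) NA_real_ else
    n_intervals * frame_interval / 60
  data.frame(
    n_samples = nrow(track),
    duration_h = duration_h,
    path_length = path,
    displacement = disp,
    mean_velocity = if (is.na(duration_h) || duration_h == 0) NA_real_
                    else path / duration_h,
    displacement_velocity = if (is.na(duration_h) || duration_h == 0) NA_real_
                            else disp / duration_h,
    straightness = if (path > 0) disp / path else NA_real_)
}

#' Track displacement, path length and velocity
#'
#' Computes, per track: the path length (sum of consecutive Euclidean
#' steps), the net displacement (first-to-last distance), the duration, and
#' two velocity readings — `mean_velocity = path_length / elapsed time`
#' (speed along the path, the default reading) and
#' `displacement_velocity = displacement / elapsed time`. A gap in the
#' frame numbering is treated as a single straight step.
#'
#' @param tracks data frame with columns `track_id`, `frame`, `x`, `y`
#'   (a single track may omit `track_id`). Coordinates in px, frames
#'   strictly increasing within a track.
#' @param frame_interval minutes per frame; taken from the
#'   `frame_interval` attribute of `tracks` when not supplied. When
#'   unknown, time-based quantities are `NA`.
#' @param pixel_size optional um/px; adds `path_length_um` and
#'   `displacement_um` columns.
#' @return data frame with one row per track: `track_id`, `n_samples`,
#'   `duration_h`, `path_length`, `displacement`, `mean_velocity` (px/h),
#'   `displacement_velocity` (px/h), `straightness`
#'   (displacement/path, in (0, 1]).
#' @examples
#' trk <- data.frame(track_id = 1, frame = 1:11, x = 0:10, y = 0)
#' track_metrics(trk, frame_interval = 10)  # 10 px in 100 min = 6 px/h
#' @export
track_metrics <- function(tracks, frame_interval = NULL, pixel_size = NULL) {
  if (is.null(frame_interval)) frame_interval <- attr(tracks, "frame_interval")
  if (!"track_id" %in% names(tracks)) tracks$track_id <- 1L
  ids <- unique(tracks$track_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    m <- track_metrics_one(tracks[tracks$track_id == id, , drop = FALSE],
                           frame_interval)
    cbind(track_id = id, m)
  }))
  if (!is.null(pixel_size)) {
    out$path_length_um <- out$path_length * pixel_size
    out$displacement_um <- out$displacement * pixel_size
  }
  rownames(out) <- NULL
  out
}

#' Split a track at an event frame and compare the halves
#'
#' Computes [track_metrics()] independently on the sub-track up to and
#' including `event_frame` (pre) and from `event_frame` onwards (post); the
#' event sample is shared by both halves. Used to compare chain dynamics
#' before and after leader-cell detachment.
#'
#' @param track one track (data frame `frame`, `x`, `y`).
#' @param event_frame frame of the event; must be strictly inside the
#'   track's frame range and present as a sample.
#' @inheritParams track_metrics
#' @return list of class `event_split` with elements `event_frame`, `pre`
#'   and `post` (each a one-row metrics data frame).
#' @export
split_at_event <- function(track, event_frame, frame_interval = NULL) {
  if (is.null(frame_interval)) frame_interval <- attr(track, "frame_interval")
  track <- check_track(track)
  fr <- track$frame
  if (event_frame <= fr[1] || event_frame >= fr[length(fr)]) {
    stop("`event_frame` must lie strictly inside the track's frame range",
         call. = FALSE)
  }
  if (!event_frame %in% fr) {
    stop("`event_frame` is not a sampled frame of this track", call. = FALSE)
  }
  pre <- track[fr <= event_frame, , drop = FALSE]
  post <- track[fr >= event_frame, , drop = FALSE]
  structure(list(event_frame = event_frame,
                 pre = track_metrics_one(pre, frame_interval),
                 post = track_metrics_one(post, frame_interval)),
            class = "event_split")
}

#' Cumulative distance profile of a track
#'
#' @inheritParams split_at_event
#' @return data frame `frame`, `time_h` (`NA` without a frame interval) and
#'   `cumulative_path` (px), starting at 0 and monotone non-decreasing.
#'   A plateau in the profile indicates an arrested chain.
#' @export
distance_profile <- function(track, frame_interval = NULL) {
  if (is.null(frame_interval)) frame_interval <- attr(track, "frame_interval")
  track <- check_track(track)
  steps <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  data.frame(
    frame = track$frame,
    time_h = if (is.null(frame_interval)) NA_real_ else
      (track$frame - track$frame[1]) * frame_interval / 60,
    cumulative_path = c(0, cumsum(steps)))
}

#' Positions relative to a reference point
#'
#' Translates all samples of a track so that `reference` maps to the
#' origin; used to plot a detached leader cell relative to the chain it
#' left behind.
#'
#' @param track one track (data frame `frame`, `x`, `y`).
#' @param reference numeric `c(x, y)` reference point.
#' @return the track with `x`, `y` replaced by reference-relative
#'   coordinates.
#' @export
relative_positions <- function(track, reference) {
  stopifnot(is.numeric(reference), length(reference) == 2)
  track <- check_track(track)
  track$x <- track$x - reference[1]
  track$y <- track$y - reference[2]
  track
}
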