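# Per-frame invasion features of a polished mask series: area, perimeter,
# centroid, invasive radius (furthest boundary point from the centroid),
# skeleton-endpoint branch count, core/invasive area split by morphological
# opening, and circularity 4*pi*A/P^2 as an indirect measure of sheet-like
# invasion.

#' Compute per-frame spheroid invasion features
#'
#' For every frame of a polished binary mask:
#' * `area` — foreground pixel count (px^2);
#' * `centroid_y`, `centroid_x` — foreground pixel mean (0-based px);
#' * `perimeter` — boundary chain length with diagonal steps weighted
#'   `sqrt(2)` (the ImageJ-style estimator);
#' * `invasive_radius` — maximum Euclidean distance from the centroid to a
#'   boundary pixel (a foreground pixel with a 4-neighbour in background);
#' * `branch_count` — number of skeleton endpoints (skeleton pixels with
#'   exactly one 8-connected skeleton neighbour) after pruning spurs
#'   shorter than `spur_prune_length`;
#' * `core_area` — area of the morphological opening with a disk of radius
#'   `core_opening_radius` (the opening removes thin branches, leaving the
#'   core);
#' * `invasive_area` — `area - core_area`;
#' * `circularity` — `4 * pi * area / perimeter^2` (1 for a disk).
#'
#' Empty frames yield `NA` for all features except `area = 0`.
#'
#' @param mask binary `(T, Y, X)` array, normally from [polish_masks()].
#' @param params a [segmentation_params()] (supplies
#'   `core_opening_radius` and `spur_prune_length`).
#' @param pixel_size optional um/px; adds `area_um2`, `invasive_area_um2`
#'   and `invasive_radius_um` columns.
#' @param frame_interval optional minutes/frame; adds a `time_h` column.
#' @return data frame of class `spheroid_features`, one row per frame.
#' @export
compute_features <- function(mask, params = segmentation_params(),
                             pixel_size = NULL, frame_interval = NULL) {
  d <- dim(mask)
  if (length(d) != 3) stop("`mask` must be a (T, Y, X) array", call. = FALSE)
  if (is.null(pixel_size)) pixel_size <- attr(mask, "pixel_size")
  if (is.null(frame_interval)) frame_interval <- attr(mask, "frame_interval")

  open_brush <- if (params$core_opening_radius > 0) {
    EBImage::makeBrush(2 * as.integer(params$core_opening_radius) + 1, "disc")
  } else NULL

  rows <- lapply(seq_len(d[1]), function(t) {
    fr <- matrix(mask[t, , ] != 0, d[2], d[3])
    frame_features(fr, open_brush, params$spur_prune_length)
  })
  tab <- do.call(rbind, rows)
  tab <- cbind(frame = seq_len(d[1]), tab)
  if (!is.null(frame_interval)) {
    tab$time_h <- (tab$frame - 1) * frame_interval / 60
    tab <- tab[, c("frame", "time_h", setdiff(names(tab), c("frame", "time_h")))]
  }
  if (!is.null(pixel_size)) {
    tab$area_um2 <- tab$area * pixel_size^2
    tab$invasive_area_um2 <- tab$invasive_area * pixel_size^2
    tab$invasive_radius_um <- tab$invasive_radius * pixel_size
  }
  structure(tab, class = c("spheroid_features", "data.frame"),
            params = params, pixel_size = pixel_size,
            frame_interval = frame_interval)
}

frame_features <- function(fr, open_brush, spur_prune_length) {
  A <- sum(fr)
  na_row <- data.frame(area = A, perimeter = NA_real_,
                       centroid_y = NA_real_, centroid_x = NA_real_,
                       invasive_radius = NA_real_, branch_count = NA_integer_,
                       core_area = NA_real_, invasive_area = NA_real_,
                       circularity = NA_real_)
  if (A == 0) return(na_row)

  px <- which(fr, arr.ind = TRUE)
  cy <- mean(px[, 1] - 1); cx <- mean(px[, 2] - 1)

  interior <- shift_mat(fr, -1, 0) & shift_mat(fr, 1, 0) &
    shift_mat(fr, 0, -1) & shift_mat(fr, 0, 1)
  bnd <- which(fr & !interior, arr.ind = TRUE)
  inv_radius <- sqrt(max((bnd[, 1] - 1 - cy)^2 + (bnd[, 2] - 1 - cx)^2))

  P <- chain_perimeter(fr)

  core_area <- if (is.null(open_brush)) A else sum(EBImage::opening(fr * 1, open_brush) > 0.5)
  branch_count <- count_skeleton_branches(skeletonize(fr), spur_prune_length)

  data.frame(area = A, perimeter = P, centroid_y = cy, centroid_x = cx,
             invasive_radius = inv_radius, branch_count = branch_count,
             core_area = core_area, invasive_area = A - core_area,
             circularity = if (is.finite(P) && P > 0) 4 * pi * A / P^2 else NA_real_)
}

#' Quantify invasion features directly from a 4D stack
#'
#' Convenience composition of the whole imaging pipeline:
#' [std_project()] then [smooth_series()] (with `params$gaussian_sigma`),
#' [segment_series()], [polish_masks()] and [compute_features()].
#'
#' @inheritParams compute_features
#' @param stack numeric `(T, Z, Y, X)` array (e.g. from
#'   [simulate_spheroid_stack()] or [read_stack_tiff()]).
#' @return a `spheroid_features` data frame (see [compute_features()]) with
#'   attributes `params` and `mask` (the polished mask series).
#' @export
feature_timecourse <- function(stack, params = segmentation_params(),
                               pixel_size = NULL, frame_interval = NULL) {
  if (is.null(pixel_size)) pixel_size <- attr(stack, "pixel_size")
  if (is.null(frame_interval)) frame_interval <- attr(stack, "frame_interval")
  proj <- std_project(stack)
  proj <- smooth_series(proj, params$gaussian_sigma)
  mask <- segment_series(proj, params)
  mask <- polish_masks(mask, params)
  feats <- compute_features(mask, params, pixel_size = pixel_size,
                            frame_interval = frame_interval)
  attr(feats, "mask") <- mask
  feats
}

# --- low-level binary-image helpers (matrix convention: row = y, col = x) ---

# result[y, x] = m[y + dy, x + dx], FALSE outside the image.
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ys <- seq_len(nr); xs <- seq_len(nc)
  oky <- ys + dy >= 1 & ys + dy <= nr
  okx <- xs + dx >= 1 & xs + dx <= nc
  out[ys[oky], xs[okx]] <- m[ys[oky] + dy, xs[okx] + dx]
  out
}

# 8-connected neighbour count of each pixel.
neighbour_count <- function(m) {
  n <- matrix(0L, nrow(m), ncol(m))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    n <- n + shift_mat(m, dy, dx)
  }
  n
}

# Morphological skeleton by Zhang-Suen thinning.
skeletonize <- function(m) {
  m <- m != 0
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north: P2..P9
      p2 <- shift_mat(m, -1, 0);  p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);   p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);   p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1);  p9 <- shift_mat(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (!seqs[[i]] & seqs[[i + 1]])
      if (step == 1) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Count skeleton endpoints whose branch extends at least `min_len` px
# before meeting a junction — i.e. endpoints that survive pruning of spurs
# shorter than `min_len`. Walks the 8-connected chain from each endpoint;
# thick diagonal corners (two mutually adjacent next pixels, a thinning
# artifact) are traversed by preferring the 4-adjacent continuation.
count_skeleton_branches <- function(skel, min_len) {
  nb <- neighbour_count(skel)
  ends <- which(skel & nb == 1)
  if (min_len <= 0 || length(ends) == 0) return(length(ends))
  dims <- dim(skel)
  n_long <- 0L
  for (e in ends) {
    cur <- arrayInd(e, dims)
    visited <- e
    len <- 0L
    repeat {
      if (len >= min_len) {
        n_long <- n_long + 1L
        break
      }
      cand <- chain_neighbours(skel, cur, dims)
      cand <- cand[!cand %in% visited]
      if (length(cand) == 0) break            # free chain ended: short spur
      if (length(cand) > 1) {
        ci <- arrayInd(cand, dims)
        mutually_adj <- all(outer(seq_along(cand), seq_along(cand),
          Vectorize(function(i, j)
            max(abs(ci[i, ] - ci[j, ])) <= 1)))
        if (!mutually_adj) break              # true junction
        # thick corner: continue along the 4-adjacent pixel if present
        d4 <- abs(ci[, 1] - cur[1]) + abs(ci[, 2] - cur[2])
        cand <- cand[order(d4)][1]
      }
      visited <- c(visited, cand)
      cur <- arrayInd(cand, dims)
      len <- len + 1L
    }
  }
  n_long
}

# linear indices of skeleton pixels 8-adjacent to `cur`
chain_neighbours <- function(skel, cur, dims) {
  ys <- cur[1] + (-1):1
  xs <- cur[2] + (-1):1
  ys <- ys[ys >= 1 & ys <= dims[1]]
  xs <- xs[xs >= 1 & xs <= dims[2]]
  idx <- as.vector(outer(ys, xs, function(y, x) (x - 1) * dims[1] + y))
  idx <- idx[idx != (cur[2] - 1) * dims[1] + cur[1]]
  idx[skel[idx]]
}

# Boundary-chain perimeter: ordered object contour (8-connected), steps of
# length 1 (axial) or sqrt(2) (diagonal), summed over all objects present.
chain_perimeter <- function(fr) {
  oc <- EBImage::ocontour(fr * 1)
  if (length(oc) == 0) return(NA_real_)
  per <- vapply(oc, function(pts) {
    if (nrow(pts) < 2) return(0)
    closed <- rbind(pts, pts[1, ])
    sum(sqrt(rowSums(diff(closed)^2)))
  }, numeric(1))
  sum(per)
}
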