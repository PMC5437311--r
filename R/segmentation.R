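# Binary segmentation of the projected series. The primary method is a
# two-label Markov-random-field graph cut over the 6-connected (t, y, x)
# lattice: unary terms from a two-class Gaussian intensity model initialized
# by a global bimodal (Otsu) threshold, and a contrast-sensitive Potts
# pairwise term, solved exactly by max-flow/min-cut. The plain global
# threshold is retained as a fast method and as an oracle: on
# well-separated bimodal images the two agree. The min-cut is computed by
# a compiled Dinic max-flow (src/maxflow.cpp).

#' Segmentation and feature-extraction parameters
#'
#' @param method `"graphcut"` (default) or `"threshold"`.
#' @param gaussian_sigma sigma of the pre-segmentation Gaussian smoothing,
#'   px (used by [feature_timecourse()]).
#' @param lambda weight of the pairwise (smoothness) term, >= 0.
#' @param beta contrast scale of the pairwise term
#'   `exp(-(Ii - Ij)^2 / (2 beta^2))`; `NULL` sets it to the root mean
#'   square neighbour difference of the image (self-scaling).
#' @param closing_radius disk radius for morphological closing during
#'   polishing, px.
#' @param core_opening_radius disk radius of the morphological opening that
#'   defines the spheroid core (thin branches are removed by the opening,
#'   so `area - core_area` measures the invasive outgrowth), px.
#' @param spur_prune_length skeleton spurs shorter than this are pruned
#'   before branch endpoints are counted, px.
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(method = c("graphcut", "threshold"),
                                gaussian_sigma = 1,
                                lambda = 1,
                                beta = NULL,
                                closing_radius = 2,
                                core_opening_radius = 8,
                                spur_prune_length = 3) {
  method <- match.arg(method)
  check_number(gaussian_sigma, "gaussian_sigma", min = 0)
  check_number(lambda, "lambda", min = 0)
  if (!is.null(beta)) check_number(beta, "beta", min = 0)
  check_number(closing_radius, "closing_radius", min = 0)
  check_number(core_opening_radius, "core_opening_radius", min = 0)
  check_number(spur_prune_length, "spur_prune_length", min = 0)
  structure(list(method = method, gaussian_sigma = gaussian_sigma,
                 lambda = lambda, beta = beta,
                 closing_radius = closing_radius,
                 core_opening_radius = core_opening_radius,
                 spur_prune_length = spur_prune_length),
            class = "segmentation_params")
}

#' Global bimodal threshold (Otsu with intermeans refinement)
#'
#' Histogram-based threshold maximizing the between-class variance,
#' refined by Ridler-Calvard intermeans iterations
#' (`thr <- (mean(below) + mean(above)) / 2` to convergence). The
#' refinement places the cut midway between the class means, so a blurred
#' step edge is cut at half-maximum regardless of how unbalanced the two
#' classes are.
#'
#' @param x numeric values.
#' @param nbins number of histogram bins.
#' @param refine apply the intermeans refinement (default `TRUE`).
#' @return the threshold, or `NA` when the values are constant (nothing to
#'   separate).
#' @export
otsu_threshold <- function(x, nbins = 256, refine = TRUE) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (!is.finite(diff(r)) || diff(r) <= 0) return(NA_real_)
  br <- seq(r[1], r[2], length.out = nbins + 1)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE,
                                        all.inside = TRUE), nbins))
  mid <- (br[-1] + br[-(nbins + 1)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mid)
  tw <- w[nbins]; tmu <- mu[nbins]
  between <- (tmu * w - tw * mu)^2 / (w * (tw - w))
  between[!is.finite(between)] <- -Inf
  thr <- mid[which.max(between)]
  if (refine) {
    for (i in 1:100) {
      lo <- x <= thr
      if (all(lo) || !any(lo)) break
      new <- (mean(x[lo]) + mean(x[!lo])) / 2
      if (abs(new - thr) < 1e-10 * max(abs(thr), 1)) break
      thr <- new
    }
  }
  thr
}

#' Segment a projected series into foreground/background
#'
#' @param series numeric array `(T, Y, X)`, typically smoothed output of
#'   [std_project()].
#' @param params a [segmentation_params()].
#' @return integer array `(T, Y, X)` of 0/1 labels, class `mask_series`,
#'   with attributes `method`, `params` and `warnings` (character vector;
#'   non-empty when the image was degenerate and an all-background mask was
#'   returned).
#' @export
segment_series <- function(series, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  d <- dim(series)
  if (length(d) != 3) stop("`series` must be a (T, Y, X) array", call. = FALSE)
  vals <- as.numeric(series)
  if (any(!is.finite(vals))) stop("`series` must be finite", call. = FALSE)
  warnings <- character(0)

  thr <- otsu_threshold(vals)
  degenerate <- is.na(thr) || all(vals > thr) || all(vals <= thr)
  if (degenerate) {
    warnings <- "degenerate (unimodal or constant) image: returning all-background mask"
    warning(warnings, call. = FALSE)
    mask <- array(0L, dim = d)
  } else if (params$method == "threshold") {
    mask <- array(as.integer(vals > thr), dim = d)
  } else {
    mask <- graphcut_segment(series, thr, params)
  }
  structure(mask, class = "mask_series", method = params$method,
            params = params, warnings = warnings,
            pixel_size = attr(series, "pixel_size"),
            frame_interval = attr(series, "frame_interval"))
}

# Exact binary MRF minimization by s-t min-cut on the 6-connected
# (t, y, x) lattice (igraph max_flow). Unary costs are negative Gaussian
# log-likelihoods of a two-class model fitted to the Otsu initialization;
# pairwise cost lambda * exp(-(Ii-Ij)^2 / (2 beta^2)) for unlike labels.
graphcut_segment <- function(series, thr, params) {
  d <- dim(series)
  vals <- as.numeric(series)
  N <- length(vals)
  init <- vals > thr

  mu0 <- mean(vals[!init]); mu1 <- mean(vals[init])
  # shared (pooled within-class) variance: the unary crossover then sits at
  # the class-mean midpoint, matching the bimodal threshold when the
  # smoothness term is unneeded
  floor_sd <- 1e-6 * max(diff(range(vals)), 1e-12)
  n0 <- sum(!init); n1 <- sum(init)
  sd_pool <- max(sqrt(((n0 - 1) * var(vals[!init]) +
                         (n1 - 1) * var(vals[init])) / (n0 + n1 - 2)),
                 floor_sd)
  d_bg <- -dnorm(vals, mu0, sd_pool, log = TRUE)
  d_fg <- -dnorm(vals, mu1, sd_pool, log = TRUE)
  base <- pmin(d_bg, d_fg)
  cap_max <- 1e4
  d_bg <- pmin(d_bg - base, cap_max)
  d_fg <- pmin(d_fg - base, cap_max)

  idx <- array(seq_len(N), dim = d)
  ep <- rbind(
    cbind(as.vector(idx[-d[1], , , drop = FALSE]), as.vector(idx[-1, , , drop = FALSE])),
    cbind(as.vector(idx[, -d[2], , drop = FALSE]), as.vector(idx[, -1, , drop = FALSE])),
    cbind(as.vector(idx[, , -d[3], drop = FALSE]), as.vector(idx[, , -1, drop = FALSE])))
  diff2 <- (vals[ep[, 1]] - vals[ep[, 2]])^2
  beta <- if (is.null(params$beta)) sqrt(mean(diff2)) else params$beta
  w <- if (beta > 0) params$lambda * exp(-diff2 / (2 * beta^2))
       else rep(params$lambda, nrow(ep))

  fg <- .maxflow_cut(N, ep[, 1], ep[, 2], w, d_bg, d_fg)
  mask <- array(0L, dim = d)
  mask[fg] <- 1L
  mask
}

#' Polish a segmented mask series
#'
#' Per frame: morphological closing (disk of radius `closing_radius`), hole
#' filling, then retention of a single connected component — the one with
#' the largest overlap with the component retained in the previous frame
#' (first frame: the largest component; ties broken by larger area, then by
#' smaller centroid distance to the image centre).
#'
#' @param mask a `mask_series` from [segment_series()] or any binary
#'   `(T, Y, X)` array.
#' @param params a [segmentation_params()].
#' @return polished `mask_series` with a `polish` attribute recording the
#'   closing radius and that holes were filled.
#' @export
polish_masks <- function(mask, params = segmentation_params()) {
  d <- dim(mask)
  if (length(d) != 3) stop("`mask` must be a (T, Y, X) array", call. = FALSE)
  if (!all(mask %in% c(0, 1))) stop("`mask` must be binary", call. = FALSE)
  out <- array(0L, dim = d)
  brush <- if (params$closing_radius > 0) {
    EBImage::makeBrush(2 * as.integer(params$closing_radius) + 1, "disc")
  } else NULL
  prev <- NULL
  cy <- (d[2] - 1) / 2; cx <- (d[3] - 1) / 2
  for (t in seq_len(d[1])) {
    fr <- matrix(as.numeric(mask[t, , ]), d[2], d[3])
    if (sum(fr) == 0) {
      warning(sprintf("frame %d is empty after segmentation", t), call. = FALSE)
      prev <- NULL
      next
    }
    if (!is.null(brush)) fr <- EBImage::closing(fr, brush)
    fr <- EBImage::fillHull(fr)
    lab <- EBImage::bwlabel(fr)
    keep <- select_component(lab, prev, cy, cx)
    fr2 <- (lab == keep) * 1L
    out[t, , ] <- fr2
    prev <- fr2
  }
  structure(out, class = "mask_series",
            method = attr(mask, "method"), params = params,
            warnings = attr(mask, "warnings"),
            pixel_size = attr(mask, "pixel_size"),
            frame_interval = attr(mask, "frame_interval"),
            polish = list(closing_radius = params$closing_radius,
                          holes_filled = TRUE))
}

# Pick the label to keep from a labelled frame. `prev` is the previous
# frame's retained binary component (or NULL).
select_component <- function(lab, prev, cy, cx) {
  nlab <- max(lab)
  if (nlab == 1) return(1L)
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  cand <- seq_len(nlab)
  if (!is.null(prev) && sum(prev) > 0) {
    ov <- tabulate(lab[prev == 1 & lab > 0], nbins = nlab)
    if (max(ov) > 0) cand <- which(ov == max(ov))
  }
  if (length(cand) > 1) cand <- cand[areas[cand] == max(areas[cand])]
  if (length(cand) > 1) {
    # remaining ties: component centroid closest to the image centre
    dists <- vapply(cand, function(l) {
      px <- which(lab == l, arr.ind = TRUE)
      sqrt((mean(px[, 1] - 1) - cy)^2 + (mean(px[, 2] - 1) - cx)^2)
    }, numeric(1))
    cand <- cand[which.min(dists)]
  }
  cand[1]
}
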