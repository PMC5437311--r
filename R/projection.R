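# Standard-deviation z-projection and Gaussian smoothing of the projected
# (t, y, x) series. The projection converts a 4D stack to a 3D series in
# which columns with z-structure (cells, which span several focal planes
# with varying intensity) stand out against flat background, enhancing the
# contrast of dim invasive branches.

#' Standard-deviation projection along z
#'
#' For every frame and every (y, x) position, computes the sample standard
#' deviation (divisor `n - 1`) of the intensities across all z-planes.
#'
#' @param stack numeric array `(T, Z, Y, X)`; `pixel_size` and
#'   `frame_interval` attributes, if present, are propagated.
#' @return numeric array `(T, Y, X)` of class `projected_series` with a
#'   `provenance` attribute recording the projection.
#' @examples
#' st <- array(0, c(1, 4, 2, 2)); st[1, , 1, 1] <- c(0, 2, 0, 2)
#' std_project(st)[1, 1, 1]  # sqrt(4/3)
#' @export
std_project <- function(stack) {
  d <- dim(stack)
  if (length(d) != 4) stop("`stack` must be a (T, Z, Y, X) array", call. = FALSE)
  Z <- d[2]
  if (Z < 2) {
    stop("std_project needs >= 2 z-planes; for single-plane data skip the projection",
         call. = FALSE)
  }
  m <- aperm(stack, c(2, 1, 3, 4))
  dim(m) <- c(Z, prod(d[-2]))
  mu <- colMeans(m)
  ss <- colSums(m^2) - Z * mu^2
  out <- sqrt(pmax(ss, 0) / (Z - 1))
  dim(out) <- d[-2]
  structure(out, class = "projected_series",
            pixel_size = attr(stack, "pixel_size"),
            frame_interval = attr(stack, "frame_interval"),
            provenance = list(projection = "z-std", divisor = "n-1", n_z = Z))
}

#' Isotropic 3D Gaussian smoothing of a projected series
#'
#' Separable Gaussian filtering over the (t, y, x) axes with replicate
#' boundary padding; `sigma = 0` returns the input unchanged. The kernel
#' half-width is `ceiling(3 * sigma)`.
#'
#' @param series numeric array `(T, Y, X)` (e.g. from [std_project()]).
#' @param sigma Gaussian standard deviation in px (and frames along t).
#' @return smoothed array with the same dimensions and attributes.
#' @export
smooth_series <- function(series, sigma = 1) {
  check_number(sigma, "sigma", min = 0)
  if (length(dim(series)) != 3) {
    stop("`series` must be a (T, Y, X) array", call. = FALSE)
  }
  if (sigma == 0) return(series)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  kern <- dnorm(seq(-h, h), sd = sigma)
  kern <- kern / sum(kern)
  out <- unclass(series)
  for (axis in 1:3) {
    if (dim(out)[axis] > 1) out <- conv1_axis(out, axis, kern)
  }
  attributes(out) <- attributes(series)
  prov <- attr(out, "provenance")
  attr(out, "provenance") <- c(prov, list(smooth_sigma = sigma))
  out
}

# 1D convolution of a 3D array along `axis` with replicate padding.
conv1_axis <- function(a, axis, kern) {
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(a, perm)
  dm <- dim(m)
  dim(m) <- c(dm[1], prod(dm[-1]))
  n <- dm[1]
  h <- (length(kern) - 1L) / 2L
  out <- matrix(0, n, ncol(m))
  for (k in -h:h) {
    rows <- pmin(pmax(seq_len(n) + k, 1L), n)
    out <- out + kern[k + h + 1L] * m[rows, , drop = FALSE]
  }
  dim(out) <- dm
  aperm(out, order(perm))
}
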