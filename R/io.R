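# Readers/writers for the on-disk interchange formats: multi-page TIFF for
# image stacks and masks (axes recorded in the page description), CSV for
# tracks, truth tables and features, TSV for expression matrices.

#' Write a (T, Z, Y, X) stack or (T, Y, X) series as multi-page TIFF
#'
#' Pages are ordered t-major (z fastest within a frame for 4D input).
#' Intensities are rescaled to `[0, 1]` for storage; the original range,
#' the axes layout and any calibration are recorded in a YAML sidecar
#' (`<path>.yaml`) so that [read_stack_tiff()] restores the array exactly
#' (up to 32-bit float precision).
#'
#' @param stack numeric array with 3 (`t,y,x`) or 4 (`t,z,y,x`) dimensions.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack)
  stopifnot(length(d) %in% c(3, 4))
  axes <- if (length(d) == 4) "tzyx" else "tyx"
  rng <- range(stack)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  meta <- list(format = "sagakit-stack", axes = axes, dims = as.integer(d),
               min = rng[1], scale = scale,
               pixel_size = attr(stack, "pixel_size"),
               frame_interval = attr(stack, "frame_interval"))
  pages <- list()
  if (length(d) == 4) {
    for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
      pages[[length(pages) + 1]] <-
        (matrix(stack[t, z, , ], d[3], d[4]) - rng[1]) / scale
    }
  } else {
    for (t in seq_len(d[1])) {
      pages[[length(pages) + 1]] <-
        (matrix(stack[t, , ], d[2], d[3]) - rng[1]) / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path TIFF file (its `<path>.yaml` sidecar must be present).
#' @return numeric array `(T, Z, Y, X)` or `(T, Y, X)` with `pixel_size` /
#'   `frame_interval` attributes restored when present.
#' @export
read_stack_tiff <- function(path) {
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar)) {
    stop("missing stack metadata sidecar: ", sidecar, call. = FALSE)
  }
  meta <- yaml::read_yaml(sidecar)
  if (!identical(meta$format, "sagakit-stack")) {
    stop("not a stack TIFF written by write_stack_tiff", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(unlist(meta$dims))
  mn <- as.numeric(meta$min); sc <- as.numeric(meta$scale)
  arr <- array(NA_real_, dim = d)
  if (length(d) == 4) {
    k <- 0
    for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
      k <- k + 1
      arr[t, z, , ] <- pages[[k]] * sc + mn
    }
  } else {
    for (t in seq_len(d[1])) arr[t, , ] <- pages[[t]] * sc + mn
  }
  for (a in c("pixel_size", "frame_interval")) {
    if (!is.null(meta[[a]])) attr(arr, a) <- as.numeric(meta[[a]])
  }
  arr
}

#' Write/read a track table
#'
#' Tracks are stored as CSV with columns `track_id, frame, x, y` (px,
#' 0-based coordinates, `x` = column, `y` = row). `write_tracks_csv()`
#' optionally echoes the simulation spec to a YAML sidecar
#' (`<path>.yaml`).
#'
#' @param tracks a track data frame (e.g. from [simulate_tracks()]).
#' @param path CSV file.
#' @param spec optional simulation spec to echo into the sidecar.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path, spec = NULL) {
  write.csv(tracks[, c("track_id", "frame", "x", "y")], path,
            row.names = FALSE)
  if (!is.null(spec)) {
    yaml::write_yaml(unclass(spec), paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname write_tracks_csv
#' @param frame_interval minutes per frame to attach to the read table.
#' @export
read_tracks_csv <- function(path, frame_interval = NULL) {
  tr <- read.csv(path)
  attr(tr, "frame_interval") <- frame_interval
  tr
}

#' Write/read an expression matrix as TSV
#'
#' First column `gene_id`, then one column per sample.
#'
#' @param mat numeric gene x sample matrix with dimnames.
#' @param path TSV file.
#' @return `path` (writer, invisibly) or the matrix (reader).
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
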