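#' Multi-view rendering configuration
#'
#' A blob is rendered as three co-registered square binary rasters: its
#' orthogonal projections onto the xy, yz, and xz planes. The raster must be
#' large enough for the dataset's maximum blob extent
#' (`image_size_px * pixel_size_nm`); the study default is 512 px at 1 nm.
#'
#' @param image_size_px square raster side in pixels.
#' @param pixel_size_nm physical subdivision unit.
#' @param binary if `TRUE` (default, the standard encoding) occupied pixels
#'   are 1; if `FALSE` pixels count the points they contain.
#' @return an object of class `multiview_config`.
#' @export
multiview_config <- function(image_size_px = 512L, pixel_size_nm = 1,
                             binary = TRUE) {
  if (image_size_px < 1 || pixel_size_nm <= 0)
    abort("image_size_px and pixel_size_nm must be positive")
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_nm = pixel_size_nm, binary = binary),
            class = "multiview_config")
}

# internal: map coordinates of one axis to raster indices, blob centroid at
# the raster center; half-open pixel intervals via floor()
axis_to_pixel <- function(coord, center, config) {
  as.integer(floor((coord - center) / config$pixel_size_nm +
                     config$image_size_px / 2)) + 1L
}

#' Project a blob onto its three orthogonal views
#'
#' The blob centroid maps to the raster center (rendering is therefore
#' translation-invariant); each point sets the pixel containing its projected
#' coordinates to 1 (or increments it in count mode). Views are `xy`, `yz`,
#' and `xz`; in each view the first named axis indexes rows.
#'
#' @param b a [blob()].
#' @param config a [multiview_config()].
#' @return object of class `cav_multiview`: list with `xy`, `yz`, `xz`
#'   matrices and `blob_id`.
#' @export
project_blob <- function(b, config = multiview_config()) {
  ctr <- colMeans(b$points)
  px <- vapply(1:3, function(a) axis_to_pixel(b$points[, a], ctr[a], config),
               integer(molecule_count(b)))
  px <- matrix(px, ncol = 3)
  if (any(px < 1 | px > config$image_size_px))
    abort(sprintf(
      "blob %s exceeds the %d px raster (ranges %.0f x %.0f x %.0f nm)",
      b$blob_id, config$image_size_px,
      diff(range(b$points[, 1])), diff(range(b$points[, 2])),
      diff(range(b$points[, 3]))))
  render <- function(a1, a2) {
    m <- matrix(0, config$image_size_px, config$image_size_px)
    idx <- px[, c(a1, a2), drop = FALSE]
    if (config$binary) m[idx] <- 1
    else for (r in seq_len(nrow(idx))) m[idx[r, 1], idx[r, 2]] <-
        m[idx[r, 1], idx[r, 2]] + 1
    m
  }
  structure(list(xy = render(1, 2), yz = render(2, 3), xz = render(1, 3),
                 blob_id = b$blob_id),
            class = "cav_multiview")
}

#' @export
print.cav_multiview <- function(x, ...) {
  cat(sprintf("<cav_multiview %s> %d px, nonzero xy/yz/xz: %d/%d/%d\n",
              x$blob_id, nrow(x$xy), sum(x$xy != 0), sum(x$yz != 0),
              sum(x$xz != 0)))
  invisible(x)
}

#' Sparsity ratio of a raster or grid
#'
#' Fraction of nonzero cells: with 512 occupied pixels on a 512 x 512 raster
#' this is 2^9 / 2^18, about 0.2%, and it collapses to 2^9 / 2^27 for the
#' equivalent voxel grid — the arithmetic behind rejecting a full 3D voxel
#' representation.
#'
#' @param x either a numeric array/matrix (counts its nonzero cells) or the
#'   number of nonzero cells.
#' @param total_cells total cell count; required when `x` is a count.
#' @return fraction of nonzero cells.
#' @export
sparsity_ratio <- function(x, total_cells = NULL) {
  if (is.null(total_cells)) {
    if (!is.array(x) && !is.matrix(x)) abort("total_cells required for a scalar count")
    return(sum(x != 0) / length(x))
  }
  if (total_cells <= 0) abort("total_cells must be positive")
  x / total_cells
}

#' Render a blob set as a multi-view image stack
#'
#' @param bs a `cav_blob_set`.
#' @param config a [multiview_config()].
#' @return array of dim `(image_size_px, image_size_px, 3, n_blobs)` with the
#'   three views as channels (xy, yz, xz), plus dimnames on the blob axis.
#' @export
render_multiview_dataset <- function(bs, config = multiview_config()) {
  s <- config$image_size_px
  out <- array(0, c(s, s, 3, length(bs)),
               dimnames = list(NULL, NULL, c("xy", "yz", "xz"), names(bs)))
  for (i in seq_along(bs)) {
    mv <- project_blob(bs[[i]], config)
    out[, , 1, i] <- mv$xy
    out[, , 2, i] <- mv$yz
    out[, , 3, i] <- mv$xz
  }
  out
}

#' Write the three views of a blob as PNG files
#'
#' @param mv a `cav_multiview`.
#' @param dir output directory; files are named `<blob_id>_<view>.png`.
#' @return the three paths, invisibly.
#' @export
write_multiview <- function(mv, dir) {
  paths <- vapply(c("xy", "yz", "xz"), function(v) {
    p <- file.path(dir, sprintf("%s_%s.png", mv$blob_id, v))
    png::writePNG(pmin(mv[[v]], 1), p)
    p
  }, character(1))
  invisible(paths)
}
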