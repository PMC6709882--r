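#' Read an SMLM eventlist
#'
#' Eventlists are delimited-text localization tables (one row per detected
#' molecule). Vendor dialects differ, so the caller supplies a column map.
#' All coordinates are converted to nm on ingestion; nothing downstream
#' converts units.
#'
#' If a sidecar manifest (`<path>.manifest.yaml`, as written by
#' [write_eventlist()]) is present, the declared row count is checked so that
#' silently truncated files are rejected.
#'
#' @param path delimited text file with a header row.
#' @param column_map named character vector mapping internal names
#'   (`x`, `y`, `z`, optionally `cell_id`) to file column names.
#' @param units `"nm"` or `"pixels"`; pixel input is scaled by
#'   `xy_pixel_nm` in XY and `z_pixel_nm` in Z (camera calibration of the
#'   acquisition: 20 nm XY, 25 nm Z).
#' @param sep field separator.
#' @param xy_pixel_nm,z_pixel_nm pixel pitch used when `units = "pixels"`.
#' @return data frame of localizations: `x`, `y`, `z` (nm), `cell_id`,
#'   `source_row`.
#' @export
read_eventlist <- function(path,
                           column_map = c(x = "x", y = "y", z = "z"),
                           units = c("nm", "pixels"),
                           sep = ",", xy_pixel_nm = 20, z_pixel_nm = 25) {
  units <- match.arg(units)
  if (!file.exists(path)) abort("eventlist not found: ", path)
  df <- read.csv(path, sep = sep, check.names = FALSE)
  if (nrow(df) == 0) abort("empty eventlist: ", path)
  need <- column_map[c("x", "y", "z")]
  if (any(is.na(need)) || !all(need %in% names(df)))
    abort("eventlist is missing mapped coordinate columns: ",
          paste(setdiff(need, names(df)), collapse = ", "))
  out <- data.frame(
    x = as.numeric(df[[need["x"]]]),
    y = as.numeric(df[[need["y"]]]),
    z = as.numeric(df[[need["z"]]])
  )
  if (any(!is.finite(as.matrix(out))))
    abort("non-numeric or non-finite coordinates in eventlist: ", path)
  if (units == "pixels") {
    out$x <- out$x * xy_pixel_nm
    out$y <- out$y * xy_pixel_nm
    out$z <- out$z * z_pixel_nm
  }
  out$cell_id <- if (!is.na(column_map["cell_id"]) && "cell_id" %in% names(column_map))
    as.character(df[[column_map["cell_id"]]]) else NA_character_
  out$source_row <- seq_len(nrow(df))
  manifest_path <- paste0(path, ".manifest.yaml")
  if (file.exists(manifest_path)) {
    man <- yaml::read_yaml(manifest_path)
    if (!is.null(man$n_rows) && man$n_rows != nrow(out))
      abort(sprintf("eventlist %s has %d rows but manifest declares %d (truncated file?)",
                    path, nrow(out), man$n_rows))
  }
  out
}

#' Write an SMLM eventlist with its manifest
#'
#' @param locs data frame with columns `x`, `y`, `z` (nm) and optionally
#'   `cell_id`.
#' @param path output CSV path; a `<path>.manifest.yaml` sidecar records the
#'   row count and units.
#' @return `path`, invisibly.
#' @export
write_eventlist <- function(locs, path) {
  cols <- intersect(c("x", "y", "z", "cell_id"), names(locs))
  write.csv(locs[, cols, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(n_rows = nrow(locs), units = "nm"), paste0(path, ".manifest.yaml"))
  invisible(path)
}

#' Construct a calibrated binary mask image
#'
#' Pixel `[i, j]` (1-based) covers the half-open nm rectangle
#' `x in [origin_x + (j-1) s, origin_x + j s)`,
#' `y in [origin_y + (i-1) s, origin_y + i s)` with `s = pixel_size_nm`:
#' rows index y, columns index x, axis-aligned with the SMLM frame.
#'
#' @param pixels numeric/logical matrix; nonzero entries become 1.
#' @param pixel_size_nm physical pixel size (> 0).
#' @param origin length-2 nm offset `c(x, y)` of pixel (1,1)'s corner.
#' @return an object of class `cav_mask`.
#' @export
mask_image <- function(pixels, pixel_size_nm, origin = c(0, 0)) {
  if (pixel_size_nm <= 0) abort("pixel_size_nm must be > 0")
  pixels <- (as.matrix(pixels) != 0) * 1L
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 origin = as.numeric(origin)),
            class = "cav_mask")
}

#' @export
print.cav_mask <- function(x, ...) {
  cat(sprintf("<cav_mask> %d x %d px, %g nm/px, %d positive px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm, sum(x$pixels)))
  invisible(x)
}

#' Read a PTRF/CAVIN1 mask raster
#'
#' Reads a TIFF or PNG raster, binarizes it (any nonzero value is mask
#' positive) and attaches the physical calibration. Multi-channel images use
#' the first channel.
#'
#' @param path raster path (`.tif`, `.tiff` or `.png`).
#' @param pixel_size_nm physical pixel size in nm (wide-field preview pixels).
#' @param origin nm position of the first pixel corner, `c(x, y)`.
#' @return a [mask_image()].
#' @export
read_mask <- function(path, pixel_size_nm, origin = c(0, 0)) {
  if (!file.exists(path)) abort("mask not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "png" = png::readPNG(path),
    "tif" = ,
    "tiff" = tiff::readTIFF(path),
    abort("unsupported mask format: .", ext)
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- mask_image(img, pixel_size_nm, origin)
  if (sum(m$pixels) == 0) warning("mask has zero positive area: ", path)
  m
}

#' Write a mask raster to PNG
#'
#' @param mask a [mask_image()].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask$pixels * 1.0, path)
  invisible(path)
}

#' Morphological closing of a binary mask
#'
#' Binary dilation followed by erosion with a disc structuring element,
#' closing holes smaller than the element (used to consolidate the wide-field
#' PTRF mask before labeling).
#'
#' @param mask a [mask_image()].
#' @param radius_px disc radius in pixels (>= 1); the element is the
#'   discretized disc of diameter `2 * radius_px + 1`.
#' @return the closed [mask_image()], same calibration.
#' @export
morphological_close <- function(mask, radius_px = 1L) {
  if (radius_px < 1) abort("radius_px must be >= 1")
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  closed <- EBImage::erode(EBImage::dilate(mask$pixels, brush), brush)
  mask_image(closed, mask$pixel_size_nm, mask$origin)
}

#' Write / read a blob set
#'
#' Serializes a blob set losslessly as two CSV tables (long-format points and
#' per-blob annotations) plus a YAML manifest declaring row counts; the
#' reader validates the counts so truncated files are rejected. Missing
#' annotations round-trip as explicit `NA`.
#'
#' @param bs a `cav_blob_set`.
#' @param prefix path prefix; files `<prefix>.points.csv`,
#'   `<prefix>.annotations.csv`, `<prefix>.manifest.yaml` are written.
#' @return `prefix`, invisibly.
#' @export
write_blobs <- function(bs, prefix) {
  tabs <- blobs_to_tables(bs)
  write.csv(tabs$points, paste0(prefix, ".points.csv"), row.names = FALSE, quote = FALSE)
  write.csv(tabs$annotations, paste0(prefix, ".annotations.csv"), row.names = FALSE, quote = FALSE)
  yaml::write_yaml(
    list(n_blobs = length(bs), n_points = nrow(tabs$points), units = "nm"),
    paste0(prefix, ".manifest.yaml")
  )
  invisible(prefix)
}

#' @rdname write_blobs
#' @export
read_blobs <- function(prefix) {
  pfile <- paste0(prefix, ".points.csv")
  afile <- paste0(prefix, ".annotations.csv")
  mfile <- paste0(prefix, ".manifest.yaml")
  for (f in c(pfile, afile, mfile)) if (!file.exists(f)) abort("missing file: ", f)
  points <- read.csv(pfile, colClasses = c(blob_id = "character"))
  ann <- read.csv(afile, colClasses = c(
    blob_id = "character", cell_id = "character",
    ptrf_status = "character", class = "character"
  ))
  man <- yaml::read_yaml(mfile)
  if (man$n_points != nrow(points) || man$n_blobs != nrow(ann))
    abort("blob tables at ", prefix, " do not match their manifest (truncated file?)")
  blobs_from_tables(points, ann)
}
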