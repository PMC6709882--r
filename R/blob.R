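#' Construct a blob
#'
#' A blob is one segmented cellular structure: an ordered set of N 3D
#' localizations (nm) plus identifiers and optional annotation. Annotation
#' fields are `NA` until the corresponding pipeline stage assigns them:
#' `ptrf_status` after mask labeling, `class` after stratification.
#'
#' @param blob_id scalar identifier (coerced to character).
#' @param points numeric N x 3 matrix of coordinates in nm (columns x, y, z).
#' @param cell_id scalar cell identifier, `NA` for cell-free data.
#' @param ptrf_status `"PTRF+"`, `"PTRF-"` or `NA`.
#' @param class `"positive"`, `"negative"` or `NA`. Positives are caveolae
#'   (or, for simulated data, the isotropic class).
#' @return an object of class `cav_blob`.
#' @export
blob <- function(blob_id, points, cell_id = NA_character_,
                 ptrf_status = NA_character_, class = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 1 || !is.numeric(points))
    abort("'points' must be a numeric N x 3 matrix with N >= 1")
  if (any(!is.finite(points))) abort("blob points must be finite")
  colnames(points) <- c("x", "y", "z")
  if (!is.na(ptrf_status) && !ptrf_status %in% c("PTRF+", "PTRF-"))
    abort("ptrf_status must be 'PTRF+', 'PTRF-' or NA")
  if (!is.na(class) && !class %in% c("positive", "negative"))
    abort("class must be 'positive', 'negative' or NA")
  structure(
    list(blob_id = as.character(blob_id), cell_id = as.character(cell_id),
         points = points, ptrf_status = ptrf_status, class = class),
    class = "cav_blob"
  )
}

#' Number of molecules (points) in a blob
#' @param b a `cav_blob`.
#' @return integer point count.
#' @export
molecule_count <- function(b) nrow(b$points)

#' @export
print.cav_blob <- function(x, ...) {
  cat(sprintf("<cav_blob %s> cell=%s N=%d ptrf=%s class=%s\n",
              x$blob_id, x$cell_id, molecule_count(x),
              x$ptrf_status, x$class))
  invisible(x)
}

#' Construct a blob set
#'
#' @param blobs list of [blob()] objects with unique ids.
#' @return an object of class `cav_blob_set` (a list of blobs, indexable by
#'   blob_id).
#' @export
blob_set <- function(blobs) {
  if (!all(vapply(blobs, inherits, logical(1), "cav_blob")))
    abort("all elements must be cav_blob objects")
  ids <- vapply(blobs, `[[`, character(1), "blob_id")
  if (anyDuplicated(ids)) abort("duplicate blob_id in blob set")
  names(blobs) <- ids
  structure(blobs, class = "cav_blob_set")
}

#' @export
print.cav_blob_set <- function(x, ...) {
  n <- vapply(x, molecule_count, integer(1))
  cl <- vapply(x, `[[`, character(1), "class")
  cat(sprintf("<cav_blob_set> %d blobs, %s points (N: %s-%s), classes: %s\n",
              length(x), format(sum(n), big.mark = ","), min(n), max(n),
              paste(names(table(cl, useNA = "ifany")), table(cl, useNA = "ifany"),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' @export
`[.cav_blob_set` <- function(x, i) {
  structure(NextMethod(), class = "cav_blob_set")
}

# internal: vectorized annotation access
blob_field <- function(bs, field) vapply(bs, `[[`, character(1), field)
blob_counts <- function(bs) vapply(bs, molecule_count, integer(1))

#' Convert a blob set to long-format tables
#'
#' @param bs a `cav_blob_set`.
#' @return list with `points` (one row per localization: blob_id, x_nm, y_nm,
#'   z_nm) and `annotations` (one row per blob: blob_id, cell_id, ptrf_status,
#'   class, molecule_count).
#' @export
blobs_to_tables <- function(bs) {
  n <- blob_counts(bs)
  pts <- do.call(rbind, lapply(bs, `[[`, "points"))
  points <- data.frame(
    blob_id = rep(names(bs), n),
    x_nm = pts[, 1], y_nm = pts[, 2], z_nm = pts[, 3],
    row.names = NULL
  )
  annotations <- data.frame(
    blob_id = names(bs),
    cell_id = blob_field(bs, "cell_id"),
    ptrf_status = blob_field(bs, "ptrf_status"),
    class = blob_field(bs, "class"),
    molecule_count = n,
    row.names = NULL
  )
  list(points = points, annotations = annotations)
}

#' Rebuild a blob set from long-format tables
#'
#' @param points data frame with blob_id, x_nm, y_nm, z_nm (row order defines
#'   point order within each blob).
#' @param annotations data frame with blob_id, cell_id, ptrf_status, class.
#' @return a `cav_blob_set`.
#' @export
blobs_from_tables <- function(points, annotations) {
  need <- c("blob_id", "x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(points))) abort("points table missing columns")
  if (!"blob_id" %in% names(annotations)) abort("annotations table missing blob_id")
  split_idx <- split(seq_len(nrow(points)), points$blob_id)
  # preserve annotation row order as the blob order
  ids <- as.character(annotations$blob_id)
  blobs <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    rows <- split_idx[[id]]
    if (is.null(rows)) abort("annotation for blob without points: ", id)
    blob(id,
         cbind(points$x_nm[rows], points$y_nm[rows], points$z_nm[rows]),
         cell_id = as.character(annotations$cell_id[i]),
         ptrf_status = as.character(annotations$ptrf_status[i]),
         class = as.character(annotations$class[i]))
  })
  blob_set(blobs)
}
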