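#' Pre-processing configuration
#'
#' Bundles the stage parameters used by [run_preprocess()]. Defaults: 20 nm
#' merge radius (multi-blink reconstruction), 80 nm segmentation radius
#' (above the merge radius, far below inter-blob spacing at observed
#' densities), a local-density noise filter at 50 nm with a 2-sigma Poisson
#' margin, inclusive 0.5 mask-overlap threshold, and the 60-molecule caveola
#' cutoff.
#'
#' @param merge_radius_nm iterative-merge radius.
#' @param segmentation_radius_nm blob segmentation (connected-component)
#'   radius.
#' @param noise_neighbor_radius_nm,noise_k local-density filter: a point is
#'   kept when its neighbor count within the radius exceeds the expected
#'   complete-spatial-randomness count by more than `noise_k` Poisson
#'   standard deviations.
#' @param mask_overlap_threshold fraction of a blob's points that must fall
#'   inside the mask for a PTRF+ label (boundary inclusive).
#' @param caveolae_min_molecules minimum molecules for a PTRF+ blob to be
#'   called a caveola.
#' @param balance_seed seed for majority-class downsampling.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(merge_radius_nm = 20,
                              segmentation_radius_nm = 80,
                              noise_neighbor_radius_nm = 50,
                              noise_k = 2,
                              mask_overlap_threshold = 0.5,
                              caveolae_min_molecules = 60L,
                              balance_seed = 1L) {
  if (merge_radius_nm <= 0 || segmentation_radius_nm <= 0 ||
      noise_neighbor_radius_nm <= 0)
    abort("all radii must be > 0")
  if (mask_overlap_threshold <= 0 || mask_overlap_threshold > 1)
    abort("mask_overlap_threshold must be in (0, 1]")
  if (caveolae_min_molecules < 1) abort("caveolae_min_molecules must be >= 1")
  structure(as.list(environment()), class = "preprocess_config")
}

# internal: connected components of the <= radius adjacency relation;
# returns an integer component label per point
radius_components <- function(pts, radius) {
  n <- nrow(pts)
  if (n == 1) return(1L)
  d <- as.matrix(stats::dist(pts))
  adj <- d <= radius
  diag(adj) <- FALSE
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership
}

#' Iteratively merge localizations
#'
#' Multiple blinking of one fluorophore scatters several localizations around
#' each true molecule. The reconstruction groups all localizations within the
#' merge radius (connected components of the adjacency relation, so the rule
#' is order-independent), replaces each group by its centroid, and repeats
#' until every pairwise distance exceeds the radius.
#'
#' Localizations from different `cell_id`s are never merged. Long chains of
#' points spaced just under the radius collapse to a single centroid; this is
#' a property of the stated rule, not special-cased.
#'
#' @param locs localization data frame (`x`, `y`, `z`, `cell_id`,
#'   `source_row`).
#' @param merge_radius_nm merge radius in nm.
#' @return merged localizations; `source_row` of a merged point is the
#'   minimum source row of its group.
#' @export
merge_localizations <- function(locs, merge_radius_nm = 20) {
  if (merge_radius_nm <= 0) abort("merge_radius_nm must be > 0")
  if (nrow(locs) == 0) return(locs)
  merge_group <- function(g) {
    repeat {
      pts <- as.matrix(g[, c("x", "y", "z")])
      comp <- radius_components(pts, merge_radius_nm)
      if (max(comp) == nrow(g)) return(g) # all singletons: fixpoint
      g <- data.frame(
        x = as.numeric(tapply(g$x, comp, mean)),
        y = as.numeric(tapply(g$y, comp, mean)),
        z = as.numeric(tapply(g$z, comp, mean)),
        cell_id = g$cell_id[1],
        source_row = as.integer(tapply(g$source_row, comp, min))
      )
    }
  }
  out <- do.call(rbind, lapply(split(locs, locs$cell_id, drop = TRUE), merge_group))
  rownames(out) <- NULL
  out[order(out$cell_id, out$source_row), , drop = FALSE]
}

#' Filter unclustered background localizations
#'
#' Density-based stand-in for a network-versus-random-network comparison: a
#' point is retained iff its neighbor count within `neighbor_radius_nm`
#' exceeds the count expected under complete spatial randomness (CSR) at the
#' dataset's global density by more than `k` Poisson standard deviations.
#' Clustered molecules vastly exceed the CSR expectation; diffuse background
#' does not. Density is estimated per cell from the bounding-box volume.
#'
#' @param locs localization data frame.
#' @param neighbor_radius_nm neighborhood radius.
#' @param k significance multiplier (Poisson standard deviations).
#' @return retained localizations.
#' @export
filter_noise <- function(locs, neighbor_radius_nm = 50, k = 2) {
  if (neighbor_radius_nm <= 0) abort("neighbor_radius_nm must be > 0")
  if (nrow(locs) < 2) {
    warning("fewer than 2 localizations; noise filter skipped")
    return(locs)
  }
  filter_group <- function(g) {
    if (nrow(g) < 2) return(g)
    pts <- as.matrix(g[, c("x", "y", "z")])
    vol <- prod(apply(pts, 2, function(v) diff(range(v))))
    if (vol == 0) {
      warning("degenerate (flat) point cloud; noise filter skipped for cell ",
              g$cell_id[1])
      return(g)
    }
    d <- as.matrix(stats::dist(pts))
    counts <- rowSums(d <= neighbor_radius_nm) - 1L
    lambda <- nrow(g) / vol * (4 / 3) * pi * neighbor_radius_nm^3
    g[counts > lambda + k * sqrt(lambda), , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(locs, locs$cell_id, drop = TRUE), filter_group))
  rownames(out) <- NULL
  out
}

#' Segment localizations into blobs
#'
#' Blobs are the connected components of the `<= radius` adjacency graph,
#' computed per cell. Every localization is assigned to exactly one blob.
#' Blob ids are deterministic: components are numbered by the minimum
#' `source_row` they contain.
#'
#' @param locs localization data frame.
#' @param segmentation_radius_nm linking radius in nm.
#' @return a `cav_blob_set`; ids are `<cell_id>_b<k>`.
#' @export
segment_blobs <- function(locs, segmentation_radius_nm = 80) {
  if (segmentation_radius_nm <= 0) abort("segmentation_radius_nm must be > 0")
  if (nrow(locs) == 0) return(blob_set(list()))
  blobs <- list()
  for (g in split(locs, locs$cell_id, drop = TRUE)) {
    pts <- as.matrix(g[, c("x", "y", "z")])
    comp <- radius_components(pts, segmentation_radius_nm)
    first_row <- tapply(g$source_row, comp, min)
    order_of <- rank(first_row) # component -> deterministic blob number
    for (ci in sort(unique(comp))) {
      sel <- comp == ci
      id <- sprintf("%s_b%04d", g$cell_id[1], order_of[as.character(ci)])
      blobs[[id]] <- blob(id, pts[sel, , drop = FALSE], cell_id = g$cell_id[1])
    }
  }
  blob_set(blobs[order(names(blobs))])
}

#' Label blobs with the PTRF/CAVIN1 mask
#'
#' A blob is PTRF+ iff at least `overlap_threshold` of its points project
#' (in XY) into positive mask pixels; the boundary is inclusive. Points
#' outside the raster extent count as outside the mask; a blob entirely
#' outside the raster is labeled PTRF- with a warning.
#'
#' @param bs a `cav_blob_set`.
#' @param mask a [mask_image()]; `NULL` declares the cell mask-free (a PTRF
#'   absent cell), labeling every blob PTRF-.
#' @param overlap_threshold required in-mask point fraction.
#' @return the blob set with `ptrf_status` assigned.
#' @export
label_with_mask <- function(bs, mask, overlap_threshold = 0.5) {
  if (is.null(mask)) {
    return(blob_set(lapply(bs, function(b) { b$ptrf_status <- "PTRF-"; b })))
  }
  px <- mask$pixels
  s <- mask$pixel_size_nm
  labeled <- lapply(bs, function(b) {
    j <- floor((b$points[, 1] - mask$origin[1]) / s) + 1 # x -> column
    i <- floor((b$points[, 2] - mask$origin[2]) / s) + 1 # y -> row
    inside <- i >= 1 & i <= nrow(px) & j >= 1 & j <= ncol(px)
    if (!any(inside))
      warning("blob ", b$blob_id, " lies entirely outside the mask raster")
    hit <- logical(length(i))
    hit[inside] <- px[cbind(i[inside], j[inside])] == 1
    b$ptrf_status <- if (mean(hit) >= overlap_threshold) "PTRF+" else "PTRF-"
    b
  })
  blob_set(labeled)
}

#' Stratify labeled blobs into caveolae and non-caveolae
#'
#' A blob is a caveola (class `"positive"`) iff it is PTRF+ and has at least
#' `caveolae_min_molecules` molecules; PTRF+ blobs below the cutoff and all
#' PTRF- blobs are non-caveolae (`"negative"`). Geometry is untouched.
#'
#' @param bs a `cav_blob_set` with `ptrf_status` assigned.
#' @param caveolae_min_molecules molecule cutoff (default 60).
#' @return the blob set with `class` assigned.
#' @export
stratify_classes <- function(bs, caveolae_min_molecules = 60L) {
  status <- blob_field(bs, "ptrf_status")
  if (any(is.na(status)))
    abort("ptrf_status missing; run label_with_mask() first")
  blob_set(lapply(bs, function(b) {
    b$class <- if (b$ptrf_status == "PTRF+" &&
                   molecule_count(b) >= caveolae_min_molecules)
      "positive" else "negative"
    b
  }))
}

#' Balance classes by downsampling the majority
#'
#' Uniform random downsampling without replacement of the majority class to
#' the minority count; annotation-only (per-blob geometry untouched).
#'
#' @param bs a `cav_blob_set` with `class` assigned.
#' @param seed RNG seed.
#' @return balanced `cav_blob_set` of size `2 * min(class counts)`, in
#'   original blob order.
#' @export
balance_classes <- function(bs, seed = 1L) {
  cl <- blob_field(bs, "class")
  if (any(is.na(cl))) abort("class missing; run stratify_classes() first")
  n_pos <- sum(cl == "positive")
  n_neg <- sum(cl == "negative")
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present to balance")
  m <- min(n_pos, n_neg)
  keep_pos <- which(cl == "positive")
  keep_neg <- which(cl == "negative")
  if (n_pos > m) keep_pos <- with_seed(seed, sort(sample(keep_pos, m)))
  if (n_neg > m) keep_neg <- with_seed(seed, sort(sample(keep_neg, m)))
  bs[sort(c(keep_pos, keep_neg))]
}
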