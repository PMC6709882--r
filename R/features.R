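#' The frozen 28-feature order
#'
#' Size (6): `n_points`, `range_x`, `range_y`, `range_z`, `hull_volume`,
#' `density`. Shape (7): covariance eigenvalues `lambda1 >= lambda2 >=
#' lambda3` (nm^2) and the Westin measures `c_linear`, `c_planar`,
#' `c_spherical` plus fractional anisotropy `fa`. Hollowness (5): `d_min`,
#' `d_max`, `d_mean`, `d_median`, `d_std` of point-to-centroid distances.
#' Network (10): `n_edges`, `mean_degree`, `max_degree`, `degree_std`,
#' `mean_clustering`, `char_path_length`, `global_efficiency`, `modularity`,
#' `assortativity`, `graph_density` of the proximity graph.
#'
#' @return character vector of the 28 feature names, in order.
#' @export
feature_names <- function() {
  c("n_points", "range_x", "range_y", "range_z", "hull_volume", "density",
    "lambda1", "lambda2", "lambda3", "c_linear", "c_planar", "c_spherical",
    "fa",
    "d_min", "d_max", "d_mean", "d_median", "d_std",
    "n_edges", "mean_degree", "max_degree", "degree_std", "mean_clustering",
    "char_path_length", "global_efficiency", "modularity", "assortativity",
    "graph_density")
}

#' Convex hull volume of a point cloud
#'
#' Volume (nm^3) of the 3D convex hull, via an incremental hull. Collinear or
#' coplanar clouds (or N < 4) have zero volume and are flagged.
#'
#' @param points numeric N x 3 matrix.
#' @return volume in nm^3, with attribute `degenerate` set to `TRUE` when the
#'   cloud spans fewer than 3 dimensions.
#' @export
convex_hull_volume <- function(points) {
  points <- as.matrix(points)
  v <- cpp_hull_volume(points)
  structure(v, degenerate = (v == 0))
}

#' Eigen-shape descriptors of a blob
#'
#' Eigenvalues of the 3x3 covariance of the mean-centered points (sample
#' covariance, N-1 denominator), sorted descending, with the Westin shape
#' measures `c_linear = (l1-l2)/S`, `c_planar = 2(l2-l3)/S`,
#' `c_spherical = 3 l3 / S` (`S = l1+l2+l3`, so they sum to 1) and fractional
#' anisotropy `fa = sqrt(3/2) * sqrt(sum((li - lbar)^2)) / sqrt(sum(li^2))`.
#'
#' @param b a [blob()].
#' @return named numeric vector `lambda1..3`, `c_linear`, `c_planar`,
#'   `c_spherical`, `fa`; all zero (with attribute `degenerate = TRUE`) when
#'   N < 3.
#' @export
blob_shape <- function(b) {
  out <- c(lambda1 = 0, lambda2 = 0, lambda3 = 0,
           c_linear = 0, c_planar = 0, c_spherical = 0, fa = 0)
  if (molecule_count(b) < 3) return(structure(out, degenerate = TRUE))
  ev <- eigen(stats::cov(b$points), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0) # clamp numerical negatives
  s <- sum(ev)
  out[1:3] <- ev
  if (s > 0) {
    out["c_linear"] <- (ev[1] - ev[2]) / s
    out["c_planar"] <- 2 * (ev[2] - ev[3]) / s
    out["c_spherical"] <- 3 * ev[3] / s
    out["fa"] <- sqrt(3 / 2) * sqrt(sum((ev - mean(ev))^2)) / sqrt(sum(ev^2))
  }
  out
}

#' Size descriptors of a blob
#'
#' Per-axis coordinate ranges, convex-hull volume, and point density
#' `N / (hull_volume + 1 nm^3)`; the +1 nm^3 regularizer keeps density finite
#' for degenerate (flat or tiny) hulls.
#'
#' @param b a [blob()].
#' @return named numeric vector `n_points`, `range_x`, `range_y`, `range_z`,
#'   `hull_volume`, `density`.
#' @export
blob_size_features <- function(b) {
  n <- molecule_count(b)
  rng <- unname(apply(b$points, 2, function(v) diff(range(v))))
  vol <- as.numeric(convex_hull_volume(b$points))
  c(n_points = n, range_x = rng[1], range_y = rng[2], range_z = rng[3],
    hull_volume = vol, density = n / (vol + 1))
}

#' Hollowness descriptors of a blob
#'
#' Summary statistics (min, max, mean, median, sample sd) of the Euclidean
#' distances from every point to the blob centroid. A hollow shell has large,
#' tightly concentrated distances; a filled blob has a broad distance spread.
#'
#' @param b a [blob()].
#' @return named numeric vector `d_min`, `d_max`, `d_mean`, `d_median`,
#'   `d_std` (all zero for N = 1).
#' @export
blob_hollowness <- function(b) {
  ctr <- colMeans(b$points)
  d <- sqrt(rowSums(sweep(b$points, 2, ctr)^2))
  c(d_min = min(d), d_max = max(d), d_mean = mean(d), d_median = median(d),
    d_std = if (length(d) > 1) sd(d) else 0)
}

# internal: longest edge of the Euclidean minimum spanning tree
mst_bottleneck <- function(points) {
  n <- nrow(points)
  if (n < 2) return(0)
  d <- as.matrix(stats::dist(points))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  max(igraph::E(igraph::mst(g))$weight)
}

#' Global proximity threshold for network construction
#'
#' The smallest edge threshold at which every blob's proximity graph is a
#' single connected component: the maximum over blobs of the per-blob
#' bottleneck (the longest edge of the blob's Euclidean minimum spanning
#' tree).
#'
#' @param bs a `cav_blob_set`.
#' @param per_blob if `TRUE`, return the per-blob bottleneck vector instead
#'   of the global maximum.
#' @return threshold in nm (or a named vector when `per_blob = TRUE`).
#' @export
connectivity_threshold <- function(bs, per_blob = FALSE) {
  bn <- vapply(bs, function(b) mst_bottleneck(b$points), numeric(1))
  if (per_blob) bn else max(bn)
}

#' Proximity graph of a blob
#'
#' Undirected, unweighted graph whose nodes are the blob's points and whose
#' edges join pairs within `threshold_nm` (inclusive); no self loops.
#'
#' @param b a [blob()].
#' @param threshold_nm proximity threshold, from [connectivity_threshold()].
#' @return an `igraph` graph.
#' @export
proximity_graph <- function(b, threshold_nm) {
  n <- molecule_count(b)
  if (n == 1) return(igraph::make_empty_graph(1, directed = FALSE))
  adj <- as.matrix(stats::dist(b$points)) <= threshold_nm
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' The ten network features of a proximity graph
#'
#' Edge count; mean, max, and sample-sd degree; mean local clustering
#' coefficient (vertices of degree < 2 contribute 0); characteristic path
#' length (mean shortest-path length over all pairs); global efficiency
#' (mean inverse shortest-path length); modularity of a deterministic greedy
#' modularity-maximizing partition; degree assortativity (0 for regular
#' graphs, where it is undefined); and graph density `2E / (N (N - 1))`.
#'
#' @param g a connected `igraph` graph (single-vertex graphs return the
#'   documented all-zero sentinel).
#' @return named numeric vector of 10 finite values.
#' @export
network_features <- function(g) {
  n <- igraph::vcount(g)
  out <- c(n_edges = 0, mean_degree = 0, max_degree = 0, degree_std = 0,
           mean_clustering = 0, char_path_length = 0, global_efficiency = 0,
           modularity = 0, assortativity = 0, graph_density = 0)
  if (n == 1) return(out)
  if (!igraph::is_connected(g))
    abort("proximity graph is not connected; threshold violates its contract")
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local")
  cc[!is.finite(cc)] <- 0
  comm <- igraph::cluster_fast_greedy(g)
  assort <- igraph::assortativity_degree(g)
  out["n_edges"] <- igraph::ecount(g)
  out["mean_degree"] <- mean(deg)
  out["max_degree"] <- max(deg)
  out["degree_std"] <- if (n > 1) sd(deg) else 0
  out["mean_clustering"] <- mean(cc)
  out["char_path_length"] <- igraph::mean_distance(g, directed = FALSE)
  out["global_efficiency"] <- igraph::global_efficiency(g)
  out["modularity"] <- igraph::modularity(g, igraph::membership(comm))
  out["assortativity"] <- if (is.finite(assort)) assort else 0
  out["graph_density"] <- igraph::edge_density(g)
  out
}

#' Compute the 1 x 28 feature vector of one blob
#'
#' Concatenates size, shape, hollowness, and network descriptors in the
#' frozen [feature_names()] order. All 28 features are translation-invariant;
#' all but the three axis ranges are also rotation-invariant.
#'
#' @param b a [blob()].
#' @param threshold_nm proximity threshold for the network block (use
#'   [connectivity_threshold()] on the full dataset).
#' @return named numeric vector of 28 finite values.
#' @export
featurize_blob <- function(b, threshold_nm) {
  v <- c(blob_size_features(b), blob_shape(b), blob_hollowness(b),
         network_features(proximity_graph(b, threshold_nm)))
  v <- v[feature_names()]
  if (any(!is.finite(v)))
    abort("non-finite feature for blob ", b$blob_id, ": ",
          paste(names(v)[!is.finite(v)], collapse = ", "))
  v
}

#' Compute the feature matrix of a blob set
#'
#' @param bs a `cav_blob_set`.
#' @param threshold_nm proximity threshold; by default the dataset-level
#'   [connectivity_threshold()] is computed (so every blob's graph is
#'   connected).
#' @return data frame with `blob_id`, `cell_id`, `class`, and the 28 feature
#'   columns; the threshold used is stored in attribute `threshold_nm`.
#' @export
featurize_blobs <- function(bs, threshold_nm = NULL) {
  if (length(bs) == 0) abort("empty blob set")
  if (is.null(threshold_nm)) threshold_nm <- connectivity_threshold(bs)
  feats <- t(vapply(bs, featurize_blob, numeric(28), threshold_nm = threshold_nm))
  out <- data.frame(
    blob_id = names(bs),
    cell_id = blob_field(bs, "cell_id"),
    class = blob_field(bs, "class"),
    feats,
    row.names = NULL
  )
  attr(out, "threshold_nm") <- threshold_nm
  out
}

#' Write a feature matrix to CSV
#'
#' @param features data frame from [featurize_blobs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
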