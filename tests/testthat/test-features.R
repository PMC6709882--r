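test_that("eigen-shape descriptors match closed-form geometries", {
  # 6 points at +/- r on each axis: perfect isotropy
  r <- 50
  iso <- blob("iso", rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0),
                           c(0, 0, r), c(0, 0, -r)))
  s <- blob_shape(iso)
  expect_equal(unname(s["lambda1"]), unname(s["lambda3"]))
  expect_equal(unname(s["fa"]), 0)
  expect_equal(unname(s["c_spherical"]), 1)
  expect_equal(unname(s["c_linear"]), 0)
  expect_equal(unname(s["c_planar"]), 0)
  # collinear points: pure linear shape
  line <- blob("line", cbind(1:10, 0, 0))
  s <- blob_shape(line)
  expect_equal(unname(s["lambda2"]), 0)
  expect_equal(unname(s["c_linear"]), 1)
  expect_equal(unname(s["fa"]), 1)
  # N < 3: documented sentinel
  tiny <- blob_shape(blob("t", rbind(c(0, 0, 0), c(1, 1, 1))))
  expect_true(attr(tiny, "degenerate"))
  expect_equal(as.vector(tiny), rep(0, 7))
})

test_that("shape of a large anisotropic blob recovers the population covariance", {
  b <- simulate_blob(simulation_params(), "negative", 1e5, seed = 8)
  s <- blob_shape(b)
  expect_lt(max(abs(s[c("lambda1", "lambda2", "lambda3")] / c(200, 100, 100) - 1)),
            0.02)
  expect_lt(abs(s[["c_linear"]] - 0.25), 0.01)
})

test_that("Westin measures always sum to one on non-degenerate blobs", {
  set.seed(13)
  for (i in 1:20) {
    b <- blob("b", matrix(rnorm(3 * sample(3:50, 1), sd = sample(1:30, 3)),
                          ncol = 3))
    s <- blob_shape(b)
    expect_equal(unname(s["c_linear"] + s["c_planar"] + s["c_spherical"]), 1)
    expect_gte(s[["fa"]], 0)
    expect_lte(s[["fa"]], 1 + 1e-12)
  }
})

test_that("hull volume matches closed forms and the facet-enumeration oracle", {
  cube <- blob("cube", as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)))
  sz <- blob_size_features(cube)
  expect_equal(unname(sz[c("range_x", "range_y", "range_z")]), c(1, 1, 1))
  expect_equal(unname(sz["hull_volume"]), 1)
  expect_equal(unname(sz["density"]), 8 / 2)
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(as.numeric(convex_hull_volume(tet)), 1 / 6)
  set.seed(17)
  for (i in 1:4) {
    pts <- matrix(runif(3 * 60, 0, 100), ncol = 3)
    v <- as.numeric(convex_hull_volume(pts))
    expect_lt(abs(v - brute_hull_volume(pts)) / v, 1e-9)
  }
  # degenerate clouds are flagged with zero volume
  flat <- cbind(runif(20), runif(20), 2)
  expect_true(attr(convex_hull_volume(flat), "degenerate"))
  expect_equal(as.numeric(convex_hull_volume(flat)), 0)
  lineish <- blob_size_features(blob("l", cbind(1:5, 1:5, 1:5)))
  expect_equal(unname(lineish["hull_volume"]), 0)
  expect_equal(unname(lineish["density"]), 5)
})

test_that("hollowness statistics follow from the distance definition", {
  shell <- blob("s", 50 * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  h <- blob_hollowness(shell)
  expect_equal(unname(h), c(50, 50, 50, 50, 0))
  # hand-computed: x = -30,-10,10,30 -> distances 30,10,10,30
  four <- blob_hollowness(blob("f", cbind(c(-30, -10, 10, 30), 0, 0)))
  expect_equal(unname(four),
               c(10, 30, 20, 20, sqrt(400 / 3)))
  expect_equal(unname(blob_hollowness(blob("one", cbind(5, 5, 5)))), rep(0, 5))
})

test_that("the connectivity threshold is the max MST bottleneck", {
  chain <- blob("c", cbind(c(0, 15, 30), 0, 0))
  expect_equal(connectivity_threshold(blob_set(list(chain))), 15)
  b1 <- blob("b1", cbind(c(0, 12), 0, 0))
  b2 <- blob("b2", cbind(c(0, 40), 0, 0))
  expect_equal(connectivity_threshold(blob_set(list(b1, b2))), 40)
  # property: connected at the threshold, disconnected just below it
  set.seed(23)
  blobs <- lapply(1:50, function(i)
    blob(paste0("b", i), matrix(rnorm(3 * sample(5:40, 1), sd = 15), ncol = 3)))
  bs <- blob_set(blobs)
  thr <- connectivity_threshold(bs)
  conn_at <- vapply(bs, function(b)
    igraph::is_connected(proximity_graph(b, thr)), logical(1))
  expect_true(all(conn_at))
  conn_below <- vapply(bs, function(b)
    igraph::is_connected(proximity_graph(b, thr - 1e-9)), logical(1))
  expect_false(all(conn_below))
})

test_that("network features match hand-computed values on canonical graphs", {
  # path graph on 3 nodes
  p3 <- network_features(igraph::make_graph(c(1, 2, 2, 3), directed = FALSE))
  expect_equal(unname(p3["n_edges"]), 2)
  expect_equal(unname(p3["mean_degree"]), 4 / 3)
  expect_equal(unname(p3["max_degree"]), 2)
  expect_equal(unname(p3["degree_std"]), sd(c(1, 2, 1)))
  expect_equal(unname(p3["mean_clustering"]), 0)
  expect_equal(unname(p3["char_path_length"]), 4 / 3)
  expect_equal(unname(p3["global_efficiency"]), (1 + 1 + 1 / 2) / 3)
  expect_equal(unname(p3["graph_density"]), 2 / 3)
  # complete graph K4
  k4 <- network_features(igraph::make_full_graph(4))
  expect_equal(unname(k4["graph_density"]), 1)
  expect_equal(unname(k4["mean_clustering"]), 1)
  expect_equal(unname(k4["char_path_length"]), 1)
  expect_equal(unname(k4["global_efficiency"]), 1)
  expect_equal(unname(k4["assortativity"]), 0) # undefined on regular graphs
  # two triangles joined by one edge: greedy modularity attains the
  # exhaustive-bipartition optimum (the two-triangle split)
  g <- igraph::make_graph(c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4, 1, 4),
                          directed = FALSE)
  nf <- network_features(g)
  expect_equal(unname(nf["modularity"]), brute_best_bipartition_modularity(g))
  expect_equal(unname(nf["modularity"]), 2 * (3 / 7 - (7 / 14)^2))
  # contract violations
  expect_error(network_features(igraph::make_graph(c(1, 2), n = 3,
                                                   directed = FALSE)),
               "connected")
  expect_equal(unname(network_features(igraph::make_empty_graph(1, directed = FALSE))),
               rep(0, 10))
})

test_that("the 28-vector is complete, ordered, and respects invariances", {
  set.seed(29)
  b <- blob("b", matrix(rnorm(3 * 40, sd = 20), ncol = 3))
  thr <- connectivity_threshold(blob_set(list(b)))
  v <- featurize_blob(b, thr)
  expect_length(v, 28)
  expect_identical(names(v), feature_names())
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["n_points"]), 40)
  # translation invariance of the full vector
  b2 <- blob("b", b$points + 1000)
  expect_equal(featurize_blob(b2, thr), v, tolerance = 1e-8)
  # rotation by 90 degrees about z: x/y ranges swap, all else equal
  rot <- b$points %*% rbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))
  v3 <- featurize_blob(blob("b", rot), thr)
  expect_equal(unname(v3["range_x"]), unname(v["range_y"]), tolerance = 1e-10)
  expect_equal(unname(v3["range_y"]), unname(v["range_x"]), tolerance = 1e-10)
  others <- setdiff(feature_names(), c("range_x", "range_y"))
  expect_equal(v3[others], v[others], tolerance = 1e-8)
  # point order permutation leaves the vector unchanged
  v4 <- featurize_blob(blob("b", b$points[sample(40), ]), thr)
  expect_equal(v4, v, tolerance = 1e-10)
})

test_that("density falls with hull volume at fixed N and the matrix exports", {
  set.seed(31)
  small <- blob("s", matrix(runif(30, 0, 10), ncol = 3))
  big <- blob("b", small$points * 10)
  expect_gt(blob_size_features(small)["density"],
            blob_size_features(big)["density"])
  bs <- blob_set(list(small, big))
  f <- featurize_blobs(bs)
  expect_equal(dim(f), c(2, 31))
  expect_true(all(feature_names() %in% names(f)))
  path <- tempfile(fileext = ".csv")
  write_features(f, path)
  back <- read.csv(path)
  expect_equal(back$hull_volume, f$hull_volume)
})
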