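make_locs <- function(x, y = 0, z = 0, cell = "c1") {
  n <- length(x)
  data.frame(x = x, y = rep_len(y, n), z = rep_len(z, n),
             cell_id = rep_len(cell, n), source_row = seq_len(n))
}

test_that("iterative merging follows the stated rule", {
  # beyond the radius: unchanged
  far <- make_locs(c(0, 25))
  expect_equal(merge_localizations(far, 20)[, c("x", "y", "z")],
               far[, c("x", "y", "z")])
  # a close pair becomes its midpoint
  pair <- make_locs(c(0, 10))
  m <- merge_localizations(pair, 20)
  expect_equal(nrow(m), 1)
  expect_equal(m$x, 5)
  # collinear 0/15/30 nm: one component, centroid 15 (hand-simulated rule)
  chain <- make_locs(c(0, 15, 30))
  m <- merge_localizations(chain, 20)
  expect_equal(nrow(m), 1)
  expect_equal(m$x, 15)
  expect_equal(m$source_row, 1L)
  # empty input allowed
  expect_equal(nrow(merge_localizations(make_locs(numeric(0)), 20)), 0)
})

test_that("merging is idempotent, non-increasing, and separates all points", {
  set.seed(5)
  for (rep in 1:5) {
    locs <- data.frame(x = runif(150, 0, 500), y = runif(150, 0, 500),
                       z = runif(150, -100, 100), cell_id = "c1",
                       source_row = 1:150)
    m1 <- merge_localizations(locs, 30)
    expect_lte(nrow(m1), nrow(locs))
    expect_gte(nrow(m1), 1)
    expect_gt(min(stats::dist(m1[, c("x", "y", "z")])), 30)
    m2 <- merge_localizations(m1, 30)
    expect_equal(m2[, c("x", "y", "z")], m1[, c("x", "y", "z")])
  }
  # different cells never merge
  two <- rbind(make_locs(0, cell = "a"), make_locs(0.1, cell = "b"))
  two$source_row <- 1:2
  expect_equal(nrow(merge_localizations(two, 20)), 2)
})

test_that("segmentation equals a brute-force union-find partition", {
  set.seed(11)
  locs <- data.frame(x = runif(200, 0, 800), y = runif(200, 0, 800),
                     z = runif(200, -150, 150), cell_id = "c1",
                     source_row = 1:200)
  for (radius in c(40, 80, 150)) {
    bs <- segment_blobs(locs, radius)
    # partition property: disjoint cover of all points
    expect_equal(sum(vapply(bs, molecule_count, integer(1))), 200)
    # equivalence to the oracle partition
    oracle <- uf_components(as.matrix(locs[, c("x", "y", "z")]), radius)
    got <- integer(200)
    for (i in seq_along(bs)) {
      pts <- bs[[i]]$points
      idx <- vapply(seq_len(nrow(pts)), function(r)
        which(locs$x == pts[r, 1] & locs$y == pts[r, 2] & locs$z == pts[r, 3]),
        integer(1))
      got[idx] <- i
    }
    same_partition <- all(vapply(unique(oracle), function(c)
      length(unique(got[oracle == c])) == 1, logical(1)))
    expect_true(same_partition)
    expect_equal(length(bs), length(unique(oracle)))
  }
})

test_that("two separated clusters segment into two blobs; chains stay single", {
  a <- matrix(rnorm(30, 0, 10), 10, 3)
  b <- matrix(rnorm(30, 0, 10), 10, 3) + 1000
  locs <- data.frame(x = c(a[, 1], b[, 1]), y = c(a[, 2], b[, 2]),
                     z = c(a[, 3], b[, 3]), cell_id = "c1", source_row = 1:20)
  bs <- segment_blobs(locs, 100)
  expect_length(bs, 2)
  expect_equal(sort(vapply(bs, molecule_count, integer(1))), c(10L, 10L),
               ignore_attr = TRUE)
  chain <- make_locs(seq(0, 900, by = 50))
  expect_length(segment_blobs(chain, 80), 1)
})

test_that("the CSR noise filter keeps clustered points and sheds background", {
  # labeled simulation: dense ball + sparse uniform background
  set.seed(21)
  u <- matrix(rnorm(300), 100, 3)
  ball <- 50 * u / sqrt(rowSums(u^2)) * runif(100)^(1 / 3)
  bg <- matrix(runif(300, 0, 2000), 100, 3)
  locs <- data.frame(x = c(ball[, 1] + 1000, bg[, 1]),
                     y = c(ball[, 2] + 1000, bg[, 2]),
                     z = c(ball[, 3] + 1000, bg[, 3]),
                     cell_id = "c1", source_row = 1:200)
  kept <- filter_noise(locs, neighbor_radius_nm = 50, k = 2)
  is_ball <- kept$source_row <= 100
  expect_gte(sum(is_ball), 95)          # >= 95% of ball points retained
  expect_lte(sum(!is_ball), 20)         # >= 80% of background removed
  # degenerate inputs pass through with a warning
  expect_warning(out <- filter_noise(locs[1, ], 50, 2), "fewer than 2")
  expect_equal(nrow(out), 1)
  expect_warning(filter_noise(make_locs(numeric(0)), 50, 2), "fewer than 2")
})

test_that("under pure CSR the retained fraction respects the Poisson tail", {
  set.seed(31)
  n <- 3000
  L <- round((n * 4 / 3 * pi * 50^3 / 4)^(1 / 3)) # lambda ~= 4
  locs <- data.frame(x = runif(n, 0, L), y = runif(n, 0, L), z = runif(n, 0, L),
                     cell_id = "c1", source_row = seq_len(n))
  lambda <- n / L^3 * 4 / 3 * pi * 50^3
  kept <- filter_noise(locs, neighbor_radius_nm = 50, k = 2)
  tail_prob <- ppois(floor(lambda + 2 * sqrt(lambda)), lambda, lower.tail = FALSE)
  se <- sqrt(tail_prob * (1 - tail_prob) / n)
  expect_lte(nrow(kept) / n, tail_prob + 3 * se)
})

test_that("mask labeling counts in-mask point fractions with inclusive boundary", {
  b_in <- blob("in", cbind(runif(10, 100, 119), runif(10, 100, 119), 0))
  b_half <- blob("half", cbind(c(rep(110, 5), rep(500, 5)), rep(110, 10), 0))
  b_out <- blob("out", cbind(runif(5, 900, 950), runif(5, 900, 950), 0))
  px <- matrix(0, 10, 10)
  px[6, 6] <- 1 # x,y in [100,120) at 20 nm/px
  m <- mask_image(px, 20)
  expect_warning(
    bs <- label_with_mask(blob_set(list(b_in, b_half, b_out)), m, 0.5),
    "outside")
  expect_equal(bs[["in"]]$ptrf_status, "PTRF+")
  expect_equal(bs[["half"]]$ptrf_status, "PTRF+") # exactly 0.5 is inclusive
  expect_equal(bs[["out"]]$ptrf_status, "PTRF-")
  # empty mask: everything PTRF-
  none <- label_with_mask(blob_set(list(b_in)), mask_image(matrix(0, 10, 10), 20))
  expect_equal(none[["in"]]$ptrf_status, "PTRF-")
  # mask-free cell declaration
  free <- label_with_mask(blob_set(list(b_in)), NULL)
  expect_equal(free[["in"]]$ptrf_status, "PTRF-")
  # blob beyond the raster extent: warning, PTRF-
  far <- blob("far", cbind(1e5, 1e5, 0))
  expect_warning(out <- label_with_mask(blob_set(list(far)), m), "outside")
  expect_equal(out[["far"]]$ptrf_status, "PTRF-")
})

test_that("stratification applies the 60-molecule caveola rule exactly", {
  mk <- function(id, n, status) {
    b <- blob(id, matrix(rnorm(3 * n), n, 3), ptrf_status = status)
    b
  }
  bs <- blob_set(list(mk("a", 60, "PTRF+"), mk("b", 59, "PTRF+"),
                      mk("c", 500, "PTRF-")))
  out <- stratify_classes(bs, 60)
  expect_equal(out$a$class, "positive")
  expect_equal(out$b$class, "negative")
  expect_equal(out$c$class, "negative")
  expect_error(stratify_classes(blob_set(list(blob("x", cbind(0, 0, 0))))),
               "ptrf_status")
  # annotation-only: geometry bitwise unchanged
  expect_identical(out$a$points, bs$a$points)
})

test_that("balancing downsamples the majority to the minority count", {
  mk <- function(id, class) blob(id, cbind(rnorm(1), rnorm(1), rnorm(1)),
                                 class = class)
  bs <- blob_set(c(lapply(seq_len(857), function(i) mk(paste0("p", i), "positive")),
                   lapply(seq_len(24500 %/% 10), function(i) mk(paste0("n", i), "negative"))))
  # scaled negatives (2450) still downsample to the positive count
  out <- balance_classes(bs, seed = 2)
  cl <- vapply(out, function(b) b$class, character(1))
  expect_length(out, 2 * 857)
  expect_equal(sum(cl == "positive"), 857)
  expect_equal(sum(cl == "negative"), 857)
  # already balanced: nothing dropped
  small <- blob_set(list(mk("a", "positive"), mk("b", "negative")))
  expect_setequal(names(balance_classes(small, 1)), c("a", "b"))
  # retained ids are distinct members of the input, across many seeds
  pool <- blob_set(c(lapply(1:5, function(i) mk(paste0("p", i), "positive")),
                     lapply(1:40, function(i) mk(paste0("n", i), "negative"))))
  for (s in 1:100) {
    ids <- names(balance_classes(pool, seed = s))
    expect_length(ids, 10)
    expect_false(anyDuplicated(ids) > 0)
    expect_true(all(ids %in% names(pool)))
  }
  expect_error(balance_classes(blob_set(list(mk("a", "positive"))), 1), "both classes")
})
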