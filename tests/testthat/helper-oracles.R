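# Independent brute-force oracles used to verify the package's algorithms.
# These deliberately use different algorithms from the implementation.

# connected components by pairwise union-find over all O(n^2) pairs
uf_components <- function(pts, radius) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  d <- as.matrix(stats::dist(pts))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] <= radius) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# convex hull volume by facet enumeration: a triplet is a hull facet iff all
# points lie on one side of its plane (general position assumed)
brute_hull_volume <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  tol <- 1e-9 * scale
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  vol <- 0
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        a <- pts[i, ]
        nrm <- cross3(pts[j, ] - a, pts[k, ] - a)
        if (sqrt(sum(nrm^2)) < tol) next
        s <- sweep(pts, 2, a) %*% nrm
        if (all(s <= tol) || all(s >= -tol)) {
          vol <- vol + abs(det(rbind(a - ctr, pts[j, ] - ctr, pts[k, ] - ctr)))
        }
      }
    }
  }
  vol / 6
}

# binary dilation/erosion/closing by direct definition (outside = 0)
brute_dilate <- function(m, se) {
  r <- (nrow(se) - 1) / 2
  out <- m * 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (se[di + r + 1, dj + r + 1] &&
          ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
          m[ii, jj] == 1) {
        out[i, j] <- 1
      }
    }
  }
  out
}

brute_erode <- function(m, se) {
  r <- (nrow(se) - 1) / 2
  out <- m * 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ok <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      if (!se[di + r + 1, dj + r + 1]) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nrow(m) || jj < 1 || jj > ncol(m) || m[ii, jj] != 1)
        ok <- FALSE
    }
    out[i, j] <- as.numeric(ok)
  }
  out
}

brute_close <- function(m, se) brute_erode(brute_dilate(m, se), se)

# hand-rolled Newman modularity of a membership vector
brute_modularity <- function(g, membership) {
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  deg <- igraph::degree(g)
  q <- 0
  for (c in unique(membership)) {
    inc <- membership[el[, 1]] == c & membership[el[, 2]] == c
    e_c <- sum(inc)
    d_c <- sum(deg[membership == c])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# best modularity over all bipartitions (exhaustive; n <= ~12)
brute_best_bipartition_modularity <- function(g) {
  n <- igraph::vcount(g)
  best <- -Inf
  for (mask in 0:(2^n - 1)) {
    mem <- as.integer(intToBits(mask))[seq_len(n)] + 1L
    best <- max(best, brute_modularity(g, mem))
  }
  best
}

# mean silhouette width, computed directly
mean_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(l) mean(d[i, labels == l]),
                    numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
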