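#' Parameters of the two-class blob simulator
#'
#' Simulated blobs are i.i.d. draws from a 3D multivariate normal centered at
#' the origin. The positive (isotropic, caveola-like) class uses
#' `Sigma = diag(sigma^2, sigma^2, sigma^2)`; the negative (anisotropic,
#' scaffold-like) class doubles the variance of the first axis,
#' `Sigma = diag(2 sigma^2, sigma^2, sigma^2)`. Points per blob are drawn
#' uniformly (inclusive) from `n_range_positive` / `n_range_negative`.
#'
#' Defaults are the validation-study conditions: `sigma` 10 nm, 1000 blobs
#' per class, 60-210 points for positives, 10-160 for negatives.
#'
#' @param sigma standard deviation in nm.
#' @param n_range_positive,n_range_negative inclusive integer ranges of points
#'   per blob.
#' @param n_blobs_per_class blobs generated per class.
#' @param mu 3-vector mean in nm.
#' @param seed master RNG seed; every blob draws from an independent
#'   sub-stream spawned from it.
#' @return an object of class `sim_params`.
#' @export
simulation_params <- function(sigma = 10,
                              n_range_positive = c(60L, 210L),
                              n_range_negative = c(10L, 160L),
                              n_blobs_per_class = 1000L,
                              mu = c(0, 0, 0),
                              seed = 1L) {
  if (sigma <= 0) abort("sigma must be > 0")
  for (r in list(n_range_positive, n_range_negative)) {
    if (length(r) != 2 || r[1] < 1 || r[2] < r[1])
      abort("point-count ranges must be c(lower, upper) with 1 <= lower <= upper")
  }
  if (n_blobs_per_class < 0) abort("n_blobs_per_class must be >= 0")
  if (length(mu) != 3) abort("mu must be a 3-vector")
  p <- list(
    sigma = sigma,
    mu = as.numeric(mu),
    cov_positive = diag(rep(sigma^2, 3)),
    cov_negative = diag(c(2 * sigma^2, sigma^2, sigma^2)),
    n_range_positive = as.integer(n_range_positive),
    n_range_negative = as.integer(n_range_negative),
    n_blobs_per_class = as.integer(n_blobs_per_class),
    seed = as.integer(seed)
  )
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0("<sim_params> sigma=%g nm, %d blobs/class, ",
                     "N+ in [%d,%d], N- in [%d,%d], seed=%d\n"),
              x$sigma, x$n_blobs_per_class,
              x$n_range_positive[1], x$n_range_positive[2],
              x$n_range_negative[1], x$n_range_negative[2], x$seed))
  invisible(x)
}

# internal: n draws from N(mu, Sigma) via the Cholesky factor
rmvn_chol <- function(n, mu, Sigma) {
  L <- chol(Sigma) # upper triangular, Sigma = t(L) %*% L
  z <- matrix(rnorm(n * 3), n, 3)
  sweep(z %*% L, 2, mu, `+`)
}

#' Generate one simulated blob
#'
#' @param params a [simulation_params()] object.
#' @param class_label `"positive"` (isotropic) or `"negative"` (anisotropic).
#' @param n_points number of points (>= 1).
#' @param seed RNG seed for this blob.
#' @param blob_id identifier to record.
#' @return a [blob()] with the true class recorded at generation time.
#' @export
simulate_blob <- function(params, class_label, n_points, seed,
                          blob_id = "sim1") {
  if (!class_label %in% c("positive", "negative"))
    abort("class_label must be 'positive' or 'negative'")
  if (length(n_points) != 1 || n_points < 1)
    abort("n_points must be a single value >= 1")
  Sigma <- if (class_label == "positive") params$cov_positive else params$cov_negative
  pts <- with_seed(seed, rmvn_chol(as.integer(n_points), params$mu, Sigma))
  b <- blob(blob_id, pts, cell_id = "simulated", class = class_label)
  b$seed_used <- as.integer(seed)
  b
}

#' Generate the full two-class simulated dataset
#'
#' Draws `n_blobs_per_class` blobs per class; each blob's point count is
#' uniform over its class range and its coordinates come from an independent
#' sub-stream of the master seed, so the dataset is reproducible blob by
#' blob.
#'
#' @param params a [simulation_params()] object.
#' @return a `cav_blob_set` with classes recorded; ids `pos_0001`, ...,
#'   `neg_1000`.
#' @export
simulate_blob_dataset <- function(params = simulation_params()) {
  m <- params$n_blobs_per_class
  if (m == 0) return(blob_set(list()))
  seeds <- spawn_seeds(params$seed, 2 * m + 1)
  counts <- with_seed(seeds[1], c(
    sample(params$n_range_positive[1]:params$n_range_positive[2], m, replace = TRUE),
    sample(params$n_range_negative[1]:params$n_range_negative[2], m, replace = TRUE)
  ))
  labels <- rep(c("positive", "negative"), each = m)
  ids <- c(sprintf("pos_%04d", seq_len(m)), sprintf("neg_%04d", seq_len(m)))
  blobs <- lapply(seq_len(2 * m), function(i) {
    simulate_blob(params, labels[i], counts[i], seeds[i + 1], blob_id = ids[i])
  })
  blob_set(blobs)
}
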