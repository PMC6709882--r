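net_forward <- caviclass:::net_forward
net_backward <- caviclass:::net_backward
nn_ce <- caviclass:::nn_cross_entropy
nn_onehot <- caviclass:::nn_onehot

# central-difference gradient check over a sample of parameters
check_gradients <- function(model, x, y, n_per_block = 4, eps = 1e-6,
                            seed = 1) {
  set.seed(seed)
  fwd <- net_forward(model, x, keep_cache = TRUE)
  grads <- net_backward(model, x, fwd$cache, (fwd$probs - y) / nrow(y))
  loss_at <- function(m) nn_ce(net_forward(m, x)$probs, y)
  worst <- 0
  for (nm in names(model$params)) {
    for (slot in c("W", "b")) {
      v <- model$params[[nm]][[slot]]
      for (i in sample(length(v), min(n_per_block, length(v)))) {
        up <- model; up$params[[nm]][[slot]][i] <- v[i] + eps
        dn <- model; dn$params[[nm]][[slot]][i] <- v[i] - eps
        num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        ana <- grads[[nm]][[slot]][i]
        worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
      }
    }
  }
  worst
}

test_that("MVCNN analytic gradients match numerical differentiation", {
  set.seed(3)
  sp <- mvcnn_spec(9L, conv_channels = c(2L, 3L), fc_sizes = c(4L, 3L))
  m <- build_mvcnn(sp, seed = 2)
  x <- array(rbinom(9 * 9 * 3 * 5, 1, 0.2), c(9, 9, 3, 5))
  y <- nn_onehot(sample(c("positive", "negative"), 5, replace = TRUE))
  expect_lt(check_gradients(m, x, y), 1e-6)
})

test_that("PointNet analytic gradients match numerical differentiation", {
  set.seed(9)
  sp <- pointnet_spec(max_points = 8L, mlp_sizes = c(4L), head_sizes = c(3L))
  m <- build_pointnet(sp, seed = 11)
  x <- array(rnorm(8 * 3 * 2), c(8, 3, 2))
  y <- nn_onehot(c("positive", "negative"))
  expect_lt(check_gradients(m, x, y, n_per_block = 8), 1e-6)
})

test_that("the MVCNN spec computes the pooling ladder and rejects misfits", {
  sp <- mvcnn_spec() # full-scale: 512 px through five 3x3 pool stages
  expect_equal(sp$stage_sizes, c(512L, 170L, 56L, 18L, 6L, 2L))
  expect_equal(sp$conv_channels, c(32L, 64L, 128L, 256L, 512L))
  expect_error(mvcnn_spec(64L), "pooling stages")
  expect_silent(mvcnn_spec(64L, conv_channels = c(8L, 16L, 32L)))
  m <- build_mvcnn(mvcnn_spec(27L, conv_channels = c(4L, 8L), fc_sizes = c(8L, 8L)),
                   seed = 1)
  expect_error(net_forward(m, array(0, c(9, 9, 3, 1))), "configured size")
})

test_that("network outputs are probability pairs", {
  set.seed(5)
  m <- build_mvcnn(mvcnn_spec(9L, conv_channels = c(2L, 3L), fc_sizes = c(4L, 3L)),
                   seed = 7)
  x <- array(rbinom(9 * 9 * 3 * 6, 1, 0.3), c(9, 9, 3, 6))
  probs <- net_forward(m, x)$probs
  expect_equal(rowSums(probs), rep(1, 6))
  expect_true(all(probs >= 0))
  pn <- build_pointnet(pointnet_spec(16L, c(8L), c(4L)), seed = 3)
  px <- array(rnorm(16 * 3 * 4), c(16, 3, 4))
  pp <- net_forward(pn, px)$probs
  expect_equal(rowSums(pp), rep(1, 4))
})

test_that("PointNet logits are exactly invariant to point order and padding", {
  set.seed(13)
  pn <- build_pointnet(pointnet_spec(64L, c(16L, 32L), c(16L)), seed = 4)
  pts <- matrix(rnorm(40 * 3, sd = 10), 40, 3)
  base <- net_forward(pn, array(pts[rep_len(1:40, 64), ], c(64, 3, 1)))$probs
  for (i in 1:100) {
    perm <- pts[sample(40), ]
    got <- net_forward(pn, array(perm[rep_len(1:40, 64), ], c(64, 3, 1)))$probs
    expect_identical(got, base)
  }
  # duplicate-padding to any size leaves the logits unchanged
  unpadded <- net_forward(pn, array(pts, c(40, 3, 1)))$probs
  expect_identical(unpadded, base)
  padded_more <- pad_points(blob_set(list(blob("b", pts))), 64L, center = FALSE)
  expect_identical(net_forward(pn, padded_more)$probs, base)
})

test_that("pad_points centers blobs and enforces the size cap", {
  b <- blob("b", matrix(1:30, 10, 3))
  arr <- pad_points(blob_set(list(b)), 16L)
  expect_equal(dim(arr), c(16, 3, 1))
  expect_equal(colMeans(arr[1:10, , 1]), c(x = 0, y = 0, z = 0))
  expect_error(pad_points(blob_set(list(b)), 4L), "max_points")
})

test_that("a small net overfits a tiny training set (capacity sanity)", {
  set.seed(17)
  bs <- simulate_blob_dataset(simulation_params(n_blobs_per_class = 10L, seed = 3L))
  labels <- vapply(bs, function(b) b$class, character(1))
  pts <- pad_points(bs, 256L)
  pn <- build_pointnet(pointnet_spec(256L, c(32L, 32L), c(16L)), seed = 5)
  pn <- train_model(pn, pts, labels,
                    train_config(epochs = 150, batch_size = 20, lr = 5e-3,
                                 l2 = 0, seed = 5))
  expect_equal(mean(predict_classes(pn, pts) == labels), 1)
  expect_true(all(is.finite(pn$history$loss)))
  expect_lt(pn$history$loss[150], pn$history$loss[1])
})

test_that("an overwhelming L2 penalty collapses outputs toward uniform", {
  set.seed(19)
  bs <- simulate_blob_dataset(simulation_params(n_blobs_per_class = 8L, seed = 4L))
  labels <- vapply(bs, function(b) b$class, character(1))
  pts <- pad_points(bs, 256L)
  pn0 <- build_pointnet(pointnet_spec(256L, c(16L), c(8L)), seed = 6)
  pn <- train_model(pn0, pts, labels,
                    train_config(epochs = 300, batch_size = 16, lr = 0.05,
                                 l2 = 10, seed = 6))
  w_norm <- function(m) sum(vapply(m$params, function(p) sum(p$W^2), numeric(1)))
  expect_lt(w_norm(pn), w_norm(pn0))
  probs <- predict_probs(pn, pts)
  expect_lt(max(abs(probs - 0.5)), 0.05)
})

test_that("training is reproducible and evaluation matches the metrics path", {
  set.seed(23)
  bs <- simulate_blob_dataset(simulation_params(n_blobs_per_class = 15L, seed = 5L))
  labels <- vapply(bs, function(b) b$class, character(1))
  mv <- render_multiview_dataset(bs, multiview_config(27L, 6))
  spec <- mvcnn_spec(27L, conv_channels = c(4L, 8L), fc_sizes = c(8L, 8L))
  cfg <- train_config(epochs = 3, batch_size = 10, seed = 9)
  m1 <- train_model(build_mvcnn(spec, seed = 2), mv, labels, cfg)
  m2 <- train_model(build_mvcnn(spec, seed = 2), mv, labels, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  # evaluation equals the shared metrics code on the same predictions
  pred <- predict_classes(m1, mv)
  rep1 <- evaluate_model(m1, mv, labels)
  rep2 <- report_from_labels(pred, labels)
  expect_identical(rep1, rep2)
  # prediction is invariant to test-set ordering
  ord <- sample(length(bs))
  expect_identical(predict_classes(m1, mv[, , , ord, drop = FALSE]), pred[ord])
  # an always-positive classifier has sensitivity 1, specificity 0
  biased <- build_pointnet(pointnet_spec(512L, c(8L), c(4L)), seed = 1)
  biased$params$head2$W[] <- 0
  biased$params$head2$b <- c(10, -10)
  pts <- pad_points(bs, 512L)
  rb <- evaluate_model(biased, pts, labels)
  expect_equal(rb$sensitivity, 1)
  expect_equal(rb$specificity, 0)
})
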