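#' Multi-view CNN specification
#'
#' Alternating 2D convolutions (square kernels, stride 1, same padding, ReLU)
#' and non-overlapping max-pool stages, followed by two ReLU fully connected
#' layers and a final 2-way softmax. The default ladder is the full-scale
#' one: channels 3-32-64-128-256-512 with 3x3 pooling on 512 px inputs.
#' Reduced ladders (fewer stages / channels, smaller rasters) trade accuracy
#' for CPU time; the input raster must survive every pooling stage.
#'
#' @param image_size_px input raster side (pixels).
#' @param conv_channels output channels of each conv stage (input has 3
#'   channels: the xy, yz, xz views).
#' @param fc_sizes widths of the two hidden fully connected layers.
#' @param kernel conv kernel side.
#' @param pool pooling window and stride (non-overlapping).
#' @return an object of class `mvcnn_spec`.
#' @export
mvcnn_spec <- function(image_size_px = 512L,
                       conv_channels = c(32L, 64L, 128L, 256L, 512L),
                       fc_sizes = c(256L, 512L),
                       kernel = 3L, pool = 3L) {
  h <- as.integer(image_size_px)
  sizes <- h
  for (l in seq_along(conv_channels)) {
    h <- (h - pool) %/% pool + 1L
    if (h < 1) abort("image size ", image_size_px, " cannot survive ",
                     length(conv_channels), " pooling stages")
    sizes <- c(sizes, h)
  }
  structure(list(image_size_px = as.integer(image_size_px),
                 conv_channels = as.integer(conv_channels),
                 fc_sizes = as.integer(fc_sizes),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 stage_sizes = sizes),
            class = "mvcnn_spec")
}

#' Build an untrained multi-view CNN
#'
#' @param spec an [mvcnn_spec()].
#' @param seed initialization seed.
#' @return an object of class `cav_mvcnn`.
#' @export
build_mvcnn <- function(spec = mvcnn_spec(), seed = 1L) {
  chans <- c(3L, spec$conv_channels)
  params <- with_seed(seed, {
    p <- list()
    for (l in seq_along(spec$conv_channels))
      p[[paste0("conv", l)]] <- nn_init_dense(spec$kernel^2 * chans[l], chans[l + 1])
    flat <- utils::tail(spec$stage_sizes, 1)^2 * utils::tail(chans, 1)
    dims <- c(flat, spec$fc_sizes, 2L)
    for (l in seq_len(length(dims) - 1))
      p[[paste0("fc", l)]] <- nn_init_dense(dims[l], dims[l + 1])
    p
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 trained = FALSE),
            class = "cav_mvcnn")
}

# forward pass; x is (H, W, 3, B). Returns list(probs = B x 2, cache)
mvcnn_forward <- function(model, x, keep_cache = FALSE) {
  spec <- model$spec
  p <- model$params
  if (dim(x)[1] != spec$image_size_px || dim(x)[3] != 3)
    abort("input raster does not match the model's configured size")
  B <- dim(x)[4]
  k <- spec$kernel
  pad <- (k - 1L) %/% 2L
  nconv <- length(spec$conv_channels)
  cache <- list(conv = vector("list", nconv))
  a <- x
  for (l in seq_len(nconv)) {
    H <- dim(a)[1]; C <- dim(a)[3]; Cout <- spec$conv_channels[l]
    cols <- cpp_im2col(a, H, H, C, B, k, 1L, pad)
    z <- crossprod(p[[paste0("conv", l)]]$W, cols) + p[[paste0("conv", l)]]$b
    r <- z * (z > 0)
    arr <- aperm(array(r, c(Cout, H, H, B)), c(2, 3, 1, 4))
    pl <- cpp_maxpool_fwd(arr, H, H, Cout, B, spec$pool, spec$pool)
    if (keep_cache)
      cache$conv[[l]] <- list(cols = cols, z = z, argmax = pl$argmax,
                              H = H, C = C, Cout = Cout,
                              pooled_dim = dim(pl$out))
    a <- pl$out
  }
  h <- matrix(a, ncol = B) # flatten: (Hf*Hf*C) x B
  nfc <- length(spec$fc_sizes) + 1L
  cache$fc <- vector("list", nfc)
  for (l in seq_len(nfc)) {
    w <- p[[paste0("fc", l)]]
    z <- crossprod(w$W, h) + w$b
    if (keep_cache) cache$fc[[l]] <- list(h = h, z = z)
    h <- if (l < nfc) z * (z > 0) else z
  }
  probs <- nn_softmax_rows(t(h)) # B x 2
  if (keep_cache) cache$probs <- probs
  list(probs = probs, cache = cache)
}

# backward pass from dlogits (B x 2); returns grads parallel to params
mvcnn_backward <- function(model, x, cache, dlogits) {
  spec <- model$spec
  p <- model$params
  B <- dim(x)[4]
  k <- spec$kernel
  pad <- (k - 1L) %/% 2L
  grads <- list()
  nfc <- length(spec$fc_sizes) + 1L
  dz <- t(dlogits) # 2 x B
  for (l in rev(seq_len(nfc))) {
    ca <- cache$fc[[l]]
    if (l < nfc) dz <- dz * (ca$z > 0)
    grads[[paste0("fc", l)]] <- list(W = ca$h %*% t(dz), b = rowSums(dz))
    dz <- p[[paste0("fc", l)]]$W %*% dz
  }
  nconv <- length(spec$conv_channels)
  for (l in rev(seq_len(nconv))) {
    ca <- cache$conv[[l]]
    dpool <- array(dz, ca$pooled_dim)
    darr <- cpp_maxpool_bwd(dpool, ca$argmax, ca$H, ca$H, ca$Cout, B)
    dr <- matrix(aperm(darr, c(3, 1, 2, 4)), nrow = ca$Cout)
    dzc <- dr * (ca$z > 0)
    grads[[paste0("conv", l)]] <- list(W = ca$cols %*% t(dzc), b = rowSums(dzc))
    if (l > 1)
      dz <- cpp_col2im(p[[paste0("conv", l)]]$W %*% dzc,
                       ca$H, ca$H, ca$C, B, k, 1L, pad)
  }
  grads[names(model$params)]
}

#' PointNet-style classifier specification
#'
#' A shared per-point multilayer perceptron lifts each 3D point into feature
#' space; a symmetric max over the blob's points aggregates them into one
#' blob descriptor (making the output exactly invariant to point order and to
#' duplicate padding); a fully connected head classifies into the two
#' classes. Following the study's alterations to the original design, there
#' is no dropout layer and no input jittering.
#'
#' @param max_points fixed point-set size; smaller blobs are duplicate-padded
#'   (invisible to the max aggregation).
#' @param mlp_sizes widths of the shared per-point layers.
#' @param head_sizes widths of the hidden classifier layers.
#' @return an object of class `pointnet_spec`.
#' @export
pointnet_spec <- function(max_points = 512L, mlp_sizes = c(64L, 128L),
                          head_sizes = c(64L)) {
  structure(list(max_points = as.integer(max_points),
                 mlp_sizes = as.integer(mlp_sizes),
                 head_sizes = as.integer(head_sizes)),
            class = "pointnet_spec")
}

#' Build an untrained PointNet-style classifier
#'
#' @param spec a [pointnet_spec()].
#' @param seed initialization seed.
#' @return an object of class `cav_pointnet`.
#' @export
build_pointnet <- function(spec = pointnet_spec(), seed = 1L) {
  params <- with_seed(seed, {
    p <- list()
    dims <- c(3L, spec$mlp_sizes)
    for (l in seq_len(length(dims) - 1))
      p[[paste0("mlp", l)]] <- nn_init_dense(dims[l], dims[l + 1])
    dims <- c(utils::tail(spec$mlp_sizes, 1), spec$head_sizes, 2L)
    for (l in seq_len(length(dims) - 1))
      p[[paste0("head", l)]] <- nn_init_dense(dims[l], dims[l + 1])
    p
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 trained = FALSE),
            class = "cav_pointnet")
}

#' Pad a blob set into a fixed-size point array
#'
#' Centers each blob at its centroid (removing the position nuisance, like
#' the centered multi-view rendering) and duplicate-pads it to `max_points`
#' by cycling through its own points — invisible to the max aggregation.
#'
#' @param bs a `cav_blob_set`.
#' @param max_points fixed size; no blob may exceed it.
#' @param center center each blob at its centroid.
#' @return array of dim `(max_points, 3, n_blobs)`.
#' @export
pad_points <- function(bs, max_points = 512L, center = TRUE) {
  n <- blob_counts(bs)
  if (any(n > max_points))
    abort("blob(s) exceed max_points = ", max_points, ": ",
          paste(names(bs)[n > max_points], collapse = ", "))
  out <- array(0, c(max_points, 3, length(bs)),
               dimnames = list(NULL, c("x", "y", "z"), names(bs)))
  for (i in seq_along(bs)) {
    pts <- bs[[i]]$points
    if (center) pts <- sweep(pts, 2, colMeans(pts))
    out[, , i] <- pts[rep_len(seq_len(nrow(pts)), max_points), ]
  }
  out
}

# forward; x is (P, 3, B) or the pre-flattened (B*P) x 3 blob-major matrix
pointnet_forward <- function(model, x, keep_cache = FALSE) {
  spec <- model$spec
  p <- model$params
  if (length(dim(x)) == 3) {
    P <- dim(x)[1]
    x <- matrix(aperm(x, c(1, 3, 2)), ncol = 3)
  } else {
    P <- spec$max_points
  }
  nmlp <- length(spec$mlp_sizes)
  nhead <- length(spec$head_sizes) + 1L
  cache <- list(mlp = vector("list", nmlp), head = vector("list", nhead), P = P)
  h <- x
  for (l in seq_len(nmlp)) {
    w <- p[[paste0("mlp", l)]]
    z <- h %*% w$W + rep(w$b, each = nrow(h))
    if (keep_cache) cache$mlp[[l]] <- list(h = h, z = z)
    h <- z * (z > 0)
  }
  gm <- cpp_group_max_fwd(h, P)
  if (keep_cache) {
    cache$argmax <- gm$argmax
    cache$n_pointrows <- nrow(h)
  }
  h <- gm$out # B x F
  for (l in seq_len(nhead)) {
    w <- p[[paste0("head", l)]]
    z <- h %*% w$W + rep(w$b, each = nrow(h))
    if (keep_cache) cache$head[[l]] <- list(h = h, z = z)
    h <- if (l < nhead) z * (z > 0) else z
  }
  probs <- nn_softmax_rows(h)
  list(probs = probs, cache = cache)
}

pointnet_backward <- function(model, cache, dlogits) {
  spec <- model$spec
  p <- model$params
  grads <- list()
  nhead <- length(spec$head_sizes) + 1L
  dz <- dlogits
  for (l in rev(seq_len(nhead))) {
    ca <- cache$head[[l]]
    if (l < nhead) dz <- dz * (ca$z > 0)
    grads[[paste0("head", l)]] <- list(W = crossprod(ca$h, dz), b = colSums(dz))
    dz <- tcrossprod(dz, p[[paste0("head", l)]]$W)
  }
  dz <- cpp_group_max_bwd(dz, cache$argmax, cache$n_pointrows)
  for (l in rev(seq_along(spec$mlp_sizes))) {
    ca <- cache$mlp[[l]]
    dz <- dz * (ca$z > 0)
    grads[[paste0("mlp", l)]] <- list(W = crossprod(ca$h, dz), b = colSums(dz))
    if (l > 1) dz <- tcrossprod(dz, p[[paste0("mlp", l)]]$W)
  }
  grads[names(model$params)]
}

# internal: dispatch helpers shared by training and prediction
net_forward <- function(model, x, keep_cache = FALSE) {
  if (inherits(model, "cav_mvcnn")) mvcnn_forward(model, x, keep_cache)
  else if (inherits(model, "cav_pointnet")) pointnet_forward(model, x, keep_cache)
  else abort("unknown model class")
}

net_backward <- function(model, x, cache, dlogits) {
  if (inherits(model, "cav_mvcnn")) mvcnn_backward(model, x, cache, dlogits)
  else pointnet_backward(model, cache, dlogits)
}

net_slice <- function(model, x, idx) {
  if (inherits(model, "cav_mvcnn")) x[, , , idx, drop = FALSE]
  else x[, , idx, drop = FALSE]
}

net_nobs <- function(model, x) {
  if (inherits(model, "cav_mvcnn")) dim(x)[4] else dim(x)[3]
}

#' Train a neural classifier
#'
#' Minimizes softmax cross-entropy plus L2 weight decay with Adam. When a
#' validation set is supplied, the parameters with the best validation
#' accuracy are returned (best-on-validation checkpoint); otherwise the final
#' parameters are. Aborts if the loss becomes non-finite.
#'
#' @param model a `cav_mvcnn` or `cav_pointnet`.
#' @param x inputs: a multi-view array `(H, W, 3, B)` from
#'   [render_multiview_dataset()] or a point array `(P, 3, B)` from
#'   [pad_points()].
#' @param labels `"positive"`/`"negative"` per observation.
#' @param config a [train_config()].
#' @param val_x,val_labels optional validation set.
#' @return the trained model, with a per-epoch `history` data frame (loss,
#'   training accuracy, validation accuracy) attached.
#' @export
train_model <- function(model, x, labels, config = train_config(),
                        val_x = NULL, val_labels = NULL) {
  n <- net_nobs(model, x)
  if (length(labels) != n) abort("labels do not match the number of inputs")
  Y <- nn_onehot(labels)
  state <- nn_adam_init(model$params)
  best <- list(acc = -Inf, params = model$params)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        train_acc = numeric(), val_acc = numeric())
  step <- 0L
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- net_slice(model, x, idx)
      yb <- Y[idx, , drop = FALSE]
      fwd <- net_forward(model, xb, keep_cache = TRUE)
      loss <- nn_cross_entropy(fwd$probs, yb) +
        nn_l2_penalty(model$params, config$l2)
      if (!is.finite(loss)) abort("training diverged (non-finite loss) at epoch ", ep)
      dlogits <- (fwd$probs - yb) / nrow(yb)
      grads <- net_backward(model, xb, fwd$cache, dlogits)
      if (config$l2 > 0)
        for (nm in names(grads))
          grads[[nm]]$W <- grads[[nm]]$W + config$l2 * model$params[[nm]]$W
      step <- step + 1L
      upd <- nn_adam_step(model$params, grads, state, config$lr, step)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(fwd$probs, ties.method = "first") ==
              max.col(yb, ties.method = "first"))
    }
    val_acc <- NA_real_
    if (!is.null(val_x)) {
      val_pred <- predict_classes(model, val_x)
      val_acc <- mean(val_pred == val_labels)
      if (val_acc > best$acc) best <- list(acc = val_acc, params = model$params)
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_loss / n, train_acc = ep_correct / n,
      val_acc = val_acc))
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  train %.3f  val %s", ep,
                      ep_loss / n, ep_correct / n,
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
  }
  if (!is.null(val_x) && is.finite(best$acc)) model$params <- best$params
  model$trained <- TRUE
  model$history <- history
  model$config <- config
  model
}

#' Predict class labels with a neural classifier
#'
#' @param model a trained `cav_mvcnn` or `cav_pointnet`.
#' @param x input array (see [train_model()]).
#' @param batch_size forward-pass batch size.
#' @return character vector of `"positive"`/`"negative"`.
#' @export
predict_classes <- function(model, x, batch_size = 128L) {
  n <- net_nobs(model, x)
  out <- character(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    probs <- net_forward(model, net_slice(model, x, idx))$probs
    out[idx] <- c("positive", "negative")[max.col(probs, ties.method = "first")]
  }
  out
}

#' Predict class probabilities with a neural classifier
#'
#' @inheritParams predict_classes
#' @return n x 2 matrix of probabilities (columns positive, negative).
#' @export
predict_probs <- function(model, x, batch_size = 128L) {
  n <- net_nobs(model, x)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("positive", "negative")))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- net_forward(model, net_slice(model, x, idx))$probs
  }
  out
}

#' Evaluate a trained classifier on a test set
#'
#' @param model a trained `cav_mvcnn` or `cav_pointnet`.
#' @param x test inputs.
#' @param truth true labels.
#' @return a `cav_report` (argmax predictions scored with
#'   [metrics_from_counts()]).
#' @export
evaluate_model <- function(model, x, truth) {
  if (net_nobs(model, x) == 0) abort("empty test set")
  report_from_labels(predict_classes(model, x), truth)
}
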