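#' Specification of the 16-weight-layer defect network
#'
#' A VGG-style stack of 13 convolutional layers (all 3 x 3 kernels, each
#' followed by batch normalization and ReLU) in five stages separated by
#' 2 x 2 max pooling, an adaptive average pooling layer decoupling the
#' input resolution from the classifier, and 3 fully connected layers
#' (1024-1024-5 at full width; the final layer is the bias-free classifier
#' weight matrix used by the w-softmax loss). 13 + 3 = 16 weight layers.
#'
#' @param width_multiplier Scales every convolutional channel count and
#'   (unless `fc_units` is given) the fully connected width; 1 is the full
#'   published architecture, 0.25 the reduced desk-scale variant.
#' @param fc_units Units in the two hidden fully connected layers
#'   (default `round(1024 * width_multiplier)`).
#' @param num_classes Output classes (default 5).
#' @param pool_grid Output grid of the adaptive average pooling layer
#'   (default 1, i.e. global average pooling to `1 x 1`).
#' @return Object of class `plum_network_spec`.
#' @export
network_spec <- function(width_multiplier = 1, fc_units = NULL,
                         num_classes = 5, pool_grid = 1) {
  base_plan <- list(64, 64, "M", 128, 128, "M", 256, 256, 256, "M",
                    512, 512, 512, "M", 512, 512, 512, "M")
  channels <- integer(0)
  pool_after <- logical(0)
  for (e in base_plan) {
    if (identical(e, "M")) {
      pool_after[length(pool_after)] <- TRUE
    } else {
      channels <- c(channels, max(4L, as.integer(round(e * width_multiplier))))
      pool_after <- c(pool_after, FALSE)
    }
  }
  if (is.null(fc_units)) fc_units <- max(16L, round(1024 * width_multiplier))
  structure(list(channels = channels, pool_after = pool_after,
                 fc_units = as.integer(fc_units),
                 num_classes = as.integer(num_classes),
                 pool_grid = as.integer(pool_grid),
                 width_multiplier = width_multiplier,
                 in_channels = 3L),
            class = "plum_network_spec")
}

#' Build (initialize) the defect classification network
#'
#' Weights use He-normal initialization; batch-norm scales start at 1,
#' shifts at 0, running statistics at (0, 1). The build is fully
#' deterministic given `seed`.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for the weight initialization.
#' @return Object of class `plum_network`.
#' @export
build_network <- function(spec = network_spec(), seed = 1) {
  stopifnot(inherits(spec, "plum_network_spec"))
  with_local_seed(as.integer(seed), {
    conv <- vector("list", length(spec$channels))
    cin <- spec$in_channels
    for (l in seq_along(spec$channels)) {
      cout <- spec$channels[l]
      conv[[l]] <- list(
        W = array(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                  dim = c(3, 3, cin, cout)),
        b = numeric(cout),
        gamma = rep(1, cout), beta = numeric(cout),
        rmean = numeric(cout), rvar = rep(1, cout),
        pool = spec$pool_after[l])
      cin <- cout
    }
    d_in <- spec$pool_grid^2 * cin
    u <- spec$fc_units
    net <- list(
      spec = spec,
      conv = conv,
      fc1 = list(W = matrix(rnorm(d_in * u, 0, sqrt(2 / d_in)), d_in, u),
                 b = numeric(u)),
      fc2 = list(W = matrix(rnorm(u * u, 0, sqrt(2 / u)), u, u),
                 b = numeric(u)),
      cls = list(U = matrix(rnorm(u * spec$num_classes, 0, sqrt(1 / u)),
                            u, spec$num_classes)),
      loss = "wsoftmax", gamma = 1,
      bn_eps = 1e-5, bn_momentum = 0.1,
      norm_stats = NULL, input_size = NULL,
      swa_pending = FALSE)
    class(net) <- "plum_network"
    net
  })
}

# forward pass over an H x W x 3 x N standardized batch; with cache = TRUE
# retains everything the backward pass needs
network_forward <- function(net, x, training = FALSE, cache = FALSE) {
  if (dim(x)[1] < 32 || dim(x)[2] < 32) {
    stop("input must be at least 32 x 32 pixels (the receptive-field ",
         "minimum of the five pooling stages)")
  }
  caches <- if (cache) vector("list", length(net$conv)) else NULL
  h <- x
  for (l in seq_along(net$conv)) {
    ly <- net$conv[[l]]
    z <- .conv3x3_fwd(h, ly$W, ly$b)
    bn <- .batchnorm_fwd(z, ly$gamma, ly$beta, net$bn_eps, training,
                         ly$rmean, ly$rvar, TRUE) # fused BN + ReLU
    a <- bn$y
    if (cache) {
      caches[[l]] <- list(x_in = h, z = z, mean = bn$mean, var = bn$var,
                          a = a)
    }
    if (ly$pool) {
      mp <- .maxpool2_fwd(a)
      h <- mp$y
      if (cache) caches[[l]]$idx <- mp$idx
    } else {
      h <- a
    }
  }
  g <- net$spec$pool_grid
  pooled <- .adaptive_avgpool_fwd(h, g, g)
  n <- dim(x)[4]
  flat <- t(matrix(pooled, ncol = n))
  a1 <- sweep(flat %*% net$fc1$W, 2, net$fc1$b, "+")
  r1 <- a1; r1[r1 < 0] <- 0
  a2 <- sweep(r1 %*% net$fc2$W, 2, net$fc2$b, "+")
  feat <- a2; feat[feat < 0] <- 0
  out <- list(features = feat)
  if (cache) {
    out$cache <- list(conv = caches, pre_pool_dim = dim(h), flat = flat,
                      r1 = r1, batch_mean = NULL)
  }
  out
}

# backward pass; dfeat is the gradient of the scalar loss w.r.t. features.
# Returns gradients with the same structure as the trainable parameters.
network_backward <- function(net, fw, dfeat) {
  cache <- fw$cache
  g <- net$spec$pool_grid
  da2 <- dfeat * (fw$features > 0)
  grads <- list()
  grads$fc2 <- list(W = t(cache$r1) %*% da2, b = colSums(da2))
  dr1 <- da2 %*% t(net$fc2$W)
  da1 <- dr1 * (cache$r1 > 0)
  grads$fc1 <- list(W = t(cache$flat) %*% da1, b = colSums(da1))
  dflat <- da1 %*% t(net$fc1$W)
  dpool <- array(t(dflat), dim = c(g, g, dim(dflat)[2] / g^2, nrow(dflat)))
  dh <- .adaptive_avgpool_bwd(dpool, cache$pre_pool_dim, g, g)
  grads$conv <- vector("list", length(net$conv))
  for (l in rev(seq_along(net$conv))) {
    ly <- net$conv[[l]]
    cc <- cache$conv[[l]]
    if (ly$pool) {
      dh <- .maxpool2_bwd(dh, cc$idx, dim(cc$a))
    }
    da <- .relu_bwd(dh, cc$a)
    bn <- .batchnorm_bwd(cc$z, da, ly$gamma, cc$mean, cc$var, net$bn_eps)
    cv <- .conv3x3_bwd(cc$x_in, ly$W, bn$dx)
    grads$conv[[l]] <- list(W = cv$dw, b = cv$db,
                            gamma = bn$dgamma, beta = bn$dbeta)
    dh <- cv$dx
  }
  grads
}

# trainable parameters as a nested list (BN running stats are buffers and
# excluded: SWA averages weights, not statistics)
get_params <- function(net) {
  list(conv = lapply(net$conv,
                     function(l) l[c("W", "b", "gamma", "beta")]),
       fc1 = net$fc1, fc2 = net$fc2, cls = net$cls)
}

set_params <- function(net, params) {
  for (l in seq_along(net$conv)) {
    net$conv[[l]][c("W", "b", "gamma", "beta")] <- params$conv[[l]]
  }
  net$fc1 <- params$fc1
  net$fc2 <- params$fc2
  net$cls <- params$cls
  net
}

#' Count trainable parameters
#'
#' @param net A [build_network()] model.
#' @return Total number of trainable scalars (convolution and FC weights
#'   and biases, batch-norm scales and shifts; running statistics are
#'   buffers and not counted).
#' @export
count_parameters <- function(net) {
  sum(vapply(rapply(get_params(net), length, how = "unlist"),
             identity, numeric(1)))
}

#' Audit the built architecture
#'
#' Inspects the constructed network (not its spec) and reports the facts
#' the architecture is contracted to satisfy: 13 convolutional plus 3
#' fully connected weight layers (16 total), every convolution kernel
#' 3 x 3, batch normalization attached to every convolution, and 5 max
#' pooling stages.
#'
#' @param net A [build_network()] model.
#' @return Named list with `n_conv`, `n_fc`, `n_weight_layers`,
#'   `all_kernels_3x3`, `bn_after_every_conv`, `n_maxpool`.
#' @export
audit_architecture <- function(net) {
  kernel_ok <- vapply(net$conv,
                      function(l) all(dim(l$W)[1:2] == c(3, 3)), logical(1))
  bn_ok <- vapply(net$conv,
                  function(l) length(l$gamma) == dim(l$W)[4] &&
                    length(l$beta) == dim(l$W)[4], logical(1))
  n_fc <- 2L + 1L # fc1, fc2 and the classifier weight matrix
  list(n_conv = length(net$conv),
       n_fc = n_fc,
       n_weight_layers = length(net$conv) + n_fc,
       all_kernels_3x3 = all(kernel_ok),
       bn_after_every_conv = all(bn_ok),
       n_maxpool = sum(vapply(net$conv, function(l) l$pool, logical(1))))
}

# stack a list of H x W x 3 images into an H x W x 3 x N array
images_to_array <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) return(images)
  d <- dim(images[[1]])
  out <- array(0, dim = c(d, length(images)))
  for (i in seq_along(images)) out[, , , i] <- images[[i]]
  out
}

# standardize a raw 0..255 batch with the network's training statistics
# and resize to its input resolution
prepare_batch <- function(net, x) {
  if (!is.null(net$input_size) &&
      (dim(x)[1] != net$input_size || dim(x)[2] != net$input_size)) {
    x <- .batch_resize(x, net$input_size, net$input_size)
  }
  x <- x / 255
  if (!is.null(net$norm_stats)) {
    for (ch in 1:3) {
      x[, , ch, ] <- (x[, , ch, ] - net$norm_stats$mean[ch]) /
        net$norm_stats$sd[ch]
    }
  } else {
    x <- x - 0.5
  }
  x
}

#' Classify images with a trained network
#'
#' Runs the network in evaluation mode (batch normalization uses running
#' statistics), so predictions are deterministic. A model whose SWA
#' average has not been finalized refuses to predict.
#'
#' @param object A `plum_network`.
#' @param images List of `H x W x 3` images (0--255) or a 4-d array.
#' @param batch_size Evaluation batch size (default 64).
#' @param ... Unused.
#' @return List with `class` (factor over [defect_classes()]) and
#'   `scores` (`N x 5` matrix of raw class scores).
#' @export
predict.plum_network <- function(object, images, batch_size = 64, ...) {
  if (isTRUE(object$swa_pending)) {
    stop("model not finalized: the SWA average has been taken but batch-",
         "norm statistics were never recomputed; call finalize_swa()")
  }
  x <- images_to_array(images)
  n <- dim(x)[4]
  Wc <- if (object$loss == "wsoftmax") {
    normalize_columns(object$cls$U)
  } else {
    object$cls$U
  }
  scores <- matrix(0, n, object$spec$num_classes)
  for (s in seq(1, n, by = batch_size)) {
    e <- min(s + batch_size - 1, n)
    xb <- prepare_batch(object, x[, , , s:e, drop = FALSE])
    fw <- network_forward(object, xb, training = FALSE)
    scores[s:e, ] <- fw$features %*% Wc
  }
  cls <- defect_classes()[max.col(scores, ties.method = "first")]
  list(class = factor(cls, levels = defect_classes()), scores = scores)
}

#' @export
print.plum_network <- function(x, ...) {
  au <- audit_architecture(x)
  cat("<plum_network> ", au$n_conv, " conv + ", au$n_fc, " FC layers, ",
      format(count_parameters(x), big.mark = ","), " parameters\n", sep = "")
  cat("  channels:", paste(x$spec$channels, collapse = "-"), "\n")
  cat("  loss:", x$loss,
      if (x$loss == "wsoftmax") sprintf("(gamma = %g)", x$gamma), "\n")
  invisible(x)
}
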