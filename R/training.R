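#' Training configuration
#'
#' Defaults follow the reference training recipe: batch size 32, SGD with
#' momentum 0.9, initial learning rate 0.1, weight decay 1e-4, and SWA
#' with a cyclic learning rate descending to the SWA rate 0.05 at the end
#' of each cycle, where a weight snapshot is folded into the running
#' average.
#'
#' @param epochs Total training epochs.
#' @param batch_size Mini-batch size (default 32).
#' @param base_lr Learning rate before SWA starts (default 0.1).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 weight decay coupled into the gradient
#'   (default 1e-4).
#' @param loss `"wsoftmax"` (default) or `"softmax"`.
#' @param gamma w-softmax bias strength (default 1; ignored for plain
#'   softmax).
#' @param gamma_warmup_epochs Epochs trained with plain softmax (gamma 0)
#'   before the bias is introduced (default 0). When training from random
#'   weights the full bias admits a degenerate optimum in which all
#'   features collapse onto a direction anti-aligned with every class
#'   weight; a softmax warm-up keeps training out of that basin.
#' @param gamma_ramp_epochs Epochs over which gamma then ramps linearly
#'   from 0 to its target (default 0 = immediate).
#' @param clip_grad_norm Global L2 norm at which gradients are rescaled
#'   before the update (default `Inf` = no clipping). The w-softmax bias
#'   divides by `||gamma w_c + w_i||`, which can spike gradients when two
#'   classifier columns drift toward antipodal; clipping tames those
#'   steps.
#' @param swa List of SWA settings: `enabled`, `start_epoch` (first epoch
#'   of the cyclic phase), `alpha1`/`alpha2` (cycle endpoints, defaults
#'   0.1 and 0.05) and `cycle_steps` (`NULL` = one epoch of steps).
#' @param input_size Optional square resolution the batches are resized to
#'   before entering the network (the adaptive pooling layer makes the
#'   network resolution-agnostic).
#' @param seed Integer seed covering initialization, shuffling and every
#'   other source of randomness in the run.
#' @return Object of class `plum_train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 32, base_lr = 0.1,
                         momentum = 0.9, weight_decay = 1e-4,
                         loss = c("wsoftmax", "softmax"), gamma = 1,
                         gamma_warmup_epochs = 0, gamma_ramp_epochs = 0,
                         clip_grad_norm = Inf,
                         swa = list(), input_size = NULL, seed = 1) {
  loss <- match.arg(loss)
  swa_defaults <- list(enabled = TRUE, start_epoch = max(1, epochs %/% 2),
                       alpha1 = 0.1, alpha2 = 0.05, cycle_steps = NULL)
  swa_defaults[names(swa)] <- swa
  stopifnot(epochs >= 1, batch_size >= 1, base_lr > 0, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 base_lr = base_lr, momentum = momentum,
                 weight_decay = weight_decay, loss = loss, gamma = gamma,
                 gamma_warmup_epochs = as.integer(gamma_warmup_epochs),
                 gamma_ramp_epochs = as.integer(gamma_ramp_epochs),
                 clip_grad_norm = clip_grad_norm,
                 swa = swa_defaults, input_size = input_size,
                 seed = as.integer(seed)),
            class = "plum_train_config")
}

# elementwise SGD-with-momentum step over the nested parameter list
sgd_step <- function(params, grads, velocity, lr, momentum, wd) {
  step_one <- function(p, g, v) {
    v_new <- momentum * v + g + wd * p
    list(p = p - lr * v_new, v = v_new)
  }
  walk <- function(p, g, v) {
    if (is.list(p)) {
      out_p <- p
      out_v <- v
      keys <- if (!is.null(names(p))) names(p) else seq_along(p)
      for (k in keys) {
        r <- walk(p[[k]], g[[k]], v[[k]])
        out_p[[k]] <- r$p
        out_v[[k]] <- r$v
      }
      return(list(p = out_p, v = out_v))
    }
    step_one(p, g, v)
  }
  walk(params, grads, velocity)
}

zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, zeros_like))
  p * 0
}

# classifier-head loss: returns loss, feature gradient and gradient on the
# raw classifier matrix U
head_loss <- function(net, feat, labels) {
  if (net$loss == "wsoftmax" && net$gamma > 0) {
    U <- net$cls$U
    nrm <- sqrt(colSums(U^2))
    Wn <- sweep(U, 2, nrm, "/")
    res <- wsoftmax_loss(feat, labels, Wn, net$gamma)
    # back through the column normalization of U
    dU <- res$dW
    for (j in seq_len(ncol(U))) {
      dU[, j] <- (res$dW[, j] - Wn[, j] * sum(Wn[, j] * res$dW[, j])) / nrm[j]
    }
    list(loss = res$loss, probs = res$probs, dX = res$dX, dU = dU,
         scores = feat %*% Wn)
  } else {
    res <- wsoftmax_loss(feat, labels, net$cls$U, 0)
    list(loss = res$loss, probs = res$probs, dX = res$dX, dU = res$dW,
         scores = feat %*% net$cls$U)
  }
}

# per-epoch gamma under the warm-up / ramp schedule
gamma_at_epoch <- function(config, epoch) {
  if (config$loss != "wsoftmax") return(0)
  w <- config$gamma_warmup_epochs
  r <- config$gamma_ramp_epochs
  if (epoch <= w) return(0)
  if (r > 0 && epoch <= w + r) return(config$gamma * (epoch - w) / r)
  config$gamma
}

#' Train the defect network
#'
#' Runs momentum SGD under the configured schedule: a constant learning
#' rate until the SWA phase starts, then the cyclic schedule of
#' [cyclic_lr()] with a weight snapshot folded into the SWA running
#' average at the end of every cycle. After the last epoch the averaged
#' weights are installed and batch-normalization statistics are
#' recalibrated with one pass over the training batches
#' ([finalize_swa()]). The run is deterministic given the config seed.
#'
#' @param images List of `H x W x 3` images (0--255) or a 4-d array.
#' @param labels Class labels (character or factor over
#'   [defect_classes()]).
#' @param config A [train_config()].
#' @param spec A [network_spec()] (default: full-width network).
#' @return Object of class `plum_fit`: `model` (the finalized
#'   `plum_network`), `history` (one tibble row per epoch), `swa`
#'   (the final [swa_state()]) and `config`.
#' @export
train_network <- function(images, labels, config = train_config(),
                          spec = network_spec()) {
  if (length(images) == 0) stop("empty training set")
  x <- images_to_array(images)
  labels <- as_defect_factor(labels)
  n <- dim(x)[4]
  if (n == 0) stop("empty training set")
  if (length(labels) != n) stop("labels must parallel the images")
  y <- as.integer(labels)

  net <- build_network(spec, seed = config$seed)
  net$loss <- config$loss
  net$gamma <- config$gamma
  net$input_size <- config$input_size
  if (!is.null(config$input_size)) {
    x <- .batch_resize(x, config$input_size, config$input_size)
  }
  x <- x / 255
  net$norm_stats <- list(
    mean = vapply(1:3, function(ch) mean(x[, , ch, ]), numeric(1)),
    sd = vapply(1:3, function(ch) max(stats::sd(x[, , ch, ]), 1e-6),
                numeric(1)))
  for (ch in 1:3) {
    x[, , ch, ] <- (x[, , ch, ] - net$norm_stats$mean[ch]) /
      net$norm_stats$sd[ch]
  }

  steps_per_epoch <- ceiling(n / config$batch_size)
  cyc <- config$swa$cycle_steps
  if (is.null(cyc)) cyc <- steps_per_epoch
  velocity <- zeros_like(get_params(net))
  swa_st <- swa_state()
  history <- vector("list", config$epochs)
  swa_step <- 0L

  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      net$gamma <- gamma_at_epoch(config, epoch)
      perm <- sample(n)
      ep_loss <- 0
      ep_correct <- 0
      lr_last <- config$base_lr
      for (s in seq(1, n, by = config$batch_size)) {
        idx <- perm[s:min(s + config$batch_size - 1, n)]
        xb <- x[, , , idx, drop = FALSE]
        fw <- network_forward(net, xb, training = TRUE, cache = TRUE)
        # refresh BN running statistics from the batch statistics
        for (l in seq_along(net$conv)) {
          m <- net$bn_momentum
          net$conv[[l]]$rmean <- (1 - m) * net$conv[[l]]$rmean +
            m * fw$cache$conv[[l]]$mean
          net$conv[[l]]$rvar <- (1 - m) * net$conv[[l]]$rvar +
            m * fw$cache$conv[[l]]$var
        }
        hl <- head_loss(net, fw$features, y[idx])
        if (!is.finite(hl$loss)) {
          stop(sprintf("non-finite loss at epoch %d, step %d", epoch,
                       (s - 1) %/% config$batch_size + 1))
        }
        grads <- network_backward(net, fw, hl$dX)
        grads$cls <- list(U = hl$dU)
        if (is.finite(config$clip_grad_norm)) {
          gnorm <- sqrt(sum(vapply(rapply(grads, function(g) sum(g^2),
                                          how = "unlist"),
                                   identity, numeric(1))))
          if (gnorm > config$clip_grad_norm) {
            scl <- config$clip_grad_norm / gnorm
            grads <- rapply(grads, function(g) g * scl, how = "replace")
          }
        }
        in_swa <- isTRUE(config$swa$enabled) &&
          epoch >= config$swa$start_epoch
        if (in_swa) {
          swa_step <- swa_step + 1L
          lr_last <- cyclic_lr(swa_step, config$swa$alpha1,
                               config$swa$alpha2, cyc)
        } else {
          lr_last <- config$base_lr
        }
        st <- sgd_step(get_params(net), grads, velocity, lr_last,
                       config$momentum, config$weight_decay)
        net <- set_params(net, st$p)
        velocity <- st$v
        if (in_swa && (swa_step - 1) %% cyc + 1 == cyc) {
          swa_st <- swa_update(swa_st, get_params(net))
        }
        ep_loss <- ep_loss + hl$loss * length(idx)
        # accuracy under the unbiased scores, matching what predict() uses
        ep_correct <- ep_correct +
          sum(max.col(hl$scores, ties.method = "first") == y[idx])
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = ep_loss / n, train_accuracy = ep_correct / n,
        lr = lr_last, swa_snapshots = swa_st$n_models)
    }
  })

  net$gamma <- config$gamma # the schedule ends at the target bias
  if (isTRUE(config$swa$enabled) && swa_st$n_models >= 1) {
    net <- set_params(net, swa_st$avg)
    net$swa_pending <- TRUE
    net <- recalibrate_bn(net, x, config$batch_size)
  }
  structure(list(model = net, history = do.call(rbind, history),
                 swa = swa_st, config = config),
            class = "plum_fit")
}

# One training-mode pass over standardized batches to rebuild the BN
# running statistics. The pass shuffles deterministically first: training
# sets are often stored class-sorted, and single-class batches would lose
# the between-class activation variance. Per-channel statistics combine by
# the law of total variance across (equal-sized) batches.
recalibrate_bn <- function(net, x, batch_size) {
  n <- dim(x)[4]
  perm <- with_local_seed(1000003L + n, sample(n))
  means <- lapply(net$conv, function(l) list())
  vars <- lapply(net$conv, function(l) list())
  nb <- 0
  for (s in seq(1, n, by = batch_size)) {
    idx <- perm[s:min(s + batch_size - 1, n)]
    xb <- x[, , , idx, drop = FALSE]
    fw <- network_forward(net, xb, training = TRUE, cache = TRUE)
    nb <- nb + 1
    for (l in seq_along(net$conv)) {
      means[[l]][[nb]] <- fw$cache$conv[[l]]$mean
      vars[[l]][[nb]] <- fw$cache$conv[[l]]$var
    }
  }
  for (l in seq_along(net$conv)) {
    mb <- do.call(rbind, means[[l]])
    vb <- do.call(rbind, vars[[l]])
    m <- colMeans(mb)
    net$conv[[l]]$rmean <- m
    net$conv[[l]]$rvar <- colMeans(vb) +
      colMeans(sweep(mb, 2, m)^2) # within- plus between-batch variance
  }
  net$swa_pending <- FALSE
  net
}

#' Finalize a model that carries an SWA average
#'
#' Installs nothing new on the weight side (the averaged weights are
#' already in place after training) but recomputes the batch-normalization
#' running statistics with one pass over the supplied training images.
#' Averaged weights without recalibrated statistics would mix layers from
#' different training moments, so [predict.plum_network()] refuses to run
#' until this has happened.
#'
#' @param net A `plum_network` flagged `swa_pending`, or any network whose
#'   BN statistics should be recomputed.
#' @param images Training images (list or 4-d array, 0--255).
#' @param batch_size Pass batch size (default 64).
#' @return The finalized network.
#' @export
finalize_swa <- function(net, images, batch_size = 64) {
  x <- images_to_array(images)
  x <- prepare_batch(net, x)
  recalibrate_bn(net, x, batch_size)
}

#' @export
print.plum_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat("<plum_fit> ", nrow(x$history), " epochs; final loss ",
      signif(h$loss, 4), ", train accuracy ",
      signif(h$train_accuracy, 4), "\n", sep = "")
  cat("  SWA snapshots averaged:", x$swa$n_models, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fit
#'
#' @param x A `plum_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `loss`,
#'   `train_accuracy`, `lr`, `swa_snapshots`.
#' @export
tidy.plum_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fit
#'
#' @param x A `plum_fit`.
#' @param ... Unused.
#' @return One-row tibble: final loss and training accuracy, epoch count,
#'   snapshot count and parameter count.
#' @export
glance.plum_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = nrow(x$history), final_loss = h$loss,
                 final_train_accuracy = h$train_accuracy,
                 swa_snapshots = x$swa$n_models,
                 parameters = count_parameters(x$model))
}
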