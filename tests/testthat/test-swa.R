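test_that("the cyclic learning rate follows the linear-descent schedule", {
  # direct arithmetic: alpha1 0.1, alpha2 0.05, c 5, i 1 -> t 0.2, alpha 0.09
  expect_equal(cyclic_lr(1, 0.1, 0.05, 5), 0.09, tolerance = 1e-15)
  # the cycle end reaches alpha2 exactly
  expect_equal(cyclic_lr(5, 0.1, 0.05, 5), 0.05, tolerance = 1e-15)
  # periodicity over full cycles
  i <- 1:50
  expect_equal(cyclic_lr(i + 5, 0.1, 0.05, 5), cyclic_lr(i, 0.1, 0.05, 5))
  # never outside [alpha2, alpha1]
  rates <- cyclic_lr(1:1000, 0.1, 0.05, 7)
  expect_true(all(rates >= 0.05 & rates <= 0.1))
  expect_error(cyclic_lr(0, 0.1, 0.05, 5), ">= 1")
  expect_error(cyclic_lr(1, 0.01, 0.05, 5), "alpha1 >= alpha2")
})

test_that("the SWA running average equals the arithmetic mean of snapshots", {
  st <- swa_state()
  expect_equal(st$n_models, 0L)
  st <- swa_update(st, 1.0)
  expect_equal(st$avg, 1.0)
  st <- swa_update(st, 2.0)
  st <- swa_update(st, 4.0)
  expect_equal(st$avg, 7 / 3, tolerance = 1e-15)

  # repeated identical snapshots leave the average unchanged
  st2 <- swa_state()
  w <- list(a = matrix(3, 2, 2), b = list(c = rep(0.5, 4)))
  for (k in 1:5) st2 <- swa_update(st2, w)
  expect_equal(st2$avg, w, tolerance = 1e-15)
  expect_equal(st2$n_models, 5L)

  # random nested snapshots against an accumulate-then-divide oracle
  set.seed(41)
  snaps <- lapply(1:7, function(i) {
    list(W = matrix(stats::rnorm(6), 2, 3), b = stats::rnorm(4))
  })
  st3 <- swa_state()
  for (s in snaps) st3 <- swa_update(st3, s)
  oracleW <- Reduce(`+`, lapply(snaps, `[[`, "W")) / 7
  oracleb <- Reduce(`+`, lapply(snaps, `[[`, "b")) / 7
  expect_equal(st3$avg$W, oracleW, tolerance = 1e-12)
  expect_equal(st3$avg$b, oracleb, tolerance = 1e-12)

  expect_error(swa_update(st3, list(W = matrix(0, 3, 3), b = numeric(4))),
               "shape mismatch")
})

test_that("averaging antipodal snapshots cancels the weights", {
  net <- build_network(network_spec(width_multiplier = 0.0625, fc_units = 8),
                       seed = 2)
  p <- plumvision:::get_params(net)
  neg <- rapply(p, function(x) -x, how = "replace")
  st <- swa_update(swa_update(swa_state(), p), neg)
  flat <- unlist(st$avg)
  expect_equal(max(abs(flat)), 0, tolerance = 1e-15)
})

test_that("finalization recomputes BN statistics and gates prediction", {
  spec <- network_spec(width_multiplier = 0.0625, fc_units = 8)
  net <- build_network(spec, seed = 7)
  imgs <- array(sample(0:255, 32 * 32 * 3 * 8, replace = TRUE),
                dim = c(32, 32, 3, 8))
  net$norm_stats <- list(mean = rep(0.5, 3), sd = rep(0.25, 3))

  pending <- net
  pending$swa_pending <- TRUE
  expect_error(predict(pending, imgs), "not finalized")

  fin <- finalize_swa(pending, imgs, batch_size = 4)
  expect_false(fin$swa_pending)
  p1 <- predict(fin, imgs)
  p2 <- predict(fin, imgs)
  expect_identical(p1$scores, p2$scores)

  # averaging a single snapshot then finalizing matches the snapshot model
  # finalized the same way
  st <- swa_update(swa_state(), plumvision:::get_params(net))
  avg_net <- plumvision:::set_params(net, st$avg)
  fin2 <- finalize_swa(avg_net, imgs, batch_size = 4)
  expect_equal(predict(fin2, imgs)$scores, p1$scores, tolerance = 1e-12)
})

test_that("training retains exactly two weight sets: the live model and the average", {
  fit_obj_fields <- c("model", "history", "swa", "config")
  imgs <- lapply(1:20, function(i) array(stats::runif(40 * 40 * 3, 0, 255),
                                         dim = c(40, 40, 3)))
  labels <- rep(defect_classes(), 4)
  cfg <- train_config(epochs = 2, batch_size = 10, base_lr = 0.01,
                      input_size = 32, seed = 3,
                      swa = list(enabled = TRUE, start_epoch = 1,
                                 alpha1 = 0.01, alpha2 = 0.005))
  fit <- train_network(imgs, labels, cfg,
                       network_spec(width_multiplier = 0.0625, fc_units = 8))
  expect_named(fit, fit_obj_fields)
  # one full parameter set in the model, one in the SWA average, none else
  expect_named(fit$swa, c("avg", "n_models"))
  expect_identical(names(fit$swa$avg),
                   names(plumvision:::get_params(fit$model)))
})
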