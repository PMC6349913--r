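test_that("loss closed forms", {
  expect_equal(mse_loss(c(1, 3), c(2, 5)), 2.5)
  expect_equal(mse_loss(c(4, 4), c(4, 4)), 0)
  # constant shift of perfect predictions costs exactly c^2
  y <- c(0.3, 2, 6.5)
  expect_equal(mse_loss(y + 1.7, y), 1.7^2)
  expect_error(mse_loss(1:3, 1:4), class = "panbinder_shape_error")

  expect_equal(bce_loss(1, 0.5), log(2))
  expect_lt(bce_loss(1, 1 - 1e-7), 1e-6)
  expect_lt(bce_loss(0, 1e-7), 1e-6)
  # clamping keeps saturated predictions finite
  expect_true(is.finite(bce_loss(c(1, 0), c(0, 1))))
  expect_error(bce_loss(c(1, 0), 0.5), class = "panbinder_shape_error")

  expect_equal(total_loss(2.5, log(2)), 2.5 + log(2))
  expect_equal(total_loss(0, 0), 0)
  expect_gte(total_loss(2.5, 0.7), max(2.5, 0.7))
})

test_that("a single SGD step decreases a one-sample loss", {
  al <- toy_alleles()
  net <- build_network(network_config("compact", seed = 5))
  one <- toy_samples(al, n_per_allele = 2)[1, ]
  enc <- panbinder:::encode_batch(one, al)
  loss_of <- function(net) {
    fw <- panbinder:::nn_forward(net, enc$pep, enc$hla, enc$hla_of, training = TRUE)
    mse_loss(fw$log_ic50_pred, one$log_ic50) +
      bce_loss(one$binary_label, fw$binding_prob)
  }
  before <- loss_of(net)
  fw <- panbinder:::nn_forward(net, enc$pep, enc$hla, enc$hla_of,
                               training = TRUE, keep_caches = TRUE)
  grads <- panbinder:::nn_backward(net, fw,
                                   dy_r = 2 * (fw$log_ic50_pred - one$log_ic50),
                                   dz_c = fw$binding_prob - one$binary_label)
  for (nm in names(net$stacks)) {
    vel <- panbinder:::stack_zero_vel(net$stacks[[nm]])
    up <- panbinder:::stack_update(net$stacks[[nm]], grads[[nm]], vel,
                                   lr = 1e-4, momentum = 0)
    net$stacks[[nm]] <- up$layers
  }
  expect_lt(loss_of(net), before)
})

test_that("training log decomposes, learning rate never rises, run is deterministic", {
  al <- toy_alleles()
  ds <- toy_samples(al, n_per_allele = 30)
  sp <- split_train_val(ds, seed = 2)
  net <- build_network(network_config("compact", seed = 5))
  fit <- train_network(net, sp$train, sp$val, al, epochs = 4, seed = 6)
  log <- tidy(fit)
  expect_equal(nrow(log), 4)
  expect_equal(log$train_total, log$train_reg + log$train_cls, tolerance = 1e-6)
  expect_equal(log$val_total, log$val_reg + log$val_cls, tolerance = 1e-6)
  expect_true(all(diff(log$learning_rate) <= 0))
  expect_true(all(log$learning_rate >= 1e-5))

  fit2 <- train_network(net, sp$train, sp$val, al, epochs = 4, seed = 6)
  expect_identical(tidy(fit2), log)
  expect_identical(predict(fit2, sp$val, al), predict(fit, sp$val, al))
})

test_that("schedule halves the learning rate after 5 stalls and stops after 15", {
  # drive the bookkeeping with a loss trace that improves once then stalls
  sched <- list(lr = 1e-3, best_val = Inf, since_improve = 0L, since_lr = 0L)
  losses <- c(5, rep(5, 40))  # epoch 1 improves (from Inf), then stagnation
  lr_trace <- numeric(0)
  stopped_at <- NA_integer_
  for (e in seq_along(losses)) {
    lr_trace <- c(lr_trace, sched$lr)
    sched <- panbinder:::sched_observe(sched, losses[e])
    if (sched$stop) {
      stopped_at <- e
      break
    }
  }
  # halvings after epochs 1+5 and 1+10; stop once 15 stagnant epochs accrue
  expect_equal(stopped_at, 16)
  expect_equal(unique(lr_trace), c(1e-3, 5e-4, 2.5e-4))
  expect_equal(lr_trace[7], 5e-4)
  expect_equal(lr_trace[12], 2.5e-4)

  # the floor: halving never goes below 1e-5
  s <- list(lr = 1.6e-5, best_val = 1, since_improve = 0L, since_lr = 0L)
  for (i in 1:20) s <- panbinder:::sched_observe(s, 2)
  expect_equal(s$lr, 1e-5)

  # learning rate is non-increasing along any loss trace
  s <- list(lr = 1e-3, best_val = Inf, since_improve = 0L, since_lr = 0L)
  trace <- withr::with_seed(8, runif(60, 1, 3))
  lrs <- numeric(0)
  for (v in trace) {
    s <- panbinder:::sched_observe(s, v)
    lrs <- c(lrs, s$lr)
    if (s$stop) break
  }
  expect_true(all(diff(lrs) <= 0))
  expect_true(all(lrs >= 1e-5))
})

test_that("training rejects empty or unlabeled datasets", {
  al <- toy_alleles()
  ds <- toy_samples(al, n_per_allele = 10)
  net <- build_network(network_config("compact", seed = 5))
  expect_error(train_network(net, ds[0, ], ds, al), class = "panbinder_size_error")
  bad <- ds
  bad$log_ic50[1] <- NA
  expect_error(train_network(net, bad, ds, al), class = "panbinder_size_error")
})

test_that("training at small scale improves validation loss on planted-rule data", {
  m <- planted_binding_model(seed = 101)
  al <- generate_alleles(m, 4, seed = 102)
  ds <- generate_samples(al, 150, m, seed = 103)
  sp <- split_train_val(ds$samples, seed = 104)
  net <- build_network(network_config("compact", seed = 105))
  fit <- train_network(net, sp$train, sp$val, al, epochs = 8,
                       batch_size = 32, seed = 106)
  log <- tidy(fit)
  expect_lt(fit$best_val_loss, log$val_total[1])
  expect_equal(fit$best_val_loss, min(log$val_total))
})

test_that("glance and autoplot summarize a fit", {
  al <- toy_alleles()
  ds <- toy_samples(al, n_per_allele = 20)
  sp <- split_train_val(ds, seed = 2)
  net <- build_network(network_config("compact", seed = 5))
  fit <- train_network(net, sp$train, sp$val, al, epochs = 2, seed = 6)
  g <- glance(fit)
  expect_equal(g$epochs, 2)
  expect_true(g$n_params > 0)
  expect_s3_class(autoplot(fit), "ggplot")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_training_log(fit, path)
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)), 2)
})
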