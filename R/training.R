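#' Training losses
#'
#' The model is trained on a dual loss: the total loss is the plain
#' (unweighted) sum of a regression loss and a classification loss.
#' `mse_loss()` is the mean squared error between predicted and true log
#' IC50 values. `bce_loss()` is the mean binary cross entropy between the
#' 0/1 binding labels and the predicted binding probabilities; predictions
#' are clamped to `[eps, 1 - eps]` (`eps = 1e-7`) before the logs so the
#' loss stays finite at saturated outputs. `total_loss()` is the exact sum
#' with no weighting coefficient.
#'
#' @param pred_log_ic50,true_log_ic50 Numeric vectors of equal length.
#' @param true_label Vector of 0/1 labels.
#' @param pred_prob Numeric vector of predicted probabilities.
#' @param loss_r,loss_c Finite numeric scalars.
#' @param eps Clamping constant for the cross entropy.
#' @return A single numeric loss value.
#' @examples
#' mse_loss(c(1, 3), c(2, 5))        # 2.5
#' bce_loss(1, 0.5)                  # log(2)
#' total_loss(2.5, log(2))
#' @export
mse_loss <- function(pred_log_ic50, true_log_ic50) {
  if (length(pred_log_ic50) != length(true_log_ic50)) {
    abort("prediction and label vectors differ in length",
          class = "panbinder_shape_error")
  }
  stopifnot(length(pred_log_ic50) >= 1L)
  mean((true_log_ic50 - pred_log_ic50)^2)
}

#' @rdname mse_loss
#' @export
bce_loss <- function(true_label, pred_prob, eps = 1e-7) {
  if (length(true_label) != length(pred_prob)) {
    abort("prediction and label vectors differ in length",
          class = "panbinder_shape_error")
  }
  stopifnot(length(true_label) >= 1L, all(true_label %in% c(0, 1)))
  p <- pmin(pmax(pred_prob, eps), 1 - eps)
  mean(-true_label * log(p) - (1 - true_label) * log(1 - p))
}

#' @rdname mse_loss
#' @export
total_loss <- function(loss_r, loss_c) {
  stopifnot(is.finite(loss_r), is.finite(loss_c))
  loss_r + loss_c
}

# Pure early-stopping / learning-rate bookkeeping. state: lr, best_val,
# since_improve, since_lr. Feed one validation loss per epoch; returns the
# new state plus `improved` and `stop` flags.
sched_observe <- function(state, val_loss, improve_tol = 1e-6,
                          lr_patience = 5L, stop_patience = 15L, min_lr = 1e-5) {
  improved <- val_loss < state$best_val - improve_tol
  if (improved) {
    state$best_val <- val_loss
    state$since_improve <- 0L
    state$since_lr <- 0L
  } else {
    state$since_improve <- state$since_improve + 1L
    state$since_lr <- state$since_lr + 1L
    if (state$since_improve < stop_patience && state$since_lr >= lr_patience) {
      state$lr <- max(state$lr / 2, min_lr)
      state$since_lr <- 0L
    }
  }
  state$improved <- improved
  state$stop <- state$since_improve >= stop_patience
  state
}

#' Train the network with SGD, learning-rate halving and early stopping
#'
#' Optimizes the dual loss with mini-batch stochastic gradient descent with
#' momentum 0.8 at an initial learning rate of 0.001. The learning rate is
#' halved whenever the validation total loss has not improved for
#' `lr_patience` (5) consecutive epochs, with a floor of 1e-5; training
#' stops once validation loss has not improved for `stop_patience` (15)
#' consecutive epochs or at the epoch cap. "Improved" means lower than the
#' best seen value by at least `improve_tol`. The parameters of the
#' best-validation epoch are returned. The regression head is trained
#' against log IC50 labels; the classification head against the 500 nM
#' binary labels. The whole run is deterministic given `seed`.
#'
#' @param net A `panbinder_network` from [build_network()].
#' @param train,val Non-empty binding-sample tibbles with finite `log_ic50`
#'   and `binary_label` on every row (see [as_binding_samples()]).
#' @param alleles Named character vector of aligned HLA sequences.
#' @param epochs Epoch cap (early stopping usually ends training first).
#'   `epochs = 0` returns the untrained network with an empty log.
#' @param batch_size Mini-batch size.
#' @param batch_by `"allele"` (default) shuffles samples within each allele
#'   and alleles within each epoch, so that consecutive mini-batches contain
#'   few distinct alleles — the HLA encoder then runs on only one or two
#'   sequences per step instead of every allele in the data, which is
#'   substantially faster on CPU. `"sample"` is plain uniform shuffling.
#'   Every sample is still visited exactly once per epoch either way.
#' @param learning_rate,momentum,min_lr,lr_patience,stop_patience,improve_tol
#'   Schedule constants; defaults are the protocol above.
#' @param seed Integer seed controlling mini-batch shuffling.
#' @param verbose Print a per-epoch progress line.
#' @return An object of class `panbinder_fit`: the best network, the
#'   per-epoch `log` tibble (train/validation total, regression and
#'   classification losses and the learning rate), `best_epoch` and
#'   `best_val_loss`.
#' @export
train_network <- function(net, train, val, alleles,
                          epochs = 500L, batch_size = 64L,
                          batch_by = c("allele", "sample"),
                          learning_rate = 1e-3, momentum = 0.8,
                          min_lr = 1e-5, lr_patience = 5L, stop_patience = 15L,
                          improve_tol = 1e-6, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(net, "panbinder_network"))
  batch_by <- match.arg(batch_by)
  for (d in list(train, val)) {
    if (!is.data.frame(d) || nrow(d) == 0L) {
      abort("training and validation sets must be non-empty",
            class = "panbinder_size_error")
    }
    if (anyNA(d$log_ic50) || anyNA(d$binary_label)) {
      abort("every sample needs log_ic50 and binary_label for training",
            class = "panbinder_size_error")
    }
  }
  enc_tr <- encode_batch(train, alleles)
  n_tr <- nrow(train)
  y_r <- train$log_ic50
  y_c <- as.numeric(train$binary_label)

  vel <- lapply(net$stacks, stack_zero_vel)
  sched <- list(lr = learning_rate, best_val = Inf,
                since_improve = 0L, since_lr = 0L)
  best <- list(net = net, val = Inf, epoch = 0L)
  log_rows <- vector("list", epochs)
  n_epochs_run <- 0L

  val_losses <- function(net) {
    pv <- predict(net, val, alleles)
    lr_ <- mse_loss(pv$log_ic50_pred, val$log_ic50)
    lc_ <- bce_loss(val$binary_label, pv$binding_prob)
    c(reg = lr_, cls = lc_, total = total_loss(lr_, lc_))
  }

  if (epochs >= 1L) withr::with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      ord <- if (batch_by == "allele") {
        blocks <- lapply(split(seq_len(n_tr), train$allele),
                         function(ix) ix[sample.int(length(ix))])
        unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
      } else {
        sample.int(n_tr)
      }
      starts <- seq.int(1L, n_tr, by = batch_size)
      ep_reg <- 0
      ep_cls <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n_tr)]
        nb <- length(idx)
        sub_of <- enc_tr$hla_of[idx]
        u <- sort(unique(sub_of))
        fw <- nn_forward(net, enc_tr$pep[idx, , , drop = FALSE],
                         enc_tr$hla[u, , , drop = FALSE],
                         match(sub_of, u),
                         training = TRUE, keep_caches = TRUE)
        net <- fw$net  # batch-norm running moments advance
        res_r <- fw$log_ic50_pred - y_r[idx]
        l_reg <- mean(res_r^2)
        l_cls <- bce_loss(y_c[idx], fw$binding_prob)
        ep_reg <- ep_reg + l_reg * nb
        ep_cls <- ep_cls + l_cls * nb
        grads <- nn_backward(net, fw,
                             dy_r = 2 * res_r / nb,
                             dz_c = (fw$binding_prob - y_c[idx]) / nb)
        for (nm in names(net$stacks)) {
          up <- stack_update(net$stacks[[nm]], grads[[nm]], vel[[nm]],
                             sched$lr, momentum)
          net$stacks[[nm]] <- up$layers
          vel[[nm]] <- up$vel
        }
      }
      vl <- val_losses(net)
      log_rows[[epoch]] <- tibble(
        epoch = epoch, learning_rate = sched$lr,
        train_reg = ep_reg / n_tr, train_cls = ep_cls / n_tr,
        train_total = (ep_reg + ep_cls) / n_tr,
        val_reg = vl[["reg"]], val_cls = vl[["cls"]], val_total = vl[["total"]]
      )
      n_epochs_run <- epoch
      if (verbose) {
        message(sprintf("epoch %3d lr %.2g train %.4f val %.4f",
                        epoch, sched$lr, (ep_reg + ep_cls) / n_tr, vl[["total"]]))
      }
      sched <- sched_observe(sched, vl[["total"]], improve_tol,
                             lr_patience, stop_patience, min_lr)
      if (sched$improved) {
        best <- list(net = net, val = vl[["total"]], epoch = epoch)
      }
      if (sched$stop) break
    }
  })

  if (!is.finite(best$val)) best <- list(net = net, val = NA_real_, epoch = 0L)
  structure(list(
    network = best$net,
    config = net$config,
    log = dplyr::bind_rows(log_rows[seq_len(n_epochs_run)]),
    best_epoch = best$epoch,
    best_val_loss = best$val,
    schedule = list(learning_rate = learning_rate, momentum = momentum,
                    min_lr = min_lr, lr_patience = lr_patience,
                    stop_patience = stop_patience, batch_size = batch_size,
                    improve_tol = improve_tol, epochs = epochs, seed = seed)
  ), class = "panbinder_fit")
}

#' @export
predict.panbinder_fit <- function(object, samples, alleles, ...) {
  predict(object$network, samples, alleles, ...)
}

#' Write a per-epoch training log to a tab-separated file
#'
#' @param fit A `panbinder_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(fit, path) {
  stopifnot(inherits(fit, "panbinder_fit"))
  readr::write_tsv(fit$log, path, progress = FALSE)
  invisible(path)
}

#' Save / load a fitted model checkpoint
#'
#' Serializes the fitted network (weights, batch-norm statistics, the
#' architecture config, the alphabet ordering and a format version) so that
#' `load_model(save_model(fit, path))` reproduces identical predictions.
#' The checkpoint is a binary RDS runtime artifact.
#'
#' @param fit A `panbinder_fit` or `panbinder_network`.
#' @param path Checkpoint path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored object.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "panbinder_fit") || inherits(fit, "panbinder_network"))
  saveRDS(list(format = "panbinder-checkpoint-1", alphabet = aa_alphabet(),
               object = fit), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "panbinder-checkpoint-1")) {
    abort("not a panbinder checkpoint", class = "panbinder_format_error")
  }
  if (!identical(x$alphabet, aa_alphabet())) {
    abort("checkpoint was written with a different alphabet ordering",
          class = "panbinder_format_error")
  }
  x$object
}
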