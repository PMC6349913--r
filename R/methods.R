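#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.panbinder_config <- function(x, ...) {
  cat("<panbinder_config> preset:", x$preset, "\n")
  cat("  peptide encoder filters:", paste(x$peptide_filters, collapse = " -> "), "\n")
  cat("  HLA encoder filters:    ", paste(x$hla_filters, collapse = " -> "), "\n")
  cat("  extractor filters:      ", paste(x$extractor_filters, collapse = " -> "),
      "(context length 2560)\n")
  cat("  head hidden units:", x$head_hidden_units,
      "| kernel width:", x$kernel_width,
      "| leaky slope:", x$leaky_slope,
      "| seed:", x$seed, "\n")
  invisible(x)
}

#' @export
print.panbinder_network <- function(x, ...) {
  n_par <- sum(vapply(x$stacks, stack_n_params, integer(1)))
  cat("<panbinder_network>", format(n_par, big.mark = ","),
      "trainable parameters (preset:", paste0(x$config$preset, ")\n"))
  invisible(x)
}

#' @export
print.panbinder_fit <- function(x, ...) {
  cat("<panbinder_fit>\n")
  cat("  epochs run:", nrow(x$log),
      "| best epoch:", x$best_epoch,
      "| best validation loss:", signif(x$best_val_loss, 5), "\n")
  invisible(x)
}

#' Tidy the per-epoch training log
#'
#' @param x A `panbinder_fit`.
#' @param ... Unused.
#' @return The training log as a tibble: epoch, learning rate, train and
#'   validation losses (total and per head).
#' @export
tidy.panbinder_fit <- function(x, ...) {
  x$log
}

#' One-row fit summary
#'
#' @param x A `panbinder_fit`.
#' @param ... Unused.
#' @return A one-row tibble: epochs run, best epoch, best validation loss
#'   (total and per head), final learning rate and parameter count.
#' @export
glance.panbinder_fit <- function(x, ...) {
  best <- x$log[x$log$epoch == x$best_epoch, , drop = FALSE]
  tibble(
    epochs = nrow(x$log),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    best_val_reg = if (nrow(best)) best$val_reg else NA_real_,
    best_val_cls = if (nrow(best)) best$val_cls else NA_real_,
    final_learning_rate = if (nrow(x$log)) x$log$learning_rate[nrow(x$log)] else NA_real_,
    n_params = sum(vapply(x$network$stacks, stack_n_params, integer(1)))
  )
}

#' Training-curve plot
#'
#' Train and validation total loss per epoch, with the best-validation epoch
#' marked.
#'
#' @param object A `panbinder_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.panbinder_fit <- function(object, ...) {
  df <- object$log |>
    tidyr::pivot_longer(c("train_total", "val_total"),
                        names_to = "set", values_to = "loss") |>
    dplyr::mutate(set = ifelse(.data$set == "train_total", "train", "validation"))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "total loss (MSE + BCE)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Dual-output correlation plot
#'
#' Scatter of predicted binding probability against predicted log IC50 —
#' the visual counterpart of [consistency_report()]. Well-trained heads
#' trace a decreasing sigmoid-like band crossing probability 0.5 near the
#' 500 nM line (`log(500) ~ 6.21`, drawn dashed).
#'
#' @param predictions Prediction tibble.
#' @return A ggplot object.
#' @export
plot_consistency <- function(predictions) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(.data$log_ic50_pred, .data$binding_prob)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_vline(xintercept = log(500), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "predicted log IC50", y = "predicted binding probability") +
    ggplot2::theme_minimal()
}

#' @export
print.panbinder_cv <- function(x, ...) {
  cat("<panbinder_cv>", x$k, "folds,", nrow(x$predictions), "pooled predictions\n")
  print(x$report[x$report$group_type != "allele", ])
  invisible(x)
}

#' @export
print.panbinder_loao <- function(x, ...) {
  cat("<panbinder_loao>", nrow(x$per_allele), "held-out alleles\n")
  print(x$per_allele)
  invisible(x)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>", nrow(x$samples), "samples,",
      length(x$alleles), "alleles; contact positions:",
      paste(x$model$contact_positions, collapse = ", "), "\n")
  invisible(x)
}
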