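# undefined metrics (single class, constant scores) become NA, quietly
metric_or_na <- function(expr) {
  tryCatch(suppressWarnings(expr), error = function(e) NA_real_)
}

hla_locus <- function(allele) {
  sub("^(HLA-[A-Za-z0-9]+)\\*.*$", "\\1", allele)
}

group_metrics <- function(rows) {
  truth_strength <- -rows$log_ic50  # larger = stronger binder
  tibble(
    n = nrow(rows),
    auc_affinity = metric_or_na(auc(-rows$log_ic50_pred, rows$binary_label)),
    srcc_affinity = metric_or_na(srcc(-rows$log_ic50_pred, truth_strength)),
    auc_prob = metric_or_na(auc(rows$binding_prob, rows$binary_label)),
    srcc_prob = metric_or_na(srcc(rows$binding_prob, truth_strength))
  )
}

#' Summarize predictions into an evaluation report
#'
#' Computes the evaluation metrics — AUC and Spearman rank correlation, each
#' on both the affinity output and the probability output — over all
#' samples, per HLA locus (the `HLA-A` / `HLA-B` / `HLA-C` prefix of the
#' allele name) and per allele. AUC uses the 0/1 binding labels; SRCC is
#' computed against the true binding strength (negated true log IC50, so
#' that positive values mean the output ranks binders correctly). Metrics
#' that are undefined for a group (a single label class, or a constant
#' score) are reported as `NA`.
#'
#' @param predictions Prediction tibble from [predict.panbinder_network()]
#'   whose rows carry the true labels (`log_ic50`, `binary_label`).
#' @return A tibble with columns `group_type` (`all` / `locus` / `allele`),
#'   `group`, `n` and the four metric columns.
#' @export
evaluate_predictions <- function(predictions) {
  stopifnot(is.data.frame(predictions))
  if (nrow(predictions) == 0L) {
    abort("no predictions to evaluate", class = "panbinder_size_error")
  }
  all_row <- dplyr::bind_cols(tibble(group_type = "all", group = "all"),
                              group_metrics(predictions))
  locus_rows <- predictions |>
    dplyr::mutate(.locus = hla_locus(.data$allele)) |>
    dplyr::group_by(.data$.locus) |>
    dplyr::group_modify(~ group_metrics(.x)) |>
    dplyr::ungroup() |>
    dplyr::rename(group = ".locus") |>
    dplyr::mutate(group_type = "locus", .before = 1L)
  allele_rows <- predictions |>
    dplyr::group_by(.data$allele) |>
    dplyr::group_modify(~ group_metrics(.x)) |>
    dplyr::ungroup() |>
    dplyr::rename(group = "allele") |>
    dplyr::mutate(group_type = "allele", .before = 1L)
  dplyr::bind_rows(all_row, locus_rows, allele_rows)
}

#' Dual-output consistency analysis
#'
#' Inspects the agreement between the two predictor heads on the same
#' binding context vector. A prediction row is *consistent* when its two
#' outputs indicate the same binding state: predicted IC50 at most 500 nM
#' versus predicted binding probability at least 0.5. A row is a *correct
#' IC50 prediction* when the predicted IC50's binding state matches the true
#' label, and a *correct binary prediction* when the probability's state
#' does. The report also quantifies the relation between the two outputs via
#' the Pearson correlation between predicted log IC50 and predicted
#' probability and a least-squares line `prob ~ log_ic50_pred` (strongly
#' negative correlation indicates the heads learned the same underlying
#' binding strength).
#'
#' @param predictions Prediction tibble carrying true labels
#'   (`binary_label`) plus `ic50_pred`, `log_ic50_pred`, `binding_prob`.
#' @return A one-row tibble: `n`, counts and fractions of consistent /
#'   correct-IC50 / correct-binary predictions, `pearson_r`, `slope`,
#'   `intercept`.
#' @export
consistency_report <- function(predictions) {
  stopifnot(is.data.frame(predictions))
  if (nrow(predictions) == 0L) {
    abort("no predictions to analyse", class = "panbinder_size_error")
  }
  bind_ic50 <- predictions$ic50_pred <= 500
  bind_prob <- predictions$binding_prob >= 0.5
  truth <- predictions$binary_label == 1
  consistent <- bind_ic50 == bind_prob
  correct_ic50 <- bind_ic50 == truth
  correct_binary <- bind_prob == truth
  fit <- lm(binding_prob ~ log_ic50_pred, data = predictions)
  tibble(
    n = nrow(predictions),
    consistent_n = sum(consistent),
    consistent_frac = mean(consistent),
    correct_ic50_n = sum(correct_ic50),
    correct_ic50_frac = mean(correct_ic50),
    correct_binary_n = sum(correct_binary),
    correct_binary_frac = mean(correct_binary),
    pearson_r = metric_or_na(cor(predictions$log_ic50_pred, predictions$binding_prob)),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1])
  )
}

#' Random k-fold cross-validation
#'
#' Partitions the samples into `k` random folds; for each fold a fresh
#' network is trained on the remaining folds (with an internal 4:1
#' train/validation split for the early-stopping schedule) and applied to
#' the held-out fold. Held-out predictions are pooled and summarized with
#' [evaluate_predictions()].
#'
#' @param samples Binding-sample tibble (needs training labels).
#' @param alleles Named character vector of aligned HLA sequences.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed driving the fold assignment, the per-fold
#'   internal splits and training.
#' @param config [network_config()] used for every fold.
#' @param epochs Epoch cap per fold; `0` evaluates the untrained networks.
#' @param ... Passed on to [train_network()].
#' @return A list of class `panbinder_cv` with `predictions` (pooled
#'   held-out predictions, with a `fold` column) and `report`.
#' @export
run_cv <- function(samples, alleles, k = 5L, seed = 1L,
                   config = network_config(), epochs = 500L, ...) {
  stopifnot(is.data.frame(samples))
  if (k < 2L) abort("k must be at least 2", class = "panbinder_size_error")
  n <- nrow(samples)
  if (n < k) abort("fewer samples than folds", class = "panbinder_size_error")
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    held <- samples[fold == f, , drop = FALSE]
    rest <- samples[fold != f, , drop = FALSE]
    fit <- fit_for_protocol(rest, alleles, config, epochs, seed + f, ...)
    preds[[f]] <- dplyr::mutate(predict(fit, held, alleles), fold = f)
  }
  predictions <- dplyr::bind_rows(preds)
  structure(list(predictions = predictions,
                 report = evaluate_predictions(predictions),
                 k = k, seed = seed),
            class = "panbinder_cv")
}

# shared by run_cv / run_loao: build, split 4:1, train (or return untrained)
fit_for_protocol <- function(train_pool, alleles, config, epochs, seed, ...) {
  cfg <- config
  cfg$seed <- as.integer(seed %% .Machine$integer.max)
  net <- build_network(cfg)
  if (epochs == 0L) {
    return(structure(list(network = net, config = cfg,
                          log = tibble(), best_epoch = 0L,
                          best_val_loss = NA_real_,
                          schedule = list(epochs = 0L, seed = seed)),
                     class = "panbinder_fit"))
  }
  sp <- split_train_val(train_pool, seed = seed)
  train_network(net, sp$train, sp$val, alleles, epochs = epochs, seed = seed, ...)
}

#' Leave-one-allele-out cross-validation
#'
#' For each allele in turn, all of its samples are held out, a fresh network
#' is trained on every other allele's samples, and the held-out allele is
#' scored — measuring generalization to HLA alleles never seen in training,
#' the defining capability of a pan-specific model.
#'
#' @inheritParams run_cv
#' @param hold_out Optional character vector naming the alleles to hold out
#'   in turn (a subset of the dataset's alleles); all of them by default.
#'   Training always uses every *other* allele's samples, so a subset runs
#'   fewer folds without changing what each fold trains on.
#' @return A list of class `panbinder_loao` with `per_allele` (one metric
#'   row per held-out allele) and `predictions` (pooled held-out
#'   predictions with a `held_out` column).
#' @export
run_loao <- function(samples, alleles, seed = 1L,
                     config = network_config(), epochs = 500L,
                     hold_out = NULL, ...) {
  folds <- loao_folds(samples)
  if (!is.null(hold_out)) {
    if (!all(hold_out %in% folds$allele)) {
      abort("hold_out names alleles absent from the dataset",
            class = "panbinder_fold_error")
    }
    folds <- folds[folds$allele %in% hold_out, , drop = FALSE]
  }
  preds <- vector("list", nrow(folds))
  for (i in seq_len(nrow(folds))) {
    fit <- fit_for_protocol(folds$train[[i]], alleles, config, epochs, seed + i, ...)
    preds[[i]] <- dplyr::mutate(predict(fit, folds$test[[i]], alleles),
                                held_out = folds$allele[i])
  }
  predictions <- dplyr::bind_rows(preds)
  per_allele <- predictions |>
    dplyr::group_by(.data$held_out) |>
    dplyr::group_modify(~ group_metrics(.x)) |>
    dplyr::ungroup() |>
    dplyr::rename(allele = "held_out")
  structure(list(per_allele = per_allele, predictions = predictions, seed = seed),
            class = "panbinder_loao")
}

#' Score a benchmark table dataset-by-dataset
#'
#' Benchmark tables mix measurement types; each (allele, measurement type)
#' combination is one benchmark dataset and is scored on the metrics its
#' type supports: `ic50` datasets get AUC (500 nM labels) and SRCC on both
#' outputs; `binary` datasets get AUC only; `t1/2` half-life datasets get
#' AUC via the 120-minute rule and SRCC against negated minutes (so that
#' larger means stronger binding, matching the affinity orientation).
#' Duplicate peptides within a dataset are dropped before scoring. Metrics
#' undefined for a dataset (e.g. a single label class) are `NA` and the run
#' continues.
#'
#' @param object A fitted `panbinder_fit` or `panbinder_network`.
#' @param benchmark Parsed benchmark samples (see [read_affinity_table()]).
#' @param alleles Named character vector of aligned HLA sequences.
#' @return A tibble with one row per (allele, measurement type) dataset:
#'   `n`, `auc_affinity`, `auc_prob`, `srcc_affinity`, `srcc_prob`.
#' @export
evaluate_benchmark <- function(object, benchmark, alleles) {
  stopifnot(is.data.frame(benchmark))
  benchmark <- benchmark[benchmark$allele %in% names(alleles), , drop = FALSE]
  if (nrow(benchmark) == 0L) {
    abort("no benchmark alleles overlap the allele index",
          class = "panbinder_coverage_error")
  }
  benchmark |>
    dplyr::group_by(.data$allele, .data$measurement_type) |>
    dplyr::group_modify(function(rows, key) {
      rows <- rows[!duplicated(rows$peptide), , drop = FALSE]
      pred <- predict(object, dplyr::mutate(rows, allele = key$allele), alleles)
      strength <- switch(key$measurement_type,
        ic50 = -pred$log_ic50,            # true log IC50, negated
        t_half = -pred$measurement_value, # negated minutes
        NULL)
      tibble(
        n = nrow(pred),
        auc_affinity = metric_or_na(auc(-pred$log_ic50_pred, pred$binary_label)),
        auc_prob = metric_or_na(auc(pred$binding_prob, pred$binary_label)),
        srcc_affinity = if (is.null(strength)) NA_real_ else
          metric_or_na(srcc(-pred$log_ic50_pred, strength)),
        srcc_prob = if (is.null(strength)) NA_real_ else
          metric_or_na(srcc(pred$binding_prob, strength))
      )
    }) |>
    dplyr::ungroup()
}
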