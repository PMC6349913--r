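#' Area under the ROC curve
#'
#' Mann–Whitney formulation: the probability that a uniformly drawn positive
#' sample outscores a uniformly drawn negative one, with ties counted as
#' one half. Computed from mean ranks, which is exactly equivalent to
#' brute-force counting over all positive–negative pairs.
#'
#' @param scores Numeric vector; larger = more likely positive.
#' @param labels Vector of 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("scores and labels differ in length", class = "panbinder_shape_error")
  }
  stopifnot(all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC is undefined when only one class is present",
          class = "panbinder_undefined_metric")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of the two rank vectors, with ties assigned mean
#' ranks. On tie-free data this equals the classical
#' `1 - 6 * sum(d^2) / (n * (n^2 - 1))` formula.
#'
#' @param x,y Numeric vectors of equal length >= 2, neither constant.
#' @return SRCC in \[-1, 1\].
#' @examples
#' srcc(1:4, c(1, 3, 2, 4))  # 0.8
#' @export
srcc <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y differ in length", class = "panbinder_shape_error")
  }
  stopifnot(length(x) >= 2L)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("SRCC is undefined for a constant vector",
          class = "panbinder_undefined_metric")
  }
  cor(rx, ry)
}

#' Orient predictions as classification scores
#'
#' AUC needs scores where larger means "more likely a binder". The
#' probability head already has that orientation; the affinity head predicts
#' log IC50 where *lower* means stronger binding, so its score is the
#' negated predicted log IC50. (AUC is rank-based, so any strictly monotone
#' decreasing transform of IC50 gives the identical value.)
#'
#' @param predictions Tibble with `log_ic50_pred` and `binding_prob`
#'   columns (from [predict.panbinder_network()]).
#' @return The tibble with `affinity_score` and `prob_score` appended.
#' @export
score_direction <- function(predictions) {
  stopifnot(is.data.frame(predictions))
  predictions |>
    dplyr::mutate(affinity_score = -.data$log_ic50_pred,
                  prob_score = .data$binding_prob)
}
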