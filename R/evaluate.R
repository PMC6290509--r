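# Metrics for imbalanced probabilistic binary prediction.
#
# Tie conventions, fixed package-wide:
#  - Average precision treats a run of equal scores as a block and reports
#    the expected AP over random orderings of the block (closed form below).
#  - AUROC gives half credit to tied positive-negative pairs (Mann-Whitney).
#  - PR points are computed once per distinct threshold, so a tied block
#    enters the curve as a single step.

check_scores_labels <- function(scores, labels, need_positive = TRUE,
                                need_both = FALSE) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (need_positive && sum(labels == 1) == 0) {
    stop("no positive labels", call. = FALSE)
  }
  if (need_both && (sum(labels == 1) == 0 || sum(labels == 0) == 0)) {
    stop("both classes must be present", call. = FALSE)
  }
  invisible(TRUE)
}

#' Average precision
#'
#' Mean, over the positives in descending-score order, of the precision at
#' each positive's rank. Ties are handled as blocks: the value returned is
#' the exact expectation of AP over uniformly random orderings of each run
#' of equal scores.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels 0/1 labels; at least one positive required.
#' @return AP in (0, 1].
#' @export
average_precision <- function(scores, labels) {
  check_scores_labels(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- unname(scores[ord])
  l <- unname(labels[ord])
  n_pos <- sum(l == 1)
  blocks <- rle(s)
  ends <- cumsum(blocks$lengths)
  starts <- ends - blocks$lengths + 1L
  total <- 0
  p0 <- 0   # positives in strictly higher blocks
  s0 <- 0L  # items in strictly higher blocks
  for (bi in seq_along(starts)) {
    b <- blocks$lengths[bi]
    k <- sum(l[starts[bi]:ends[bi]] == 1)
    if (k > 0) {
      if (b == 1L) {
        total <- total + (p0 + 1) / (s0 + 1)
      } else {
        t <- seq_len(b)
        # P(slot t holds a positive) = k/b; conditional expected positives at
        # or above slot t is 1 + (k-1)(t-1)/(b-1)
        exp_prec <- (k / b) * (p0 + 1 + (k - 1) * (t - 1) / (b - 1)) / (s0 + t)
        total <- total + sum(exp_prec)
      }
    }
    p0 <- p0 + k
    s0 <- s0 + b
  }
  total / n_pos
}

#' Area under the ROC curve
#'
#' The Mann-Whitney statistic: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, with ties counted 1/2.
#'
#' @inheritParams average_precision
#' @param labels 0/1 labels; both classes required.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  check_scores_labels(scores, labels, need_both = TRUE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and outcome.
#'
#' @param scores Probabilities in [0, 1].
#' @param labels 0/1 labels.
#' @return Brier score in [0, 1]; lower is better.
#' @export
brier <- function(scores, labels) {
  check_scores_labels(scores, labels, need_positive = FALSE)
  if (any(scores < 0 | scores > 1)) stop("scores must be in [0,1]", call. = FALSE)
  mean((scores - labels)^2)
}

#' Interpolated precision-recall curve
#'
#' Raw precision/recall at every distinct score threshold, plus the standard
#' information-retrieval interpolation: interpolated precision at recall r is
#' the maximum precision attained at any recall >= r, which makes the
#' interpolated curve non-increasing.
#'
#' @inheritParams average_precision
#' @return A `pr_curve`: tibble `threshold`, `recall`, `precision`,
#'   `interpolated_precision`, ordered by increasing recall.
#' @export
interpolated_pr <- function(scores, labels) {
  check_scores_labels(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  tp <- vapply(thr, function(t) sum(labels == 1 & scores >= t), 0)
  npred <- vapply(thr, function(t) sum(scores >= t), 0)
  out <- tibble::tibble(
    threshold = thr,
    recall = tp / n_pos,
    precision = tp / npred
  )
  out <- dplyr::arrange(out, .data$recall, .data$precision)
  # running max of precision from the high-recall end; sorting ties by
  # ascending precision makes every point at the same recall share the max
  out$interpolated_precision <- rev(cummax(rev(out$precision)))
  structure(out, class = c("pr_curve", class(out)))
}

#' Interpolated precision at a recall level
#'
#' @param pr A `pr_curve` from [interpolated_pr()].
#' @param recall Recall levels in [0, 1].
#' @return Interpolated precision: max precision over curve points with
#'   recall at least the requested level; `NA` beyond the maximum recall
#'   (which only occurs if the curve lacks a recall-1 point).
#' @export
precision_at_recall <- function(pr, recall) {
  vapply(recall, function(r) {
    ok <- pr$recall >= r - 1e-12
    if (!any(ok)) return(NA_real_)
    max(pr$interpolated_precision[ok])
  }, 0)
}

#' Recall at a precision target
#'
#' The largest recall whose interpolated precision still meets `target`;
#' 0 when the curve never reaches the target.
#'
#' @param pr A `pr_curve` from [interpolated_pr()].
#' @param target Precision target in (0, 1].
#' @return Recall in [0, 1].
#' @export
recall_at_precision <- function(pr, target = 0.9) {
  stopifnot(target > 0, target <= 1)
  ok <- pr$interpolated_precision >= target - 1e-12
  if (!any(ok)) return(0)
  max(pr$recall[ok])
}

#' Reliability (calibration) curve
#'
#' Equal-width, right-closed probability bins on [0, 1] (scores of 0 fall in
#' the first bin). Per bin: count, mean predicted probability, and observed
#' positive fraction. Empty bins are kept and flagged rather than dropped.
#'
#' @param scores Probabilities in [0, 1].
#' @param labels 0/1 labels.
#' @param n_bins Number of bins, default 10.
#' @return A `reliability_bins` tibble: `bin`, `lower`, `upper`, `n`,
#'   `mean_score`, `event_rate`, `empty`.
#' @export
reliability_curve <- function(scores, labels, n_bins = 10L) {
  check_scores_labels(scores, labels, need_positive = FALSE)
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  if (any(scores < 0 | scores > 1)) stop("scores must be in [0,1]", call. = FALSE)
  bin <- pmin(pmax(ceiling(scores * n_bins), 1L), n_bins)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, score = scores, label = labels),
                    .data$bin),
    n = dplyr::n(), mean_score = mean(.data$score),
    event_rate = mean(.data$label), .groups = "drop"
  )
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    lower = (seq_len(n_bins) - 1) / n_bins,
    upper = seq_len(n_bins) / n_bins
  )
  out <- dplyr::left_join(out, agg, by = "bin")
  out <- dplyr::mutate(out,
                       n = ifelse(is.na(.data$n), 0L, .data$n),
                       empty = .data$n == 0L)
  structure(out, class = c("reliability_bins", class(out)))
}

#' Evaluate probabilistic predictions
#'
#' Computes the full report for one set of predictions: raw average
#' precision, AUROC, Brier score, the interpolated precision-recall curve,
#' recall at each requested precision target, and the reliability curve.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels (both classes required).
#' @param precision_targets Precision levels for recall-at-precision,
#'   default 0.9.
#' @param n_bins Reliability bins, default 10.
#' @return An `evaluation_report` with elements `ap`, `auroc`, `brier`,
#'   `recall_at_precision` (named vector), `pr` and `reliability`.
#' @export
evaluate_predictions <- function(scores, labels, precision_targets = 0.9,
                                 n_bins = 10L) {
  check_scores_labels(scores, labels, need_both = TRUE)
  pr <- interpolated_pr(scores, labels)
  rap <- vapply(precision_targets, function(t) recall_at_precision(pr, t), 0)
  names(rap) <- format(precision_targets)
  structure(list(
    ap = average_precision(scores, labels),
    auroc = auroc(scores, labels),
    brier = brier(scores, labels),
    recall_at_precision = rap,
    pr = pr,
    reliability = reliability_curve(scores, labels, n_bins),
    n = length(scores),
    prevalence = mean(labels)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> n = ", x$n,
      sprintf(" (prevalence %.3f)\n", x$prevalence),
      sprintf("  AP    %.4f\n", x$ap),
      sprintf("  AUROC %.4f\n", x$auroc),
      sprintf("  Brier %.4f\n", x$brier), sep = "")
  for (t in names(x$recall_at_precision)) {
    cat(sprintf("  recall at %s precision: %.4f\n", t,
                x$recall_at_precision[[t]]))
  }
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return Long tibble `metric`, `value`.
#' @export
tidy.evaluation_report <- function(x, ...) {
  tibble::tibble(
    metric = c("ap", "auroc", "brier",
               paste0("recall_at_precision_", names(x$recall_at_precision))),
    value = c(x$ap, x$auroc, x$brier, unname(x$recall_at_precision))
  )
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(n = x$n, prevalence = x$prevalence, ap = x$ap,
                 auroc = x$auroc, brier = x$brier)
}

#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$interpolated_precision),
                       direction = "vh") +
    ggplot2::geom_point(ggplot2::aes(y = .data$precision), alpha = 0.4) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  title = "Interpolated precision-recall curve") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.reliability_bins <- function(object, ...) {
  occ <- object[!object$empty, ]
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$mean_score, y = .data$event_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "mean predicted probability", y = "observed event rate",
                  title = "Reliability curve") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.evaluation_report <- function(object, ...) {
  autoplot(object$pr)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  out <- list(
    ap = report$ap, auroc = report$auroc, brier = report$brier,
    recall_at_precision = as.list(report$recall_at_precision),
    n = report$n, prevalence = report$prevalence,
    pr = as.data.frame(report$pr),
    reliability = as.data.frame(report$reliability)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
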