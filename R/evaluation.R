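#' Multi-label ranking loss
#'
#' For each bag whose relevant label set is neither empty nor full, the
#' fraction of (relevant, irrelevant) label pairs where the relevant label's
#' confidence does not exceed the irrelevant one's; ties count as
#' misordered (the pessimistic convention, so reported scores never flatter
#' a method). Bags with empty or full label sets are skipped; the mean over
#' the remaining bags is returned.
#'
#' @param confidences `n x K` real matrix of per-class confidences.
#' @param Y `n x K` binary relevance matrix.
#' @return scalar in `[0, 1]`; invariant under strictly monotone transforms
#'   of the confidences.
#' @export
ranking_loss <- function(confidences, Y) {
  check_eval_shapes(confidences, Y)
  K <- ncol(Y)
  per_bag <- vapply(seq_len(nrow(Y)), function(i) {
    rel <- which(Y[i, ] == 1)
    irr <- which(Y[i, ] == 0)
    if (!length(rel) || !length(irr)) return(NA_real_)
    bad <- sum(outer(confidences[i, rel], confidences[i, irr], "<="))
    bad / (length(rel) * length(irr))
  }, numeric(1))
  if (all(is.na(per_bag))) {
    stop("ranking loss undefined: every bag has an empty or full label set")
  }
  mean(per_bag, na.rm = TRUE)
}

#' Multi-label coverage
#'
#' How far down the confidence-ranked label list one must go to cover all
#' relevant labels, averaged over bags: `max rank of a relevant label - 1`,
#' with rank 1 the highest confidence and ties assigned the worst (largest)
#' rank in the tied group. Bags with no relevant label contribute 0.
#'
#' @inheritParams ranking_loss
#' @return scalar in `[0, K - 1]`.
#' @export
coverage <- function(confidences, Y) {
  check_eval_shapes(confidences, Y)
  per_bag <- vapply(seq_len(nrow(Y)), function(i) {
    rel <- which(Y[i, ] == 1)
    if (!length(rel)) return(0)
    h <- confidences[i, ]
    worst_rank <- max(vapply(rel, function(y) sum(h >= h[y]), numeric(1)))
    worst_rank - 1
  }, numeric(1))
  mean(per_bag)
}

#' Set-based average recall, precision and F1
#'
#' `avg_recall` averages `|h(X) intersect Y| / |Y|` over bags with at least
#' one relevant label; `avg_precision` averages `|h(X) intersect Y| / |h(X)|`
#' over bags with at least one predicted label; `avg_f1` is the harmonic
#' mean of the two averaged values (0 when both are 0).
#'
#' @param pred_labels `n x K` binary predictions.
#' @param Y `n x K` binary relevance matrix.
#' @return named vector `c(avg_recall, avg_precision, avg_f1)`.
#' @export
set_metrics <- function(pred_labels, Y) {
  check_eval_shapes(pred_labels, Y)
  inter <- rowSums(pred_labels * Y)
  n_rel <- rowSums(Y)
  n_pred <- rowSums(pred_labels)
  if (!any(n_rel > 0)) stop("average recall undefined: no bag has a relevant label")
  rec <- mean(inter[n_rel > 0] / n_rel[n_rel > 0])
  prec <- if (any(n_pred > 0)) mean(inter[n_pred > 0] / n_pred[n_pred > 0]) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(avg_recall = rec, avg_precision = prec, avg_f1 = f1)
}

check_eval_shapes <- function(a, b) {
  if (!all(dim(as.matrix(a)) == dim(as.matrix(b)))) {
    stop("confidence/label matrices must have matching shapes")
  }
}

eval_all_metrics <- function(confidences, pred_labels, Y) {
  c(ranking_loss = ranking_loss(confidences, Y),
    coverage = coverage(confidences, Y),
    set_metrics(pred_labels, Y))
}

#' Friedman/Nemenyi average-rank comparison of methods over datasets
#'
#' Ranks the methods on every dataset (ties averaged; rank 1 is best),
#' computes average ranks and the Friedman chi-square statistic, and the
#' Nemenyi critical distance `CD = q_alpha sqrt(m (m + 1) / (6 N))` with
#' the studentized-range constant `q_alpha = qtukey(1 - alpha, m, Inf) /
#' sqrt(2)`. Method pairs whose average ranks differ by at least `CD` are
#' flagged significantly different.
#'
#' @param score_matrix `N datasets x m methods` numeric matrix.
#' @param higher_is_better direction of the score.
#' @param alpha significance level (default 0.05).
#' @return Object of class `mimtl_rank_table`: per-dataset `ranks`,
#'   `avg_ranks`, `cd`, `q_alpha`, Friedman `statistic` and `p_value`, and
#'   a logical `significant` matrix over method pairs.
#' @export
friedman_nemenyi <- function(score_matrix, higher_is_better = TRUE,
                             alpha = 0.05) {
  S <- as.matrix(score_matrix)
  N <- nrow(S); m <- ncol(S)
  if (N < 2L || m < 2L) stop("need at least 2 datasets and 2 methods")
  if (is.null(colnames(S))) colnames(S) <- paste0("method", seq_len(m))
  ranks <- t(apply(S, 1L, function(row) {
    rank(if (higher_is_better) -row else row, ties.method = "average")
  }))
  colnames(ranks) <- colnames(S)
  avg <- colMeans(ranks)
  stat <- 12 * N / (m * (m + 1)) * (sum(avg^2) - m * (m + 1)^2 / 4)
  p <- pchisq(stat, df = m - 1, lower.tail = FALSE)
  q_alpha <- qtukey(1 - alpha, m, Inf) / sqrt(2)
  cd <- q_alpha * sqrt(m * (m + 1) / (6 * N))
  sig <- abs(outer(avg, avg, "-")) >= cd
  diag(sig) <- FALSE
  structure(list(ranks = ranks, avg_ranks = avg, cd = cd, q_alpha = q_alpha,
                 statistic = stat, p_value = p, alpha = alpha,
                 significant = sig),
            class = "mimtl_rank_table")
}

#' @export
print.mimtl_rank_table <- function(x, ...) {
  cat("Friedman/Nemenyi average-rank comparison\n")
  cat(sprintf("  chi^2 = %.4g (p = %.4g), CD(alpha = %g) = %.4g\n",
              x$statistic, x$p_value, x$alpha, x$cd))
  print(round(x$avg_ranks, 3))
  invisible(x)
}
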