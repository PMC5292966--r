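# Minimal deterministic SMO solver for soft-margin kernel SVM (C-SVC).
# No SVM library is assumed; sample sizes here are a few hundred bags at
# most, so a dense-kernel maximal-violating-pair SMO is adequate.

rbf_kernel_matrix <- function(X, Y, gamma) {
  sq <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(sq, 0))
}

#' Train a soft-margin kernel SVM by sequential minimal optimization
#'
#' Solves the C-SVC dual `min 1/2 a'Qa - e'a` s.t. `0 <= a <= C`,
#' `y'a = 0` (`Q_ij = y_i y_j K_ij`) with maximal-violating-pair working-set
#' selection; deterministic for a given kernel matrix.
#'
#' @param K symmetric kernel matrix of the training points.
#' @param y labels in `{-1, +1}`.
#' @param cost box constraint `C`.
#' @param tol KKT gap stopping tolerance.
#' @param max_iter cap on pair updates.
#' @return list with `alpha`, `b`, `y`, `kkt_gap`, `iterations`; decision
#'   values on new points with kernel rows `Knew` are
#'   `Knew %*% (alpha * y) + b`.
#' @export
svm_smo <- function(K, y, cost = 1, tol = 1e-4, max_iter = 20000L) {
  n <- length(y)
  stopifnot(all(dim(K) == n), all(y %in% c(-1, 1)))
  alpha <- numeric(n)
  G <- rep(-1, n)                        # gradient of the dual objective
  Q <- K * tcrossprod(y)
  it <- 0L
  gap <- Inf
  while (it < max_iter) {
    up <- (y == 1 & alpha < cost) | (y == -1 & alpha > 0)
    low <- (y == -1 & alpha < cost) | (y == 1 & alpha > 0)
    yg <- -y * G
    m_up <- max(yg[up])
    m_low <- min(yg[low])
    gap <- m_up - m_low
    if (gap < tol) break
    i <- which(up)[which.max(yg[up])]
    j <- which(low)[which.min(yg[low])]
    a <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (a <= 0) a <- 1e-12
    old_i <- alpha[i]; old_j <- alpha[j]
    if (y[i] != y[j]) {
      delta <- (-G[i] - G[j]) / a
      diff <- alpha[i] - alpha[j]
      alpha[i] <- alpha[i] + delta
      alpha[j] <- alpha[j] + delta
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- diff }
      } else {
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- -diff }
      }
      if (diff > 0) {
        if (alpha[i] > cost) { alpha[i] <- cost; alpha[j] <- cost - diff }
      } else {
        if (alpha[j] > cost) { alpha[j] <- cost; alpha[i] <- cost + diff }
      }
    } else {
      delta <- (G[i] - G[j]) / a
      ssum <- alpha[i] + alpha[j]
      alpha[i] <- alpha[i] - delta
      alpha[j] <- alpha[j] + delta
      if (ssum > cost) {
        if (alpha[i] > cost) { alpha[i] <- cost; alpha[j] <- ssum - cost }
        if (alpha[j] > cost) { alpha[j] <- cost; alpha[i] <- ssum - cost }
      } else {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- ssum }
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- ssum }
      }
    }
    G <- G + Q[, i] * (alpha[i] - old_i) + Q[, j] * (alpha[j] - old_j)
    it <- it + 1L
  }
  free <- alpha > 1e-12 & alpha < cost - 1e-12
  fx <- as.vector(K %*% (alpha * y))
  b <- if (any(free)) mean(y[free] - fx[free]) else {
    up <- (y == 1 & alpha < cost) | (y == -1 & alpha > 0)
    low <- (y == -1 & alpha < cost) | (y == 1 & alpha > 0)
    yg <- -y * G
    (max(yg[up]) + min(yg[low])) / 2
  }
  list(alpha = alpha, b = b, y = y, kkt_gap = gap, iterations = it)
}

svm_decision <- function(model, Knew) {
  as.vector(Knew %*% (model$alpha * model$y)) + model$b
}
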