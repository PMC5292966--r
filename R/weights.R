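#' Normalized multi-instance set kernel between two bags
#'
#' The MI-kernel sums an RBF instance kernel over all cross-bag instance
#' pairs, `S(X, Y) = sum_{x in X} sum_{y in Y} exp(-gamma ||x - y||^2)`, and
#' is normalized as `k(X, Y) = S(X, Y) / sqrt(S(X, X) S(Y, Y))` so that
#' `k(X, X) = 1` and bag size does not set the scale. The unnormalized sum
#' is available with `normalize = FALSE`.
#'
#' @param bagX,bagY bags of equal instance dimension.
#' @param gamma positive RBF width.
#' @param normalize logical; default `TRUE`.
#' @return Scalar in `(0, 1]` (normalized) or `(0, Inf)` (unnormalized).
#' @export
mi_kernel <- function(bagX, bagY, gamma, normalize = TRUE) {
  if (gamma <= 0) stop("gamma must be positive")
  if (bag_dim(bagX) != bag_dim(bagY)) stop("bags have different dimensions")
  s <- rbf_sum(bagX$instances, bagY$instances, gamma)
  if (!normalize) return(s)
  s / sqrt(rbf_sum(bagX$instances, bagX$instances, gamma) *
           rbf_sum(bagY$instances, bagY$instances, gamma))
}

rbf_sum <- function(X, Y, gamma) {
  sq <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  sum(exp(-gamma * pmax(sq, 0)))
}

#' Basis configuration for density-ratio fitting
#'
#' @param basis_bags list of bags serving as kernel centers (size `p`).
#' @param gamma positive MI-kernel width.
#' @param ridge non-negative conditioning constant added to the diagonal of
#'   the system matrix.
#' @param normalize use the normalized MI-kernel (default).
#' @return Object of class `mimtl_basis`.
#' @export
basis_config <- function(basis_bags, gamma, ridge = 1e-6, normalize = TRUE) {
  if (length(basis_bags) < 1L) stop("need at least one basis bag")
  if (gamma <= 0) stop("gamma must be positive")
  if (ridge < 0) stop("ridge must be non-negative")
  structure(list(basis_bags = basis_bags, gamma = gamma, ridge = ridge,
                 normalize = normalize),
            class = "mimtl_basis")
}

psi_matrix <- function(bags, basis) {
  vapply(basis$basis_bags,
         function(bb) vapply(bags, mi_kernel, numeric(1),
                             bagY = bb, gamma = basis$gamma,
                             normalize = basis$normalize),
         numeric(length(bags)))
}

#' Build the least-squares density-ratio system
#'
#' Assembles `B = (1/n_src) sum_{X in SD} psi(X) psi(X)' + ridge I` and
#' `b = (1/n_tgt) sum_{X in TD} psi(X)`, where `psi_j(X)` is the MI-kernel
#' between bag `X` and the j-th basis bag. Minimizing
#' `alpha' B alpha / 2 - b' alpha` over `alpha >= 0` fits the bag importance
#' weights `w(X) = P'(X)/P(X) ~ sum_j alpha_j psi_j(X)`.
#'
#' @param source_bags,target_bags nonempty lists of bags.
#' @param basis a [basis_config()].
#' @return list with `B` (`p x p`, symmetric PSD; PD when `ridge > 0`) and
#'   `b` (`p`-vector).
#' @export
build_weight_system <- function(source_bags, target_bags, basis) {
  if (!length(source_bags) || !length(target_bags)) {
    stop("both domains must be nonempty")
  }
  p <- length(basis$basis_bags)
  Psi_s <- matrix(psi_matrix(source_bags, basis), ncol = p)
  Psi_t <- matrix(psi_matrix(target_bags, basis), ncol = p)
  B <- crossprod(Psi_s) / length(source_bags) + diag(basis$ridge, p)
  list(B = (B + t(B)) / 2, b = colMeans(Psi_t))
}

#' Non-negative quadratic program for the basis coefficients
#'
#' Minimizes `alpha' B alpha / 2 - b' alpha` subject to `alpha >= 0` by
#' projected gradient descent with backtracking from a zero start; the
#' objective is non-increasing across iterations and the exit point
#' satisfies the KKT conditions to within `tol`.
#'
#' @param B symmetric positive semidefinite matrix.
#' @param b vector.
#' @param max_iter iteration cap.
#' @param tol KKT residual tolerance.
#' @return Non-negative coefficient vector `alpha`.
#' @export
fit_bag_weights <- function(B, b, max_iter = 2000L, tol = 1e-8) {
  B <- as.matrix(B)
  p <- length(b)
  stopifnot(all(dim(B) == p))
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (min(ev) < -1e-8 * scale) stop("B is not positive semidefinite")
  alpha <- numeric(p)
  step <- 1 / max(ev[1L], .Machine$double.eps)
  obj <- function(a) 0.5 * sum(a * (B %*% a)) - sum(b * a)
  f <- obj(alpha)
  for (it in seq_len(max_iter)) {
    g <- as.vector(B %*% alpha - b)
    kkt <- max(abs(g[alpha > 0]), pmax(0, -g[alpha == 0]), 0)
    if (kkt <= tol) break
    s <- step
    repeat {
      cand <- pmax(0, alpha - s * g)
      fc <- obj(cand)
      if (fc <= f || s < 1e-16) break
      s <- s / 2
    }
    if (fc > f) break   # no descent possible at machine precision
    alpha <- cand
    f <- fc
  }
  alpha
}

#' Median-heuristic MI-kernel width
#'
#' `gamma = 1 / median(pairwise distance between bag means)^2`, computed
#' over the pooled source and target bags.
#'
#' @param bags list of bags.
#' @return positive scalar.
#' @export
median_heuristic_gamma <- function(bags) {
  M <- bag_means(bags)
  med <- median(dist(M))
  if (!is.finite(med) || med <= 0) return(1)
  1 / med^2
}

#' Estimate bag importance weights by density-ratio least squares
#'
#' Selects up to `basis_size` target bags uniformly at random (under `seed`)
#' as kernel centers, builds the system with [build_weight_system()], solves
#' the non-negative least-squares problem, and evaluates
#' `w_i = sum_j alpha_j psi_j(X_i)` for every source bag. All weights are
#' non-negative since `alpha >= 0` and the kernel is positive.
#'
#' @param source,target nonempty [miml_dataset()]s of equal dimension.
#' @param basis_size number of basis bags (capped at `n_target`).
#' @param gamma MI-kernel width, or `NULL` for the median heuristic on the
#'   pooled bag means.
#' @param ridge conditioning constant (default `1e-6`).
#' @param normalize_omega if `TRUE`, rescale weights to unit mean over the
#'   source domain (off by default; it alters the lambda/beta trade-off in
#'   the downstream metric objective, so it is explicit).
#' @param seed seed for the basis subsample.
#' @return Object of class `mimtl_importance`: fields `alpha`, `basis`,
#'   `omega` (one non-negative weight per source bag), `gamma`.
#' @export
estimate_weights <- function(source, target, basis_size = 100L, gamma = NULL,
                             ridge = 1e-6, normalize_omega = FALSE,
                             seed = 1L) {
  stopifnot(inherits(source, "mimtl_dataset"), inherits(target, "mimtl_dataset"))
  if (source$d != target$d) stop("source and target dimensions differ")
  if (is.null(gamma)) {
    gamma <- median_heuristic_gamma(c(source$bags, target$bags))
  }
  p <- min(basis_size, n_bags(target))
  set.seed(as.integer(seed))
  idx <- sort(sample.int(n_bags(target), p))
  basis <- basis_config(target$bags[idx], gamma = gamma, ridge = ridge)
  sys <- build_weight_system(source$bags, target$bags, basis)
  alpha <- fit_bag_weights(sys$B, sys$b)
  omega <- as.vector(matrix(psi_matrix(source$bags, basis), ncol = p) %*% alpha)
  if (normalize_omega && mean(omega) > 0) omega <- omega / mean(omega)
  structure(list(alpha = alpha, basis = basis, omega = omega, gamma = gamma,
                 basis_indices = idx),
            class = "mimtl_importance")
}

#' @export
print.mimtl_importance <- function(x, ...) {
  cat(sprintf("<mimtl_importance: p = %d basis bags, gamma = %.4g, mean(omega) = %.4g>\n",
              length(x$alpha), x$gamma, mean(x$omega)))
  invisible(x)
}
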