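#' Squared Mahalanobis distance between two vectors
#'
#' `D(u, v) = (u - v)' A'A (u - v) = ||A (u - v)||^2`. Parameterizing the
#' metric by the linear map `A` keeps `M = A'A` positive semidefinite at
#' every iterate without an explicit projection.
#'
#' @param u,v numeric vectors of equal length.
#' @param A `d x d` matrix.
#' @return Non-negative scalar; 0 when `u == v`.
#' @export
mahalanobis_sq <- function(u, v, A) {
  if (length(u) != length(v) || ncol(A) != length(u)) {
    stop("dimension mismatch in mahalanobis_sq")
  }
  w <- A %*% (u - v)
  sum(w * w)
}

#' Squared Mahalanobis distance between two bags
#'
#' Bags are represented by their instance means; the distance is
#' [mahalanobis_sq()] between the means, hence symmetric.
#'
#' @param bagX,bagY bags of equal dimension.
#' @param A `d x d` matrix.
#' @return Non-negative scalar.
#' @export
bag_distance <- function(bagX, bagY, A) {
  mahalanobis_sq(bag_mean(bagX), bag_mean(bagY), A)
}

#' Hyperparameters for the per-class metric objective
#'
#' @param lambda,beta non-negative balance weights on the within-bag and
#'   between-class slack sums (both default 1, the configuration used on the
#'   organism benchmarks).
#' @param delta_s,delta_d within-bag radius and between-class margin
#'   (`delta_s < delta_d`), both unitless squared distances. `NULL` (the
#'   default) sets `delta_s` to the median within-bag instance-to-center
#'   squared distance and `delta_d` to the median between-class bag distance
#'   at `A = I`, clamped so `delta_s < delta_d`.
#' @param sigma positive penalty coefficient of the one-sided quadratic
#'   constraint penalties.
#' @param epsilon convergence threshold on `|f_t - f_{t-1}|`.
#' @param step_a,step_xi,step_zeta base gradient step sizes for `A` and the
#'   two slack vectors; a shared backtracking multiplier rescales all three.
#' @param max_iter iteration cap.
#' @param max_pairs cap on between-class bag pairs; larger constraint sets
#'   are down-sampled uniformly under `seed`.
#' @param sigma_continuation if `TRUE`, multiply `sigma` by 10 and continue
#'   optimizing whenever the inner loop converges with residual constraint
#'   violation (off by default; `sigma` is fixed).
#' @param seed integer seed (pair down-sampling).
#' @return Object of class `mimtl_hyperparams`.
#' @export
metric_hyperparams <- function(lambda = 1, beta = 1, delta_s = NULL,
                               delta_d = NULL, sigma = 10, epsilon = 1e-5,
                               step_a = 0.01, step_xi = 0.01,
                               step_zeta = 0.01, max_iter = 2000L,
                               max_pairs = 5000L, sigma_continuation = FALSE,
                               seed = 1L) {
  if (lambda < 0 || beta < 0) stop("lambda and beta must be non-negative")
  if (sigma <= 0) stop("sigma must be positive")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (!is.null(delta_s) && !is.null(delta_d) && delta_s >= delta_d) {
    stop("need delta_s < delta_d")
  }
  structure(list(lambda = lambda, beta = beta, delta_s = delta_s,
                 delta_d = delta_d, sigma = sigma, epsilon = epsilon,
                 step_a = step_a, step_xi = step_xi, step_zeta = step_zeta,
                 max_iter = as.integer(max_iter),
                 max_pairs = as.integer(max_pairs),
                 sigma_continuation = sigma_continuation,
                 seed = as.integer(seed)),
            class = "mimtl_hyperparams")
}

#' Build the weighted constraint set for one class
#'
#' Within-bag constraints `D(x, c_i) <= delta_s + xi` are enumerated for
#' every (bag, instance) of every training bag, each carrying its bag's
#' importance weight (labeled target-domain bags carry weight exactly 1).
#' Between-class constraints `D(X_i, X_j) >= delta_d - zeta_ij` pair every
#' positive bag with every negative bag for `class_k`, weighted by the
#' product `w_i w_j` (the expected pairwise loss over independent draws
#' factorizes into the product of marginal density ratios); pairs beyond
#' `max_pairs` are down-sampled uniformly under the hyperparameter seed.
#' With `td_labeled = NULL` the source-only formulation is reproduced
#' exactly.
#'
#' @param train source-domain [miml_dataset()].
#' @param class_k class identifier present in `train$class_ids`.
#' @param omega per-source-bag weights (`NULL` for all ones).
#' @param td_labeled optional labeled target-domain dataset (weights 1), or
#'   `NULL`.
#' @param hyperparams a [metric_hyperparams()].
#' @return Object of class `mimtl_constraints`: difference matrices `U`
#'   (`d x n_within`, instance minus bag center) and `V` (`d x n_between`,
#'   bag-mean differences), weights `w_within`/`w_between`, resolved
#'   `delta_s`/`delta_d`, and bookkeeping indices.
#' @export
build_constraints <- function(train, class_k, omega = NULL, td_labeled = NULL,
                              hyperparams = metric_hyperparams()) {
  stopifnot(inherits(train, "mimtl_dataset"))
  if (is.null(omega)) omega <- rep(1, n_bags(train))
  if (length(omega) != n_bags(train)) stop("omega must have one weight per source bag")
  if (any(omega < 0)) stop("omega must be non-negative")
  bags <- train$bags
  wts <- omega
  y <- label_for_class(train, class_k)
  if (!is.null(td_labeled)) {
    stopifnot(inherits(td_labeled, "mimtl_dataset"))
    if (td_labeled$d != train$d) stop("td_labeled dimension mismatch")
    bags <- c(bags, td_labeled$bags)
    wts <- c(wts, rep(1, n_bags(td_labeled)))
    y <- c(y, label_for_class(td_labeled, class_k))
  }
  if (sum(y == 1) == 0) {
    stop("class '", class_k, "' has no positive bag in the training set")
  }

  d <- train$d
  centers <- t(vapply(bags, bag_mean, numeric(d)))
  U <- t(do.call(rbind, lapply(seq_along(bags), function(i) {
    sweep(bags[[i]]$instances, 2L, centers[i, ], "-")
  })))
  sizes <- vapply(bags, bag_size, integer(1))
  within_bag <- rep(seq_along(bags), sizes)
  w_within <- wts[within_bag]

  pos <- which(y == 1)
  neg <- which(y == 0)
  pairs <- as.matrix(expand.grid(i = pos, j = neg))
  if (nrow(pairs) > hyperparams$max_pairs) {
    set.seed(hyperparams$seed)
    pairs <- pairs[sort(sample.int(nrow(pairs), hyperparams$max_pairs)), ,
                   drop = FALSE]
  }
  if (nrow(pairs) > 0) {
    V <- t(centers[pairs[, 1L], , drop = FALSE] -
           centers[pairs[, 2L], , drop = FALSE])
    w_between <- wts[pairs[, 1L]] * wts[pairs[, 2L]]
  } else {
    V <- matrix(0, d, 0L)
    w_between <- numeric(0)
  }

  delta_s <- hyperparams$delta_s
  delta_d <- hyperparams$delta_d
  if (is.null(delta_s)) delta_s <- median(colSums(U^2))
  if (is.null(delta_d)) {
    delta_d <- if (ncol(V)) median(colSums(V^2)) else delta_s * 2 + 1
  }
  if (delta_d <= delta_s) delta_d <- delta_s * 1.5 + 1e-8

  structure(list(U = U, w_within = w_within, within_bag = within_bag,
                 V = V, w_between = w_between, pairs = pairs,
                 delta_s = delta_s, delta_d = delta_d,
                 class_id = class_k, d = d,
                 n_within = ncol(U), n_between = ncol(V)),
            class = "mimtl_constraints")
}

label_for_class <- function(dataset, class_k) {
  k <- match(class_k, dataset$class_ids)
  if (is.na(k)) stop("class '", class_k, "' not in dataset class_ids")
  dataset$labels[, k]
}

#' Penalty-function objective of the metric program
#'
#' The constrained program (minimize `r(A)` plus weighted slack sums subject
#' to within-bag and between-class distance constraints and non-negative
#' slacks) is converted to the unconstrained
#' \deqn{f = \|A\|_F^2 + \lambda \sum w\,\xi + \beta \sum w\,\zeta +
#'   \sigma\big[\sum \max(0, D(x,c)-\delta_S-\xi)^2 +
#'   \sum \max(0, \delta_D-\zeta-D(X_i,X_j))^2 +
#'   \sum \max(0,-\xi)^2 + \sum \max(0,-\zeta)^2\big]}
#' with one-sided quadratic penalties, smooth so the analytic gradients of
#' [penalty_gradients()] exist everywhere.
#'
#' @param A `d x d` matrix.
#' @param xi,zeta slack vectors sized to the within / between constraints.
#' @param constraints a [build_constraints()] object.
#' @param hyperparams a [metric_hyperparams()].
#' @return scalar objective value.
#' @export
penalty_objective <- function(A, xi, zeta, constraints, hyperparams) {
  parts <- penalty_parts(A, xi, zeta, constraints)
  hp <- hyperparams
  sum(A^2) +
    hp$lambda * sum(constraints$w_within * xi) +
    hp$beta * sum(constraints$w_between * zeta) +
    hp$sigma * (sum(parts$viol_w^2) + sum(parts$viol_b^2) +
                sum(pmax(0, -xi)^2) + sum(pmax(0, -zeta)^2))
}

penalty_parts <- function(A, xi, zeta, cs) {
  if (length(xi) != cs$n_within || length(zeta) != cs$n_between) {
    stop("slack vectors do not match the constraint set size")
  }
  AU <- A %*% cs$U
  dw <- .colSums(AU * AU, nrow(AU), ncol(AU))
  if (cs$n_between) {
    AV <- A %*% cs$V
    db <- .colSums(AV * AV, nrow(AV), ncol(AV))
  } else {
    AV <- matrix(0, nrow(A), 0L)
    db <- numeric(0)
  }
  list(AU = AU, AV = AV, dw = dw, db = db,
       viol_w = pmax(0, dw - cs$delta_s - xi),
       viol_b = pmax(0, cs$delta_d - zeta - db))
}

#' Analytic gradients of the penalty objective
#'
#' A violated within constraint contributes
#' `sigma * 2 * viol * 2 A (x - c)(x - c)'` to the `A`-gradient and a
#' violated between constraint `-sigma * 2 * viol * 2 A (m_i - m_j)(m_i - m_j)'`,
#' on top of `2A` from the Frobenius regularizer. The slack gradients are
#' the linear terms `lambda w` / `beta w` minus the penalty pushback.
#'
#' @inheritParams penalty_objective
#' @return list with `grad_A` (`d x d`), `grad_xi`, `grad_zeta`.
#' @export
penalty_gradients <- function(A, xi, zeta, constraints, hyperparams) {
  cs <- constraints
  hp <- hyperparams
  p <- penalty_parts(A, xi, zeta, cs)
  grad_A <- 2 * A
  if (any(p$viol_w > 0)) {
    grad_A <- grad_A + 4 * hp$sigma *
      tcrossprod(p$AU * rep(p$viol_w, each = nrow(A)), cs$U)
  }
  if (cs$n_between && any(p$viol_b > 0)) {
    grad_A <- grad_A - 4 * hp$sigma *
      tcrossprod(p$AV * rep(p$viol_b, each = nrow(A)), cs$V)
  }
  grad_xi <- hp$lambda * cs$w_within -
    2 * hp$sigma * (p$viol_w + pmax(0, -xi))
  grad_zeta <- hp$beta * cs$w_between -
    2 * hp$sigma * (p$viol_b + pmax(0, -zeta))
  list(grad_A = grad_A, grad_xi = grad_xi, grad_zeta = grad_zeta)
}

#' Fit the per-class metric by gradient descent with backtracking
#'
#' Starting from `A = I` (the Euclidean baseline), `xi = zeta = 0`, each
#' iteration applies the three gradient updates in alternation (`A`, then
#' `xi`, then `zeta`), each block with its own backtracking multiplier
#' (halved until the objective does not increase, doubled after an accepted
#' step) — the blocks are scaled very differently, so a shared step would
#' stall the slack updates. Iteration stops when the objective decrease
#' over a full sweep falls below `epsilon`, or at `max_iter`. The objective
#' trace is non-increasing over accepted steps by construction.
#'
#' @param constraints a [build_constraints()] object.
#' @param hyperparams a [metric_hyperparams()].
#' @return Object of class `mimtl_metric`: fields `A`, `xi`, `zeta`,
#'   `class_id`, `hyperparams`, `trace` (objective per accepted iterate),
#'   `converged`, `iterations`.
#' @export
fit_metric <- function(constraints, hyperparams = metric_hyperparams()) {
  cs <- constraints
  hp <- hyperparams
  if (cs$n_within + cs$n_between == 0L) stop("empty constraint set")
  hp$delta_s <- cs$delta_s
  hp$delta_d <- cs$delta_d
  A <- diag(cs$d)
  xi <- numeric(cs$n_within)
  zeta <- numeric(cs$n_between)
  f <- penalty_objective(A, xi, zeta, cs, hp)
  if (!is.finite(f)) stop("non-finite objective at initialization")
  trace <- f
  mult <- c(A = 1, xi = 1, zeta = 1)
  converged <- FALSE
  sigma_rounds <- 0L
  it <- 0L
  # one backtracked gradient step on a single block; returns the new value
  # and objective, updating the block's persistent multiplier
  block_step <- function(block, grad, value, step0, f_cur, eval_f) {
    s <- mult[[block]]
    for (bt in 1:50) {
      cand <- value - s * step0 * grad
      f2 <- eval_f(cand)
      if (!is.finite(f2)) stop("non-finite objective at iteration ", it)
      if (f2 <= f_cur) {
        mult[[block]] <<- min(s * 2, 1e8)
        return(list(value = cand, f = f2))
      }
      s <- s / 2
    }
    list(value = value, f = f_cur)   # no descent at machine precision
  }
  while (it < hp$max_iter) {
    it <- it + 1L
    f_sweep <- f
    g <- penalty_gradients(A, xi, zeta, cs, hp)
    st <- block_step("A", g$grad_A, A, hp$step_a, f,
                     function(v) penalty_objective(v, xi, zeta, cs, hp))
    A <- st$value; f <- st$f
    if (cs$n_within) {
      g_xi <- penalty_gradients(A, xi, zeta, cs, hp)$grad_xi
      st <- block_step("xi", g_xi, xi, hp$step_xi, f,
                       function(v) penalty_objective(A, v, zeta, cs, hp))
      xi <- st$value; f <- st$f
    }
    if (cs$n_between) {
      g_zeta <- penalty_gradients(A, xi, zeta, cs, hp)$grad_zeta
      st <- block_step("zeta", g_zeta, zeta, hp$step_zeta, f,
                       function(v) penalty_objective(A, xi, v, cs, hp))
      zeta <- st$value; f <- st$f
    }
    delta_f <- f_sweep - f
    trace <- c(trace, f)
    if (delta_f < hp$epsilon) {
      if (hp$sigma_continuation && sigma_rounds < 4L) {
        parts <- penalty_parts(A, xi, zeta, cs)
        if (max(parts$viol_w, parts$viol_b, 0) > 1e-6) {
          hp$sigma <- hp$sigma * 10
          f <- penalty_objective(A, xi, zeta, cs, hp)
          sigma_rounds <- sigma_rounds + 1L
          next
        }
      }
      converged <- TRUE
      break
    }
  }
  structure(list(A = A, xi = xi, zeta = zeta, class_id = cs$class_id,
                 hyperparams = hp, trace = trace, converged = converged,
                 iterations = it),
            class = "mimtl_metric")
}

#' @export
print.mimtl_metric <- function(x, ...) {
  cat(sprintf("<mimtl_metric '%s': d = %d, %d iteration(s), f = %.6g, converged = %s>\n",
              x$class_id, nrow(x$A), x$iterations, tail(x$trace, 1L),
              x$converged))
  invisible(x)
}

#' Train one metric per class (one-vs-rest)
#'
#' Builds a one-vs-rest constraint set and fits one linear map `A` per
#' requested class. Classes without a positive training bag are skipped
#' with a warning. Fits are independent and order-invariant.
#'
#' @param train source-domain [miml_dataset()].
#' @param omega per-source-bag importance weights (`NULL` for ones).
#' @param td_labeled optional labeled target-domain dataset.
#' @param hyperparams a [metric_hyperparams()].
#' @param classes class identifiers to fit; default all classes of `train`.
#' @return Named list of `mimtl_metric` models (skipped classes absent).
#' @export
train_per_class <- function(train, omega = NULL, td_labeled = NULL,
                            hyperparams = metric_hyperparams(),
                            classes = NULL) {
  if (is.null(classes)) classes <- train$class_ids
  models <- list()
  for (k in classes) {
    y <- label_for_class(train, k)
    if (!is.null(td_labeled)) y <- c(y, label_for_class(td_labeled, k))
    if (sum(y == 1) == 0) {
      warning("skipping class '", k, "': no positive training bag")
      next
    }
    cs <- build_constraints(train, k, omega, td_labeled, hyperparams)
    models[[k]] <- fit_metric(cs, hyperparams)
  }
  models
}

#' Per-bag within-bag hinge loss under a fixed metric
#'
#' `(1/n_i) sum_j max(0, D(x_j, c_i) - delta_s)` — the bag-level statistic
#' whose importance-weighted source expectation matches its target
#' expectation when the weights equal the true density ratio.
#'
#' @param bag a bag.
#' @param A metric map.
#' @param delta_s within-bag radius.
#' @return non-negative scalar.
#' @export
within_bag_loss <- function(bag, A, delta_s) {
  Uc <- A %*% t(sweep(bag$instances, 2L, bag_mean(bag), "-"))
  mean(pmax(0, colSums(Uc^2) - delta_s))
}
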