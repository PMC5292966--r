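# Prediction heads consuming the learned per-class metrics: citation-kNN
# voting and the k-medoid embedding + RBF max-margin classifier.

metric_A <- function(metric_models, class_k, d) {
  m <- metric_models[[class_k]]
  if (is.null(m)) diag(d) else m$A
}

# Projected bag means under a class metric: rows are A %*% mean(bag).
project_means <- function(M, A) M %*% t(A)

sq_dist_rows <- function(P, Q) {
  outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q)
}

#' Citation-kNN head over learned per-class metrics
#'
#' @param train training [miml_dataset()] (already centered as used for
#'   metric learning).
#' @param metric_models named list from [train_per_class()]; classes absent
#'   from the list fall back to the identity metric.
#' @param r number of reference neighbors (`>= 1`).
#' @param c citer rank threshold (`>= 0`).
#' @return Object of class `mimtl_knn_head`.
#' @export
knn_head <- function(train, metric_models, r = 3L, c = 5L) {
  stopifnot(inherits(train, "mimtl_dataset"))
  if (n_bags(train) < 1L) stop("empty training set")
  if (r < 1L) stop("r must be >= 1")
  if (c < 0L) stop("c must be >= 0")
  structure(list(train = train, metric_models = metric_models,
                 classes = names(metric_models),
                 r = as.integer(r), c = as.integer(c)),
            class = "mimtl_knn_head")
}

# Core citation-kNN rule for one class given projected means.
# References: the r training bags nearest to the test bag. Citers: training
# bags B for which the test bag ranks within B's c nearest neighbors among
# the other training bags plus the test bag; ties rank the test bag last
# (pessimistic, deterministic). Vote over the multiset references + citers.
knn_vote_class <- function(p_test, P_train, y, r, c) {
  n <- nrow(P_train)
  d_test <- colSums((t(P_train) - p_test)^2)
  refs <- order(d_test, seq_len(n))[seq_len(min(r, n))]
  citers <- integer(0)
  if (c > 0L) {
    D <- sq_dist_rows(P_train, P_train)
    for (b in seq_len(n)) {
      d_others <- D[b, -b]
      rank_test <- 1L + sum(d_others < d_test[b]) + sum(d_others == d_test[b])
      if (rank_test <= c) citers <- c(citers, b)
    }
  }
  voters <- c(refs, citers)
  if (!length(voters)) return(c(label = 0, confidence = 0.5))
  pos <- sum(y[voters] == 1)
  tot <- length(voters)
  c(label = as.numeric(pos > tot - pos), confidence = pos / tot)
}

#' Citation-kNN prediction for a single bag and class
#'
#' @param test_bag a bag.
#' @param head a [knn_head()].
#' @param class_k class identifier.
#' @return named vector `c(label, confidence)`; `label` is 1 iff positive
#'   votes strictly outnumber negative votes (ties predict negative, the
#'   conservative choice under ~1% positive rates), `confidence` the
#'   positive vote fraction (0.5 with no voters).
#' @export
citation_knn_predict <- function(test_bag, head, class_k) {
  stopifnot(inherits(head, "mimtl_knn_head"))
  A <- metric_A(head$metric_models, class_k, head$train$d)
  P <- project_means(bag_means(head$train), A)
  p_test <- as.vector(A %*% bag_mean(test_bag))
  y <- label_for_class(head$train, class_k)
  knn_vote_class(p_test, P, y, head$r, head$c)
}

#' k-medoids clustering of bags under a metric
#'
#' Alternates nearest-medoid assignment and within-cluster medoid updates
#' (both tie-broken by lowest bag index) from a seeded random
#' initialization until the medoid set stops changing. Medoids are members
#' of the input bag set; the objective is the summed [bag_distance()] of
#' every bag to its medoid.
#'
#' @param bags list of bags or a [miml_dataset()].
#' @param A metric map.
#' @param k number of medoids, `1 <= k <= n`.
#' @param seed integer seed for the initialization.
#' @return list with `medoids` (sorted bag indices), `assignment` (index
#'   into `medoids` per bag), `cost`.
#' @export
kmedoids_bags <- function(bags, A, k, seed = 1L) {
  if (inherits(bags, "mimtl_dataset")) bags <- bags$bags
  n <- length(bags)
  if (k > n) stop("k = ", k, " exceeds the number of bags (", n, ")")
  if (k < 1L) stop("k must be >= 1")
  P <- project_means(bag_means(bags), A)
  D <- pmax(sq_dist_rows(P, P), 0)
  set.seed(as.integer(seed))
  medoids <- sort(sample.int(n, k))
  for (iter in 1:100) {
    assignment <- apply(D[, medoids, drop = FALSE], 1L, which.min)
    new_medoids <- vapply(seq_len(k), function(cl) {
      members <- which(assignment == cl)
      if (!length(members)) return(medoids[cl])
      members[which.min(colSums(D[members, members, drop = FALSE]))]
    }, integer(1))
    new_medoids <- sort(new_medoids)
    if (identical(new_medoids, medoids)) break
    medoids <- new_medoids
  }
  assignment <- apply(D[, medoids, drop = FALSE], 1L, which.min)
  cost <- sum(D[cbind(seq_len(n), medoids[assignment])])
  list(medoids = medoids, assignment = assignment, cost = cost)
}

#' Distance embedding of a bag against medoid bags
#'
#' Coordinate `i` is [bag_distance()] between the bag and the `i`-th
#' medoid under `A` — the single-instance representation fed to the
#' max-margin classifier.
#'
#' @param bag a bag.
#' @param medoid_bags list of medoid bags.
#' @param A metric map.
#' @return numeric vector of length `length(medoid_bags)`.
#' @export
bag_embedding <- function(bag, medoid_bags, A) {
  vapply(medoid_bags, function(m) bag_distance(bag, m, A), numeric(1))
}

embed_all <- function(bags, medoid_means_proj, A) {
  P <- project_means(bag_means(bags), A)
  pmax(sq_dist_rows(P, medoid_means_proj), 0)
}

#' Fit the k-medoid embedding + SVM head
#'
#' Per class: `k = max(1, round(cluster_ratio * n_train))` medoid bags are
#' found under the class metric, all training bags are embedded by their
#' distances to the medoids, and a binary RBF max-margin classifier
#' (defaults cost 1, kernel coefficient 0.2) is trained on the embeddings.
#' Embedding coordinates are min-max scaled to `[0, 1]` on the training
#' bags before the kernel (the standard LIBSVM-style preprocessing; the
#' 0.2 kernel coefficient presumes unit-scale features) and test
#' embeddings reuse the training scale. A class whose training labels are
#' all identical gets a constant predictor (logged via `message`).
#'
#' @param train training [miml_dataset()].
#' @param metric_models named list from [train_per_class()].
#' @param cluster_ratio fraction of training bags used as medoids
#'   (default 0.4).
#' @param cost,rbf_gamma SVM box constraint and RBF kernel coefficient.
#' @param seed integer seed (medoid initialization).
#' @return Object of class `mimtl_svm_head`.
#' @export
fit_svm_head <- function(train, metric_models, cluster_ratio = 0.4,
                         cost = 1, rbf_gamma = 0.2, seed = 1L) {
  stopifnot(inherits(train, "mimtl_dataset"))
  n <- n_bags(train)
  k <- max(1L, round(cluster_ratio * n))
  per_class <- list()
  for (class_k in names(metric_models)) {
    A <- metric_A(metric_models, class_k, train$d)
    km <- kmedoids_bags(train$bags, A, k, seed = seed)
    medoid_means_proj <- project_means(bag_means(train$bags[km$medoids]), A)
    Z <- embed_all(train$bags, medoid_means_proj, A)
    scale_min <- apply(Z, 2L, min)
    scale_rng <- pmax(apply(Z, 2L, max) - scale_min, .Machine$double.eps)
    Zs <- scale_embedding(Z, scale_min, scale_rng)
    y01 <- label_for_class(train, class_k)
    y <- ifelse(y01 == 1, 1, -1)
    if (length(unique(y)) == 1L) {
      message("class '", class_k, "': single-label training set, ",
              "using a constant predictor")
      per_class[[class_k]] <- list(A = A, medoid_means_proj = medoid_means_proj,
                                   scale_min = scale_min, scale_rng = scale_rng,
                                   constant = y[1L], svm = NULL)
    } else {
      K <- rbf_kernel_matrix(Zs, Zs, rbf_gamma)
      per_class[[class_k]] <- list(A = A, medoid_means_proj = medoid_means_proj,
                                   scale_min = scale_min, scale_rng = scale_rng,
                                   constant = NULL,
                                   svm = svm_smo(K, y, cost = cost),
                                   Z_train = Zs)
    }
  }
  structure(list(train = train, per_class = per_class, k = k,
                 cluster_ratio = cluster_ratio, cost = cost,
                 rbf_gamma = rbf_gamma, classes = names(per_class)),
            class = "mimtl_svm_head")
}

scale_embedding <- function(Z, scale_min, scale_rng) {
  sweep(sweep(Z, 2L, scale_min, "-"), 2L, scale_rng, "/")
}

svm_head_decision <- function(head, class_k, test_bags) {
  pc <- head$per_class[[class_k]]
  if (!is.null(pc$constant)) return(rep(pc$constant, length(test_bags)))
  Z <- scale_embedding(embed_all(test_bags, pc$medoid_means_proj, pc$A),
                       pc$scale_min, pc$scale_rng)
  Knew <- rbf_kernel_matrix(Z, pc$Z_train, head$rbf_gamma)
  svm_decision(pc$svm, Knew)
}

#' Predict multi-label annotations with a trained head
#'
#' @param object a [knn_head()] or [fit_svm_head()] head.
#' @param newdata a [miml_dataset()] of test bags (same dimension and
#'   centering frame as the training data).
#' @param ... unused.
#' @return list with `labels` and `confidences`, both `n_test x K'`
#'   matrices over the trained classes (classes skipped at training are
#'   absent). SVM decision values are squashed to `[0, 1]` confidences by
#'   the logistic map; ranking metrics are invariant to this monotone
#'   transform, and `labels == (decision > 0) == (confidence > 0.5)`.
#' @export
predict.mimtl_svm_head <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "mimtl_dataset"))
  if (newdata$d != object$train$d) stop("test dimension mismatch")
  n <- n_bags(newdata)
  classes <- object$classes
  conf <- matrix(NA_real_, n, length(classes),
                 dimnames = list(rownames(newdata$labels), classes))
  lab <- conf
  for (class_k in classes) {
    dv <- svm_head_decision(object, class_k, newdata$bags)
    conf[, class_k] <- plogis(dv)
    lab[, class_k] <- as.numeric(dv > 0)
  }
  list(labels = lab, confidences = conf)
}

#' @rdname predict.mimtl_svm_head
#' @export
predict.mimtl_knn_head <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "mimtl_dataset"))
  if (newdata$d != object$train$d) stop("test dimension mismatch")
  n <- n_bags(newdata)
  classes <- object$classes
  if (is.null(classes)) classes <- object$train$class_ids
  conf <- matrix(NA_real_, n, length(classes),
                 dimnames = list(rownames(newdata$labels), classes))
  lab <- conf
  M_test <- bag_means(newdata)
  M_train <- bag_means(object$train)
  for (class_k in classes) {
    A <- metric_A(object$metric_models, class_k, object$train$d)
    P <- project_means(M_train, A)
    PT <- project_means(M_test, A)
    y <- label_for_class(object$train, class_k)
    for (i in seq_len(n)) {
      v <- knn_vote_class(PT[i, ], P, y, object$r, object$c)
      lab[i, class_k] <- v["label"]
      conf[i, class_k] <- v["confidence"]
    }
  }
  list(labels = lab, confidences = conf)
}
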