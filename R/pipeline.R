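#' Train a full MIMTL model
#'
#' End-to-end pipeline: center the training-visible data (source bags plus
#' any labeled target bags — unlabeled target bags never enter the
#' centering statistics), estimate bag importance weights mapping the
#' source bag distribution onto the target domain, learn one Mahalanobis
#' map per class from the reweighted constraints, and fit the requested
#' prediction head.
#'
#' @param source labeled source-domain [miml_dataset()].
#' @param target target-domain [miml_dataset()]; its labels are never used
#'   for training (only its bags, for density-ratio estimation).
#' @param head `"svm"` (k-medoid embedding + RBF max-margin classifier) or
#'   `"knn"` (citation-kNN voting).
#' @param weights `"estimate"` for density-ratio weights or `"uniform"` for
#'   `omega == 1` (the no-transfer ablation).
#' @param metric `"learn"` for the fitted per-class maps or `"identity"`
#'   for `A = I` (the Euclidean ablation). With `weights = "uniform"` and
#'   `metric = "identity"`, the SVM head reduces to a MIMLSVM-like
#'   Euclidean medoid-embedding pipeline — the internal baseline.
#' @param td_labeled optional labeled target-domain dataset joined to the
#'   training set with weight 1.
#' @param classes classes to train; default all with a positive bag.
#' @param hyperparams a [metric_hyperparams()].
#' @param basis_size,gamma,ridge passed to [estimate_weights()].
#' @param knn_r,knn_c citation-kNN reference count and citer threshold.
#' @param cluster_ratio,svm_cost,svm_gamma SVM head parameters.
#' @param center_on `"source_and_td"` (default) or `"source"`; which bags
#'   define the centering transform.
#' @param seed integer seed driving every stochastic step.
#' @return Object of class `mimtl_model` with the fitted head, centering
#'   transform, importance model, per-class metrics, and the trained class
#'   list.
#' @export
mimtl_train <- function(source, target, head = c("svm", "knn"),
                        weights = c("estimate", "uniform"),
                        metric = c("learn", "identity"),
                        td_labeled = NULL, classes = NULL,
                        hyperparams = metric_hyperparams(),
                        basis_size = 100L, gamma = NULL, ridge = 1e-6,
                        knn_r = 3L, knn_c = 5L, cluster_ratio = 0.4,
                        svm_cost = 1, svm_gamma = 0.2,
                        center_on = c("source_and_td", "source"),
                        seed = 1L) {
  head <- match.arg(head)
  weights <- match.arg(weights)
  metric <- match.arg(metric)
  center_on <- match.arg(center_on)
  hyperparams$seed <- as.integer(seed)

  center_ds <- if (center_on == "source_and_td" && !is.null(td_labeled)) {
    miml_dataset(c(source$bags, td_labeled$bags),
                 rbind(source$labels, td_labeled$labels),
                 class_ids = source$class_ids, domain = "source")
  } else source
  transform <- centralize(center_ds)$transform
  src_c <- apply_centering(source, transform)
  tgt_c <- apply_centering(target, transform)
  td_c <- if (!is.null(td_labeled)) apply_centering(td_labeled, transform)

  importance <- NULL
  omega <- rep(1, n_bags(source))
  if (weights == "estimate") {
    importance <- estimate_weights(src_c, tgt_c, basis_size = basis_size,
                                   gamma = gamma, ridge = ridge, seed = seed)
    omega <- importance$omega
  }

  if (is.null(classes)) {
    npos <- colSums(source$labels)
    if (!is.null(td_labeled)) npos <- npos + colSums(td_labeled$labels)
    classes <- source$class_ids[npos > 0]
  }
  metric_models <- if (metric == "learn") {
    train_per_class(src_c, omega, td_c, hyperparams, classes)
  } else {
    setNames(lapply(classes, function(k) {
      structure(list(A = diag(source$d), class_id = k,
                     hyperparams = hyperparams, trace = numeric(0),
                     converged = TRUE, iterations = 0L),
                class = "mimtl_metric")
    }), classes)
  }

  train_c <- if (!is.null(td_c)) {
    miml_dataset(c(src_c$bags, td_c$bags), rbind(src_c$labels, td_c$labels),
                 class_ids = src_c$class_ids, domain = "source")
  } else src_c

  fitted_head <- if (head == "svm") {
    fit_svm_head(train_c, metric_models, cluster_ratio = cluster_ratio,
                 cost = svm_cost, rbf_gamma = svm_gamma, seed = seed)
  } else {
    knn_head(train_c, metric_models, r = knn_r, c = knn_c)
  }

  structure(list(head = fitted_head, head_type = head,
                 centering = transform, importance = importance,
                 metric_models = metric_models, classes = names(metric_models),
                 d = source$d, seed = as.integer(seed)),
            class = "mimtl_model")
}

#' @export
print.mimtl_model <- function(x, ...) {
  cat(sprintf("<mimtl_model: %s head, %d class(es), d = %d>\n",
              x$head_type, length(x$classes), x$d))
  invisible(x)
}

#' Predict annotations for new bags with a trained MIMTL model
#'
#' Applies the training-time centering transform to `newdata` and runs the
#' fitted prediction head. Deterministic across repeated calls.
#'
#' @param object a [mimtl_train()] model.
#' @param newdata a [miml_dataset()] of test bags.
#' @param ... unused.
#' @return list with `labels` and `confidences` (`n_test x K'` over the
#'   trained classes).
#' @export
predict.mimtl_model <- function(object, newdata, ...) {
  if (newdata$d != object$d) stop("test dimension mismatch")
  predict(object$head, apply_centering(newdata, object$centering))
}

benchmark_methods <- function() {
  list(
    mimtl_svm = list(head = "svm", weights = "estimate", metric = "learn"),
    mimtl_knn = list(head = "knn", weights = "estimate", metric = "learn"),
    euclidean_svm_baseline = list(head = "svm", weights = "uniform",
                                  metric = "identity"),
    unweighted_metric = list(head = "svm", weights = "uniform",
                             metric = "learn")
  )
}

#' Repeated-run benchmark over methods on shifted MIML data
#'
#' For each repetition: obtain a source/target pair (regenerating from a
#' [generator_config()] with the rep's seed, or re-splitting a fixed
#' dataset), train each method on the source (plus target bags for weight
#' estimation), predict the target bags, and score all five metrics
#' against the target labels. Fully reproducible from the seed list.
#'
#' @param x a [generator_config()] or a [miml_dataset()].
#' @param split_protocol for a dataset input: `"median"`
#'   ([split_by_feature_median()]) or `"cluster"`
#'   ([split_random_clusters()]); ignored for a config input.
#' @param methods subset of `c("mimtl_svm", "mimtl_knn",
#'   "euclidean_svm_baseline", "unweighted_metric")`.
#' @param n_reps number of repetitions.
#' @param seeds integer seed per rep; default `base_seed + 0:(n_reps-1)`.
#' @param hyperparams a [metric_hyperparams()].
#' @param ... further arguments passed to [mimtl_train()].
#' @return Named list of per-method reports (class `mimtl_eval_report`):
#'   `per_run` (one row per rep, five metrics), `mean`, `sd`, `seeds`,
#'   `method`.
#' @export
benchmark_run <- function(x, split_protocol = c("median", "cluster"),
                          methods = names(benchmark_methods()),
                          n_reps = 20L, seeds = NULL,
                          hyperparams = metric_hyperparams(), ...) {
  split_protocol <- match.arg(split_protocol)
  spec <- benchmark_methods()
  methods <- match.arg(methods, names(spec), several.ok = TRUE)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (is.null(seeds)) {
    base <- if (inherits(x, "mimtl_generator_config")) x$seed else 1L
    seeds <- base + seq_len(n_reps) - 1L
  }
  if (length(seeds) != n_reps) stop("need one seed per rep")
  runs <- setNames(vector("list", length(methods)), methods)
  for (r in seq_len(n_reps)) {
    pair <- if (inherits(x, "mimtl_generator_config")) {
      cfg <- x; cfg$seed <- as.integer(seeds[r])
      g <- generate_shifted_miml(cfg)
      list(source = g$source, target = g$target)
    } else if (inherits(x, "mimtl_dataset")) {
      split <- if (split_protocol == "median") split_by_feature_median(x)
               else split_random_clusters(x, seed = seeds[r])
      apply_split(x, split)
    } else stop("x must be a generator config or a MIML dataset")
    for (m in methods) {
      cfg_m <- spec[[m]]
      fit <- tryCatch(
        mimtl_train(pair$source, pair$target, head = cfg_m$head,
                    weights = cfg_m$weights, metric = cfg_m$metric,
                    hyperparams = hyperparams, seed = seeds[r], ...),
        error = function(e) stop("rep ", r, ", method '", m, "': ",
                                 conditionMessage(e)))
      pred <- predict(fit, pair$target)
      Y <- pair$target$labels[, colnames(pred$confidences), drop = FALSE]
      runs[[m]] <- rbind(runs[[m]],
                         eval_all_metrics(pred$confidences, pred$labels, Y))
    }
  }
  lapply(setNames(methods, methods), function(m) {
    per_run <- runs[[m]]
    rownames(per_run) <- paste0("rep", seq_len(n_reps))
    structure(list(method = m, per_run = per_run,
                   mean = colMeans(per_run),
                   sd = apply(per_run, 2L, sd),
                   seeds = seeds),
              class = "mimtl_eval_report")
  })
}

#' @export
print.mimtl_eval_report <- function(x, ...) {
  cat(sprintf("<mimtl_eval_report '%s': %d run(s)>\n", x$method,
              nrow(x$per_run)))
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}
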