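#' Configuration for the covariate-shifted MIML simulator
#'
#' The generator emulates the statistical shape of the organism MIML
#' benchmarks: bags of ~3 instances (shifted-Poisson sizes, default mean
#' 3.13), hundreds of classes each with ~1% positive rate, and a per-bag
#' covariate shift between a source and a target domain.
#'
#' Instances are drawn from a Gaussian mixture: with probability `pi_k` an
#' instance realizes class concept `k` (mean `concept_means[k, ]`, spherical
#' spread `concept_spread`), otherwise the background (mean 0, spread
#' `background_spread`). A bag is positive for class `k` iff at least one of
#' its instances realizes concept `k` (the multi-instance assumption). The
#' target domain translates every instance by `shift_vector`.
#'
#' So that the bag density ratio P'(X)/P(X) has an exact closed form, the
#' shift is confined to the coordinates where `shift_vector` is nonzero and
#' acts per bag: on those coordinates each bag draws a latent center
#' `t ~ N(domain mean, bag_effect_sd^2)` shared by all its instances, and
#' instances scatter around `t` with the complementary spread so that the
#' marginal instance spread equals `background_spread`. The target domain
#' translates the latent-center mean by `shift_vector`. Concept structure
#' lives on the remaining coordinates and is identical across domains, so
#' it cancels in the ratio; the bag log density ratio is linear in the bag
#' mean over the shifted coordinates (see [true_density_ratio()]).
#'
#' @param d instance dimension (216 matches the conjoint-triad features of
#'   the real organism data).
#' @param K number of classes.
#' @param n_source,n_target bags per domain.
#' @param bag_size_mean mean instances per bag; sizes are
#'   `1 + Poisson(bag_size_mean - 1)` so every bag has at least one instance.
#' @param concept_means `K x d` matrix of concept means, or `NULL` to draw
#'   them (standard normal entries on the non-shift coordinates) from `seed`.
#'   Must be zero on the shift coordinates.
#' @param concept_spread,background_spread spherical standard deviations.
#' @param label_rate expected fraction of positive bags per class, in (0,1).
#'   Per-instance concept probability is `1 - (1 - label_rate)^(1/bag_size_mean)`;
#'   the total concept mass `K * pi_k` must stay below 1.
#' @param shift_vector `d`-vector translating target-domain instance means,
#'   or `NULL` for a unit shift on the first `min(2, d)` coordinates.
#' @param bag_effect_sd standard deviation of the per-bag latent center on
#'   the shift coordinates; must satisfy `0 < bag_effect_sd <
#'   background_spread`. Default `background_spread / sqrt(2)` (half the
#'   marginal variance between bags, half within).
#' @param seed integer seed; identical seeds reproduce datasets bit-for-bit.
#' @return An object of class `mimtl_generator_config`.
#' @export
generator_config <- function(d = 216, K = 234, n_source = 152, n_target = 152,
                             bag_size_mean = 3.13, concept_means = NULL,
                             concept_spread = 0.5, background_spread = 1,
                             label_rate = 0.01, shift_vector = NULL,
                             bag_effect_sd = NULL, seed = 1L) {
  if (d < 1 || K < 1) stop("degenerate config: need d >= 1 and K >= 1")
  if (n_source < 1 || n_target < 1) stop("degenerate config: need bags in both domains")
  if (bag_size_mean < 1) stop("bag_size_mean must be >= 1")
  if (label_rate <= 0 || label_rate >= 1) stop("label_rate must lie in (0, 1)")
  if (concept_spread <= 0 || background_spread <= 0) stop("spreads must be positive")
  if (is.null(shift_vector)) {
    shift_vector <- numeric(d)
    shift_vector[seq_len(min(2L, d))] <- 1
  }
  if (length(shift_vector) != d) stop("shift_vector must have length d")
  pi_k <- 1 - (1 - label_rate)^(1 / bag_size_mean)
  if (K * pi_k >= 1) {
    stop("label_rate ", label_rate, " with K = ", K,
         " needs total concept mass ", signif(K * pi_k, 3),
         " >= 1; lower label_rate or K")
  }
  if (is.null(bag_effect_sd)) bag_effect_sd <- background_spread / sqrt(2)
  if (bag_effect_sd <= 0 || bag_effect_sd >= background_spread) {
    stop("bag_effect_sd must lie in (0, background_spread)")
  }
  shift_coords <- which(shift_vector != 0)
  if (is.null(concept_means)) {
    set.seed(as.integer(seed) + 7L)
    concept_means <- matrix(rnorm(K * d), K, d)
    concept_means[, shift_coords] <- 0
  }
  concept_means <- as.matrix(concept_means)
  if (!all(dim(concept_means) == c(K, d))) stop("concept_means must be K x d")
  if (length(shift_coords) && any(concept_means[, shift_coords] != 0)) {
    stop("concept_means must be zero on the shift coordinates ",
         "(the shift subspace carries no class signal; this keeps the ",
         "density ratio exact)")
  }
  structure(list(d = d, K = K, n_source = n_source, n_target = n_target,
                 bag_size_mean = bag_size_mean, concept_means = concept_means,
                 concept_spread = concept_spread,
                 background_spread = background_spread,
                 label_rate = label_rate, pi_k = pi_k,
                 shift_vector = shift_vector, bag_effect_sd = bag_effect_sd,
                 seed = as.integer(seed)),
            class = "mimtl_generator_config")
}

gen_domain <- function(config, n, shifted, prefix) {
  d <- config$d; K <- config$K
  shift_coords <- which(config$shift_vector != 0)
  tau <- config$bag_effect_sd
  s_within <- sqrt(config$background_spread^2 - tau^2)
  sizes <- 1L + rpois(n, config$bag_size_mean - 1)
  probs <- c(1 - K * config$pi_k, rep(config$pi_k, K))
  bags <- vector("list", n)
  assignments <- vector("list", n)
  Y <- matrix(0, n, K)
  for (i in seq_len(n)) {
    comp <- sample.int(K + 1L, sizes[i], replace = TRUE, prob = probs) - 1L
    X <- matrix(rnorm(sizes[i] * d), sizes[i], d)
    for (j in seq_len(sizes[i])) {
      if (comp[j] == 0L) {
        X[j, ] <- X[j, ] * config$background_spread
      } else {
        X[j, ] <- X[j, ] * config$concept_spread + config$concept_means[comp[j], ]
      }
    }
    if (length(shift_coords)) {
      # per-bag latent center on the shift coordinates, shared by all
      # instances; domain shift translates its mean
      centre <- rnorm(length(shift_coords), sd = tau)
      if (shifted) centre <- centre + config$shift_vector[shift_coords]
      X[, shift_coords] <- rep(centre, each = sizes[i]) +
        matrix(rnorm(sizes[i] * length(shift_coords), sd = s_within),
               sizes[i], length(shift_coords))
    }
    bags[[i]] <- new_bag(X, sprintf("%s%04d", prefix, i))
    assignments[[i]] <- comp
    pos <- unique(comp[comp > 0L])
    if (length(pos)) Y[i, pos] <- 1
  }
  list(bags = bags, labels = Y, assignments = assignments)
}

#' Generate a covariate-shifted pair of MIML datasets
#'
#' @param config a [generator_config()].
#' @return List with elements `source` and `target` ([miml_dataset()]s) and
#'   `truth` (class `mimtl_ground_truth`): the generative parameters plus the
#'   per-bag concept assignments, sufficient to evaluate the source and
#'   target bag densities in closed form.
#' @export
generate_shifted_miml <- function(config) {
  stopifnot(inherits(config, "mimtl_generator_config"))
  set.seed(config$seed)
  class_ids <- sprintf("class%04d", seq_len(config$K))
  src <- gen_domain(config, config$n_source, shifted = FALSE, prefix = "src")
  tgt <- gen_domain(config, config$n_target, shifted = TRUE, prefix = "tgt")
  source <- miml_dataset(src$bags, src$labels, class_ids, domain = "source")
  target <- miml_dataset(tgt$bags, tgt$labels, class_ids, domain = "target")
  truth <- structure(list(config = config,
                          assignments_source = src$assignments,
                          assignments_target = tgt$assignments,
                          class_ids = class_ids),
                     class = "mimtl_ground_truth")
  list(source = source, target = target, truth = truth)
}

#' Exact density ratio of a bag under the generative model
#'
#' Returns `P'(X)/P(X)`, the target-over-source bag density ratio. The bag
#' density on the shift coordinates integrates the per-bag latent center
#' out of the conditionally independent instance product; the non-shift
#' coordinates are identically distributed across domains and cancel, and
#' the bag-size law is shift-invariant and cancels. The log ratio is
#' linear in the bag mean over the shifted coordinates:
#' \deqn{\log w(X) = \sum_{j} \delta_j (\bar x_j - \delta_j / 2) /
#'   (\tau^2 + s^2 / n_i)}
#' with \eqn{\tau} the bag-effect spread, \eqn{s^2 = s_b^2 - \tau^2} the
#' within-bag spread, and \eqn{\bar x} the bag's instance mean. For a
#' single-instance bag this reduces to the quotient of the marginal
#' instance densities `N(x; delta, s_b^2) / N(x; 0, s_b^2)`.
#'
#' @param truth `mimtl_ground_truth` from [generate_shifted_miml()].
#' @param bag a [new_bag()] with the truth's instance dimension.
#' @return Positive finite scalar; exactly 1 everywhere when the shift is 0.
#' @export
true_density_ratio <- function(truth, bag) {
  stopifnot(inherits(truth, "mimtl_ground_truth"))
  cfg <- truth$config
  if (bag_dim(bag) != cfg$d) {
    stop("bag dimension ", bag_dim(bag), " does not match generator d = ", cfg$d)
  }
  delta <- cfg$shift_vector
  tau2 <- cfg$bag_effect_sd^2
  s2 <- cfg$background_spread^2 - tau2
  n_i <- bag_size(bag)
  xbar <- bag_mean(bag)
  exp(sum(delta * (xbar - delta / 2)) / (tau2 + s2 / n_i))
}

#' Deterministic source/target split on the bag feature-value median
#'
#' Each bag is scored by the mean of all its feature values (over instances
#' and coordinates); the half with the larger scores becomes the source
#' domain, so the source has a higher density of bags with large feature
#' values. Ties (and the odd-`n` middle element) are resolved by stable
#' index order; sizes differ by at most one (`ceiling(n/2)` source bags).
#'
#' @param dataset a [miml_dataset()] with at least 2 bags.
#' @return Object of class `mimtl_domain_split` with `source_indices` and
#'   `target_indices` (disjoint, covering).
#' @export
split_by_feature_median <- function(dataset) {
  n <- n_bags(dataset)
  if (n < 2L) stop("need at least 2 bags to split")
  s <- vapply(dataset$bags, function(b) mean(b$instances), numeric(1))
  ord <- order(-s, seq_len(n))   # descending score, stable in index
  n_src <- ceiling(n / 2)
  structure(list(source_indices = sort(ord[seq_len(n_src)]),
                 target_indices = sort(ord[-seq_len(n_src)])),
            class = "mimtl_domain_split")
}

#' Random two-cluster source/target split
#'
#' Bags are clustered into two groups by k-means on their mean vectors
#' (`nstart = 10` restarts under the seed); one cluster, chosen uniformly at
#' random under the same seed, becomes the source domain. Deterministic
#' given `seed`.
#'
#' @param dataset a [miml_dataset()] with at least 2 bags.
#' @param seed integer seed.
#' @return A `mimtl_domain_split`.
#' @export
split_random_clusters <- function(dataset, seed = 1L) {
  n <- n_bags(dataset)
  if (n < 2L) stop("need at least 2 bags to split")
  M <- bag_means(dataset)
  set.seed(as.integer(seed))
  km <- kmeans(M, centers = 2L, nstart = 10L, iter.max = 100L)
  src_cluster <- sample.int(2L, 1L)
  structure(list(source_indices = which(km$cluster == src_cluster),
                 target_indices = which(km$cluster != src_cluster)),
            class = "mimtl_domain_split")
}

#' Materialize a domain split as two datasets
#'
#' @param dataset a [miml_dataset()].
#' @param split a `mimtl_domain_split`.
#' @return list with `source` and `target` datasets, domain tags set.
#' @export
apply_split <- function(dataset, split) {
  stopifnot(inherits(split, "mimtl_domain_split"))
  take <- function(idx, dom) {
    miml_dataset(dataset$bags[idx],
                 dataset$labels[idx, , drop = FALSE],
                 class_ids = dataset$class_ids, domain = dom)
  }
  list(source = take(split$source_indices, "source"),
       target = take(split$target_indices, "target"))
}
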