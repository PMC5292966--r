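#' Construct a bag of instances
#'
#' A bag represents one protein: an ordered set of `n_i` instance vectors
#' (e.g. conjoint-triad frequency vectors for the protein's structural
#' domains), all of dimension `d`.
#'
#' @param instances numeric matrix (`n_i x d`) or a single numeric vector
#'   (taken as one instance). All entries must be finite.
#' @param bag_id character scalar identifying the bag.
#' @return An object of class `mimtl_bag` with fields `bag_id` and
#'   `instances`.
#' @examples
#' b <- new_bag(rbind(c(0, 0), c(2, 2)), "prot1")
#' bag_mean(b)
#' @export
new_bag <- function(instances, bag_id) {
  if (is.null(dim(instances))) instances <- matrix(instances, nrow = 1L)
  instances <- as.matrix(instances)
  storage.mode(instances) <- "double"
  if (nrow(instances) < 1L) stop("a bag needs at least one instance")
  if (!all(is.finite(instances))) {
    stop("bag '", bag_id, "' contains non-finite instance values")
  }
  structure(list(bag_id = as.character(bag_id)[1L], instances = instances),
            class = "mimtl_bag")
}

#' @export
print.mimtl_bag <- function(x, ...) {
  cat(sprintf("<mimtl_bag '%s': %d instance(s), d = %d>\n",
              x$bag_id, nrow(x$instances), ncol(x$instances)))
  invisible(x)
}

bag_dim <- function(bag) ncol(bag$instances)

bag_size <- function(bag) nrow(bag$instances)

#' Mean instance of a bag
#'
#' The arithmetic mean over the bag's instances. This is also the bag center
#' `c_i` used by the within-bag metric constraints and the representative
#' point for bag-level distances.
#'
#' @param bag a [new_bag()] object.
#' @return Numeric `d`-vector.
#' @export
bag_mean <- function(bag) colMeans(bag$instances)

#' Construct a multi-instance multi-label dataset
#'
#' @param bags list of [new_bag()] objects, all with the same instance
#'   dimension.
#' @param labels binary `n_bag x K` matrix; row `i` holds the class
#'   memberships of `bags[[i]]`. May have zero columns.
#' @param class_ids character vector of `K` class identifiers (e.g. GO term
#'   accessions); defaults to `colnames(labels)`.
#' @param domain one of `"source"`, `"target"`, `"unsplit"`.
#' @return An object of class `mimtl_dataset` with fields `bags`, `labels`,
#'   `class_ids`, `domain`, `d`.
#' @export
miml_dataset <- function(bags, labels = NULL,
                         class_ids = colnames(labels),
                         domain = c("unsplit", "source", "target")) {
  domain <- match.arg(domain)
  if (length(bags) < 1L) stop("dataset needs at least one bag")
  dims <- vapply(bags, bag_dim, integer(1))
  if (length(unique(dims)) != 1L) {
    stop("all bags must share the same instance dimension; saw d in {",
         paste(unique(dims), collapse = ", "), "}")
  }
  if (is.null(labels)) labels <- matrix(0, length(bags), 0L)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "double"
  if (nrow(labels) != length(bags)) {
    stop("labels has ", nrow(labels), " rows but there are ",
         length(bags), " bags")
  }
  if (ncol(labels) > 0 && !all(labels %in% c(0, 1))) {
    stop("label entries must be 0 or 1")
  }
  if (is.null(class_ids)) class_ids <- character(ncol(labels))
  if (length(class_ids) != ncol(labels)) {
    stop("class_ids length must equal ncol(labels)")
  }
  colnames(labels) <- class_ids
  rownames(labels) <- vapply(bags, `[[`, character(1), "bag_id")
  structure(list(bags = bags, labels = labels,
                 class_ids = as.character(class_ids),
                 domain = domain, d = dims[1L]),
            class = "mimtl_dataset")
}

#' @export
print.mimtl_dataset <- function(x, ...) {
  cat(sprintf("<mimtl_dataset: %d bags, %d instances, d = %d, K = %d, domain = %s>\n",
              n_bags(x), n_instances(x), x$d, length(x$class_ids), x$domain))
  invisible(x)
}

#' Number of bags in a dataset
#' @param dataset a [miml_dataset()].
#' @return integer.
#' @export
n_bags <- function(dataset) length(dataset$bags)

#' Total number of instances across all bags
#' @param dataset a [miml_dataset()].
#' @return integer.
#' @export
n_instances <- function(dataset) {
  sum(vapply(dataset$bags, bag_size, integer(1)))
}

#' Matrix of bag means
#' @param dataset a [miml_dataset()] or list of bags.
#' @return `n_bag x d` matrix, one row per bag mean.
#' @export
bag_means <- function(dataset) {
  bags <- if (inherits(dataset, "mimtl_dataset")) dataset$bags else dataset
  t(vapply(bags, bag_mean, numeric(bag_dim(bags[[1L]]))))
}

all_instances <- function(dataset) {
  do.call(rbind, lapply(dataset$bags, `[[`, "instances"))
}

#' Center a MIML dataset on its grand instance mean
#'
#' Subtracts the grand mean over all `n_all` instances (instance-weighted,
#' not bag-weighted) from every instance of every bag. The returned
#' transform can be reapplied with [apply_centering()] to map held-out or
#' target-domain bags into the same frame, so test-time statistics never
#' leak into the preprocessing.
#'
#' @param dataset a [miml_dataset()].
#' @return list with elements `dataset` (the centered data) and `transform`
#'   (class `mimtl_centering`: fields `mean_vector`, `n_all`).
#' @export
centralize <- function(dataset) {
  stopifnot(inherits(dataset, "mimtl_dataset"))
  X <- all_instances(dataset)
  transform <- structure(list(mean_vector = colMeans(X), n_all = nrow(X)),
                         class = "mimtl_centering")
  list(dataset = apply_centering(dataset, transform), transform = transform)
}

#' Apply a previously learned centering transform
#'
#' @param dataset a [miml_dataset()].
#' @param transform a `mimtl_centering` object from [centralize()].
#' @return The centered dataset.
#' @export
apply_centering <- function(dataset, transform) {
  stopifnot(inherits(transform, "mimtl_centering"))
  mu <- transform$mean_vector
  if (length(mu) != dataset$d) {
    stop("centering dimension ", length(mu),
         " does not match dataset d = ", dataset$d)
  }
  bags <- lapply(dataset$bags, function(b) {
    b$instances <- sweep(b$instances, 2L, mu, "-")
    b
  })
  out <- dataset
  out$bags <- bags
  out
}
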