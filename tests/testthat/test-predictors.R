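make_labeled_train <- function(n, d, y, seed = 1) {
  bags <- rand_bags(n, d, seed = seed, prefix = "tr")
  miml_dataset(bags, matrix(y, ncol = 1), class_ids = "k", domain = "source")
}

test_that("citation-kNN votes follow the reference/citer contract", {
  train <- make_labeled_train(5, 3, rep(1, 5), seed = 50)
  head_all_pos <- knn_head(train, list(), r = 3, c = 2)
  v <- citation_knn_predict(rand_bag(2, 3, "t", seed = 51), head_all_pos, "k")
  expect_equal(unname(v["label"]), 1)
  expect_equal(unname(v["confidence"]), 1)
  # test bag identical to a positive training bag, r = 1, c = 0
  y <- c(1, 0, 0, 0, 0)
  train2 <- make_labeled_train(5, 3, y, seed = 52)
  head2 <- knn_head(train2, list(), r = 1, c = 0)
  v2 <- citation_knn_predict(train2$bags[[1]], head2, "k")
  expect_equal(unname(v2["label"]), 1)
  expect_error(knn_head(train, list(), r = 0), "r must")
})

test_that("reference and citer sets match exhaustive enumeration", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 6; d <- 3; r <- 2; cth <- 2
    M <- matrix(rnorm(n * d), n, d)          # training bag means (1 instance each)
    y <- rbinom(n, 1, 0.5)
    bags <- lapply(seq_len(n), function(i) new_bag(M[i, ], paste0("b", i)))
    train <- miml_dataset(bags, matrix(y, ncol = 1), class_ids = "k",
                          domain = "source")
    hd <- knn_head(train, list(), r = r, c = cth)
    tb <- new_bag(rnorm(d), "t")
    v <- citation_knn_predict(tb, hd, "k")
    # oracle: full distance-matrix enumeration under the documented rule
    d_test <- colSums((t(M) - as.vector(tb$instances))^2)
    refs <- order(d_test)[seq_len(r)]
    citers <- integer(0)
    for (b in seq_len(n)) {
      d_others <- colSums((t(M[-b, , drop = FALSE]) - M[b, ])^2)
      rank_test <- 1 + sum(d_others < d_test[b]) + sum(d_others == d_test[b])
      if (rank_test <= cth) citers <- c(citers, b)
    }
    votes <- y[c(refs, citers)]
    expect_equal(unname(v["label"]), as.numeric(sum(votes) > length(votes) / 2))
    expect_equal(unname(v["confidence"]),
                 if (length(votes)) mean(votes) else 0.5)
  }
})

test_that("kmedoids at k = n and k = 1 match closed forms", {
  bags <- rand_bags(7, 3, seed = 60)
  A <- diag(3)
  km_n <- kmedoids_bags(bags, A, k = 7, seed = 1)
  expect_equal(km_n$cost, 0)
  expect_identical(km_n$medoids, 1:7)
  km_1 <- kmedoids_bags(bags, A, k = 1, seed = 1)
  costs <- vapply(seq_along(bags), function(i) {
    sum(vapply(bags, bag_distance, numeric(1), bagY = bags[[i]], A = A))
  }, numeric(1))
  expect_equal(km_1$medoids, which.min(costs))
  expect_equal(km_1$cost, min(costs), tolerance = 1e-10)
  expect_error(kmedoids_bags(bags, A, k = 8), "exceeds")
})

test_that("kmedoids converges to a swap-stable partition", {
  set.seed(61)
  bags <- rand_bags(15, 2, seed = 61)
  A <- matrix(c(1, 0.3, 0, 1), 2)
  km <- kmedoids_bags(bags, A, k = 3, seed = 4)
  expect_setequal(unique(km$assignment), 1:3)
  D <- outer(seq_along(bags), seq_along(bags),
             Vectorize(function(i, j) bag_distance(bags[[i]], bags[[j]], A)))
  # no within-cluster medoid swap lowers the cost
  for (cl in 1:3) {
    members <- which(km$assignment == cl)
    cur <- sum(D[members, km$medoids[cl]])
    for (cand in members) {
      expect_gte(sum(D[members, cand]), cur - 1e-10)
    }
  }
  expect_identical(km, kmedoids_bags(bags, A, k = 3, seed = 4))
})

test_that("bag_embedding equals per-coordinate bag distances", {
  bags <- rand_bags(6, 4, seed = 62)
  A <- matrix(rnorm(16), 4)
  med <- bags[c(2, 5)]
  z <- bag_embedding(bags[[1]], med, A)
  expect_equal(z, c(bag_distance(bags[[1]], med[[1]], A),
                    bag_distance(bags[[1]], med[[2]], A)), tolerance = 1e-12)
  expect_equal(bag_embedding(med[[1]], med, A)[1], 0)
  zi <- bag_embedding(bags[[1]], med, diag(4))
  expect_equal(zi[1], sum((bag_mean(bags[[1]]) - bag_mean(med[[1]]))^2))
})

test_that("svm_smo solves the two-point problem in closed form", {
  # two separable points, linear kernel K = X X': alpha = min(C, 2/||x1-x2||^2)
  X <- rbind(c(0, 0), c(2, 0))
  K <- tcrossprod(X)
  y <- c(-1, 1)
  m <- svm_smo(K, y, cost = 1)
  expect_equal(m$alpha, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(m$b, -1, tolerance = 1e-6)
  dv <- mimtl:::svm_decision(m, K)
  expect_equal(sign(dv), y)
  # KKT gap closed at exit on random problems
  for (seed in 1:5) {
    set.seed(seed)
    Z <- matrix(rnorm(30), 15, 2)
    yy <- ifelse(Z[, 1] + rnorm(15, 0, 0.5) > 0, 1, -1)
    if (length(unique(yy)) < 2) next
    Kr <- mimtl:::rbf_kernel_matrix(Z, Z, 0.5)
    mr <- svm_smo(Kr, yy, cost = 1)
    expect_lt(mr$kkt_gap, 1e-4)
  }
})

test_that("svm head fits separable data and predicts consistently", {
  set.seed(63)
  y <- rep(c(1, 0), each = 10)
  bags <- lapply(1:20, function(i) {
    mu <- if (y[i] == 1) c(3, 3, 0) else c(-3, -3, 0)
    new_bag(matrix(rnorm(6, mu, 0.3), 2, 3, byrow = TRUE), paste0("b", i))
  })
  train <- miml_dataset(bags, matrix(y, ncol = 1), class_ids = "k",
                        domain = "source")
  models <- list(k = structure(list(A = diag(3), class_id = "k"),
                               class = "mimtl_metric"))
  hd <- fit_svm_head(train, models, cluster_ratio = 0.4, seed = 1)
  expect_equal(hd$k, 8L)   # round(0.4 * 20)
  pr <- predict(hd, train)
  expect_equal(unname(pr$labels[, "k"]), y)   # training accuracy 1
  # labels equal thresholded confidences everywhere
  expect_equal(pr$labels > 0.5 * 0, pr$confidences > 0.5, ignore_attr = TRUE)
  # deterministic across repeated calls
  expect_identical(pr, predict(hd, train))
})

test_that("single-label classes fall back to a constant predictor", {
  train <- make_labeled_train(6, 3, rep(1, 6), seed = 64)
  models <- list(k = structure(list(A = diag(3), class_id = "k"),
                               class = "mimtl_metric"))
  expect_message(hd <- fit_svm_head(train, models, seed = 1), "constant")
  pr <- predict(hd, train)
  expect_true(all(pr$labels[, "k"] == 1))
  expect_true(all(pr$confidences[, "k"] > 0.5))
})

test_that("head predictions have the right shape and class coverage", {
  ds <- rand_dataset(8, 3, 2, seed = 65, domain = "source")
  test <- rand_dataset(1, 3, 2, seed = 66, domain = "target")
  hp <- quick_hp()
  models <- train_per_class(ds, hyperparams = hp)
  hd <- knn_head(ds, models, r = 2, c = 2)
  pr <- predict(hd, test)
  expect_equal(dim(pr$labels), c(1L, 2L))
  expect_equal(dim(pr$confidences), c(1L, 2L))
  expect_error(predict(hd, rand_dataset(2, 4, 2, seed = 67)), "dimension")
})
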