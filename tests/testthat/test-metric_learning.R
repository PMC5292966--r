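test_that("mahalanobis_sq and bag_distance satisfy their contracts", {
  set.seed(20)
  A <- matrix(rnorm(16), 4)
  u <- rnorm(4); v <- rnorm(4)
  expect_equal(mahalanobis_sq(u, v, diag(4)), sum((u - v)^2))
  expect_equal(mahalanobis_sq(u, u, A), 0)
  oracle <- as.numeric(t(u - v) %*% t(A) %*% A %*% (u - v))
  expect_equal(mahalanobis_sq(u, v, A), oracle, tolerance = 1e-12)
  expect_error(mahalanobis_sq(u, v[1:3], A), "dimension")
  b1 <- rand_bag(3, 4, "p", seed = 21)
  b2 <- rand_bag(2, 4, "q", seed = 22)
  expect_equal(bag_distance(b1, b1, A), 0)
  expect_equal(bag_distance(b1, b2, A), bag_distance(b2, b1, A))
  s1 <- new_bag(c(1, 0, 0, 0), "s1"); s2 <- new_bag(c(0, 1, 0, 0), "s2")
  expect_equal(bag_distance(s1, s2, diag(4)), 2)
})

test_that("build_constraints enumerates weighted pairs per the one-vs-rest rule", {
  ds <- rand_dataset(5, 3, 1, seed = 30)
  ds$labels[, 1] <- c(1, 1, 0, 0, 0)
  cs <- build_constraints(ds, "c01", hyperparams = quick_hp())
  expect_equal(cs$n_between, 6L)           # 2 positives x 3 negatives
  expect_true(all(cs$w_between == 1))
  expect_equal(cs$n_within, n_instances(ds))
  # weighted: within weight = bag omega, between = product
  om <- c(2, 0.5, 1, 3, 0.25)
  csw <- build_constraints(ds, "c01", omega = om, hyperparams = quick_hp())
  sizes <- vapply(ds$bags, function(b) nrow(b$instances), integer(1))
  expect_equal(csw$w_within, rep(om, sizes))
  expect_equal(csw$w_between,
               om[csw$pairs[, 1]] * om[csw$pairs[, 2]])
  # pair labels: positives x negatives only
  expect_true(all(ds$labels[csw$pairs[, 1], 1] == 1))
  expect_true(all(ds$labels[csw$pairs[, 2], 1] == 0))
  expect_error(build_constraints(ds, "nope"), "not in dataset")
  ds0 <- ds; ds0$labels[, 1] <- 0
  expect_error(build_constraints(ds0, "c01"), "no positive")
})

test_that("between pairs are capped reproducibly under the seed", {
  ds <- rand_dataset(10, 3, 1, seed = 31)
  ds$labels[, 1] <- rep(c(1, 0), 5)
  hp <- quick_hp(max_pairs = 10L, seed = 77)
  cs1 <- build_constraints(ds, "c01", hyperparams = hp)
  cs2 <- build_constraints(ds, "c01", hyperparams = hp)
  expect_equal(cs1$n_between, 10L)
  expect_identical(cs1$pairs, cs2$pairs)
  expect_equal(nrow(unique(cs1$pairs)), 10L)
})

test_that("labeled target-domain bags join with weight exactly 1", {
  src <- rand_dataset(4, 3, 1, seed = 32)
  src$labels[, 1] <- c(1, 0, 0, 0)
  td <- rand_dataset(3, 3, 1, seed = 33, domain = "target")
  td$labels[, 1] <- c(1, 0, 1)
  om <- c(2, 2, 2, 2)
  cs <- build_constraints(src, "c01", omega = om, td_labeled = td,
                          hyperparams = quick_hp())
  # positives: src bag 1 (w 2), td bags 1,3 (w 1); negatives: src 2-4 (w 2), td 2 (w 1)
  expect_equal(cs$n_between, 3L * 4L)
  expect_equal(sort(unique(cs$w_between)), c(1, 2, 4))
  n_inst_td <- n_instances(td)
  expect_equal(tail(cs$w_within, n_inst_td), rep(1, n_inst_td))
})

test_that("penalty objective matches a term-by-term loop oracle", {
  set.seed(35)
  ds <- rand_dataset(3, 3, 1, seed = 35)
  ds$labels[, 1] <- c(1, 0, 1)
  hp <- quick_hp(lambda = 0.7, beta = 1.3, sigma = 4,
                 delta_s = 0.5, delta_d = 2)
  cs <- build_constraints(ds, "c01", omega = c(1.5, 0.8, 1), hyperparams = hp)
  A <- matrix(rnorm(9), 3)
  xi <- rnorm(cs$n_within, 0.2, 0.5)
  zeta <- rnorm(cs$n_between, 0.2, 0.5)
  # independent loop oracle
  f_or <- sum(A^2)
  for (t in seq_len(cs$n_within)) {
    u <- cs$U[, t]
    D <- sum((A %*% u)^2)
    f_or <- f_or + hp$lambda * cs$w_within[t] * xi[t] +
      hp$sigma * (max(0, D - 0.5 - xi[t])^2 + max(0, -xi[t])^2)
  }
  for (t in seq_len(cs$n_between)) {
    v <- cs$V[, t]
    D <- sum((A %*% v)^2)
    f_or <- f_or + hp$beta * cs$w_between[t] * zeta[t] +
      hp$sigma * (max(0, 2 - zeta[t] - D)^2 + max(0, -zeta[t])^2)
  }
  expect_equal(penalty_objective(A, xi, zeta, cs, hp), f_or,
               tolerance = 1e-12)
  # no-constraint edge: objective reduces to the Frobenius term
  cs0 <- cs; cs0$U <- cs$U[, 0]; cs0$w_within <- numeric(0)
  cs0$n_within <- 0L; cs0$V <- cs$V[, 0]; cs0$w_between <- numeric(0)
  cs0$n_between <- 0L
  expect_equal(penalty_objective(A, numeric(0), numeric(0), cs0, hp),
               sum(A^2))
  expect_error(penalty_objective(A, xi[-1], zeta, cs, hp), "slack")
})

test_that("penalty gradients match central finite differences", {
  for (seed in c(40, 41)) {
    set.seed(seed)
    d <- 4
    ds <- rand_dataset(3, d, 1, seed = seed)
    ds$labels[, 1] <- c(1, 0, 1)
    hp <- quick_hp(lambda = 0.5, beta = 2, sigma = 3,
                   delta_s = 0.4, delta_d = 1.5)
    cs <- build_constraints(ds, "c01", omega = runif(3, 0.5, 2),
                            hyperparams = hp)
    A <- diag(d) + 0.3 * matrix(rnorm(d * d), d)
    xi <- rnorm(cs$n_within, 0.1, 0.4)
    zeta <- rnorm(cs$n_between, 0.1, 0.4)
    g <- penalty_gradients(A, xi, zeta, cs, hp)
    h <- 1e-5
    fd <- function(f_plus, f_minus) (f_plus - f_minus) / (2 * h)
    gA_num <- matrix(0, d, d)
    for (i in seq_len(d)) for (j in seq_len(d)) {
      Ap <- A; Ap[i, j] <- Ap[i, j] + h
      Am <- A; Am[i, j] <- Am[i, j] - h
      gA_num[i, j] <- fd(penalty_objective(Ap, xi, zeta, cs, hp),
                         penalty_objective(Am, xi, zeta, cs, hp))
    }
    expect_lt(max(abs(g$grad_A - gA_num)) / max(abs(gA_num)), 1e-5)
    gx_num <- vapply(seq_along(xi), function(t) {
      xp <- xi; xp[t] <- xp[t] + h
      xm <- xi; xm[t] <- xm[t] - h
      fd(penalty_objective(A, xp, zeta, cs, hp),
         penalty_objective(A, xm, zeta, cs, hp))
    }, numeric(1))
    expect_lt(max(abs(g$grad_xi - gx_num)) / max(1, max(abs(gx_num))), 1e-5)
  }
})

test_that("interior points recover the analytic slack gradients", {
  ds <- rand_dataset(3, 3, 1, seed = 42)
  ds$labels[, 1] <- c(1, 1, 0)
  hp <- quick_hp(lambda = 0.9, beta = 1.1, sigma = 5,
                 delta_s = 100, delta_d = 101)
  cs <- build_constraints(ds, "c01", omega = c(1, 2, 3), hyperparams = hp)
  A <- diag(3)
  xi <- rep(0.5, cs$n_within)     # positive slack, no violation (D << delta_s)
  zeta <- rep(200, cs$n_between)  # slack large enough to satisfy the margin
  g <- penalty_gradients(A, xi, zeta, cs, hp)
  expect_equal(g$grad_xi, hp$lambda * cs$w_within)
  expect_equal(g$grad_zeta, hp$beta * cs$w_between)
  # no constraints: grad_A = 2A
  cs0 <- cs
  cs0$U <- cs$U[, 0]; cs0$w_within <- numeric(0); cs0$n_within <- 0L
  cs0$V <- cs$V[, 0]; cs0$w_between <- numeric(0); cs0$n_between <- 0L
  g0 <- penalty_gradients(A, numeric(0), numeric(0), cs0, hp)
  expect_equal(g0$grad_A, 2 * A)
})

test_that("fit_metric produces a non-increasing trace and converges", {
  ds <- rand_dataset(8, 4, 1, seed = 43)
  ds$labels[, 1] <- rep(c(1, 0), 4)
  hp <- metric_hyperparams(max_iter = 500)
  cs <- build_constraints(ds, "c01", hyperparams = hp)
  m <- fit_metric(cs, hp)
  expect_true(all(diff(m$trace) <= 1e-9))
  expect_true(m$converged)
  expect_s3_class(m, "mimtl_metric")
  # M = A'A is PSD at the solution
  expect_gte(min(eigen(crossprod(m$A), symmetric = TRUE)$values), -1e-10)
})

test_that("with only the regularizer active the map shrinks", {
  ds <- rand_dataset(2, 3, 1, seed = 44)
  ds$labels[, 1] <- c(1, 1)   # no negatives: no between constraints
  # satisfied within constraints at A = I and lambda = beta = 0: r(A) drives
  hp <- metric_hyperparams(lambda = 0, beta = 0, sigma = 100,
                           delta_s = 1e4, delta_d = 2e4, max_iter = 100)
  cs <- build_constraints(ds, "c01", hyperparams = hp)
  m <- fit_metric(cs, hp)
  expect_lte(sqrt(sum(m$A^2)), sqrt(3) + 1e-12)
})

test_that("train_per_class fits independent one-vs-rest models", {
  ds <- rand_dataset(10, 4, 3, seed = 45)
  ds$labels[, 3] <- 0   # class with no positives is skipped
  hp <- quick_hp()
  expect_warning(models <- train_per_class(ds, hyperparams = hp, classes = ds$class_ids),
                 "no positive")
  expect_setequal(names(models), c("c01", "c02"))
  one <- train_per_class(ds, hyperparams = hp, classes = "c01")
  expect_length(one, 1L)
  # per-class between pairs match a brute-force one-vs-rest recount
  for (k in c("c01", "c02")) {
    cs <- build_constraints(ds, k, hyperparams = hp)
    y <- ds$labels[, k]
    expect_equal(cs$n_between, sum(y == 1) * sum(y == 0))
  }
})

test_that("learned metric separates classes better than identity", {
  # two concepts separated along 2 coordinates, 30+30 bags, 10 seeds
  wins <- 0L
  for (s in 1:10) {
    cm <- matrix(0, 2, 6)
    cm[1, 3:4] <- 1.5
    cm[2, 5:6] <- 1.5
    cfg <- generator_config(d = 6, K = 2, n_source = 30, n_target = 30,
                            label_rate = 0.4, concept_means = cm,
                            concept_spread = 0.4, seed = 200 + s)
    g <- generate_shifted_miml(cfg)
    cent <- centralize(g$source)
    hp <- metric_hyperparams(max_iter = 400, seed = s)
    cs <- build_constraints(cent$dataset, "class0001", hyperparams = hp)
    m <- fit_metric(cs, hp)
    ratio <- function(A) {
      mean(colSums((A %*% cs$V)^2)) / mean(colSums((A %*% cs$U)^2))
    }
    if (ratio(m$A) >= ratio(diag(6))) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
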