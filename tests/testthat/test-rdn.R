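test_that("pairwise Euclidean distances are exact and symmetric", {
  A <- rbind(c(0, 0), c(3, 4))
  D <- pairwise_euclidean(A, A)
  expect_equal(D, rbind(c(0, 5), c(5, 0)))
  set.seed(1)
  B <- matrix(rnorm(40), 8, 5)
  DB <- pairwise_euclidean(B, B)
  expect_equal(DB, t(DB))
  expect_equal(DB, as.matrix(dist(B)), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(pairwise_euclidean(A, matrix(0, 2, 3)), "mismatch")
})

test_that("average k-NN distance matches hand enumeration on a line", {
  D <- pairwise_euclidean(matrix(c(0, 1, 3)), matrix(c(0, 1, 3)))
  expect_equal(avg_knn_distance(D, 1), c(1, 1, 2))
  expect_equal(avg_knn_distance(D, 2), c(2, 1.5, 2.5))
  expect_error(avg_knn_distance(D, 3), "smaller")
  # duplicated points have zero distance to their copy
  D2 <- pairwise_euclidean(matrix(c(0, 0, 5)), matrix(c(0, 0, 5)))
  expect_equal(avg_knn_distance(D2, 1), c(0, 0, 5))
  # monotone non-decreasing in k for every instance
  set.seed(3)
  Dr <- as.matrix(dist(matrix(rnorm(60), 20, 3)))
  avg <- vapply(1:19, function(k) avg_knn_distance(Dr, k),
                numeric(20))
  expect_true(all(diff(t(avg)) >= -1e-12))
})

test_that("the Tukey fence uses type-7 quartiles", {
  expect_equal(tukey_refval(rep(4, 10)), 4)        # IQR 0
  expect_equal(tukey_refval(1:8), 11.5)            # Q1 2.75, Q3 6.25
  v <- c(1, 1.2, 1.1, 0.9, 50)
  expect_gte(tukey_refval(v), quantile(v, 0.75, names = FALSE))
  expect_true(is.finite(tukey_refval(v)))
  expect_error(tukey_refval(numeric()), "empty")
})

test_that("neighbourhood radii average the within-fence neighbours", {
  D <- pairwise_euclidean(matrix(c(0, 1, 3)), matrix(c(0, 1, 3)))
  expect_equal(neighborhood_thresholds(D, 2), c(1, 1.5, 2))
  expect_equal(neighborhood_thresholds(D, 0.5), c(0, 0, 0))
  expect_equal(neighborhood_thresholds(D, 10), c(2, 1.5, 2.5))
})

test_that("the step schedule scales radii by iteration band", {
  sch <- rdn_schedule()
  expect_equal(step_scale(10, sch), 1 / 3)
  expect_equal(step_scale(1, sch), 1 / 3)
  expect_equal(step_scale(30, sch), 1 / 3)
  expect_equal(step_scale(31, sch), 1 / 2)
  expect_equal(step_scale(35, sch), 1 / 2)
  expect_equal(step_scale(40, sch), 1 / 2)
  expect_equal(step_scale(41, sch), 1)
  expect_equal(step_scale(50, sch), 1)
  expect_equal(step_scale(1:100, unit_schedule()), rep(1, 100))
  custom <- rdn_schedule(c(5, 10), c(0.25, 0.75))
  expect_equal(step_scale(c(3, 7, 99), custom), c(0.25, 0.75, 0.75))
  expect_error(rdn_schedule(c(10, 5), c(1, 1)), "increasing")
  expect_error(rdn_schedule(5, -1), "positive")
  expect_error(step_scale(0, sch), ">= 1")
})

test_that("coverage equals the brute-force pair scan and handles degeneracies", {
  # coincident query with a positive-radius instance is covered
  cov <- coverage_at_iteration(matrix(0, 1, 1), effective_radii = 1)
  expect_true(cov$included)
  # zero radii never cover, even at distance zero
  cov0 <- coverage_at_iteration(matrix(0, 1, 1), effective_radii = 0)
  expect_false(cov0$included)
  expect_error(coverage_at_iteration(matrix(0, 1, 1), 1, min_neighbors = 0),
               ">= 1")

  set.seed(8)
  Dq <- matrix(abs(rnorm(20 * 10)), 20, 10)
  r <- c(abs(rnorm(8)), 0, 0)
  for (mn in c(1, 2, 3)) {
    got <- coverage_at_iteration(Dq, r, mn)
    want <- sapply(seq_len(20), function(q)
      sum(vapply(seq_len(10), function(i)
        r[i] > 0 && Dq[q, i] <= r[i], logical(1))))
    expect_identical(got$n_covering, as.integer(want))
    expect_identical(got$included, want >= mn)
  }
})

test_that("rdn profiles match the naive full recomputation oracle", {
  for (s in 1:6) {
    set.seed(100 + s)
    n <- sample(15:40, 1); m <- sample(5:25, 1); d <- sample(1:4, 1)
    k_max <- sample(3:8, 1)
    train <- random_set(n, d, seed = 200 + s)
    ext <- random_set(m, d, seed = 300 + s)
    W <- runif(n)
    fit <- rdn(train, W, k_max = k_max, schedule = rdn_schedule())
    prof <- ad_profile_rdn(fit, list(e = ext))
    oracle <- naive_rdn_oracle(
      apply_standardizer(fit$standardizer, train),
      apply_standardizer(fit$standardizer, ext),
      W, k_max, step_scale(seq_len(k_max), rdn_schedule()),
      min_neighbors = 1)
    expect_identical(prof$n_included_cum, oracle$n_included_cum)
    expect_identical(predict(fit, ext)$first_k, oracle$first_k)
  }
})

test_that("cumulative inclusion is a union: non-decreasing in k", {
  st <- simulate_study(seed = 21)
  p <- rdn_profile(st$train, st$weights,
                   list(e1 = st$external_1, e2 = st$external_2),
                   k_max = 45)
  for (ds in c("e1", "e2")) {
    cnt <- profile_dataset(p, ds)$n_included_cum
    expect_true(all(diff(cnt) >= 0))
  }
})

test_that("shrinking one weight never increases any covering count", {
  train <- random_set(25, 3, seed = 31)
  ext <- random_set(12, 3, seed = 32)
  W <- runif(25, 0.3, 1)
  fit <- rdn(train, W, k_max = 10)
  base_cov <- predict(fit, ext)$n_covering
  for (i in c(1, 10, 25)) {
    W2 <- W; W2[i] <- W2[i] * 0.2
    cov2 <- predict(rdn(train, W2, k_max = 10), ext)$n_covering
    expect_true(all(cov2 <= base_cov))
  }
})

test_that("raising min_neighbors only removes compounds from the AD", {
  train <- random_set(30, 3, seed = 41)
  ext <- random_set(15, 3, seed = 42)
  W <- runif(30, 0.5, 1)
  f1 <- rdn(train, W, k_max = 12, min_neighbors = 1)
  p1 <- predict(f1, ext)
  for (mn in c(2, 4)) {
    fm <- rdn(train, W, k_max = 12, min_neighbors = mn)
    pm <- predict(fm, ext)
    expect_true(all(pm$included <= p1$included))
    both <- pm$included & p1$included
    expect_true(all(pm$first_k[both] >= p1$first_k[both]))
  }
})

test_that("dk-NN is the unweighted unit-step special case, bit for bit", {
  for (s in 1:5) {
    train <- random_set(sample(15:35, 1), sample(2:4, 1), seed = 500 + s)
    ext <- random_set(10, ncol(train$X), seed = 600 + s)
    via_rdn <- rdn_profile(train, rep(1, nrow(train$X)), list(e = ext),
                           k_max = 8, schedule = unit_schedule())
    via_dknn <- dknn_profile(train, list(e = ext), k_max = 8)
    df1 <- as.data.frame(via_rdn); df2 <- as.data.frame(via_dknn)
    expect_identical(df1$n_included_cum, df2$n_included_cum)
    expect_identical(df1$accuracy_cum, df2$accuracy_cum)
    expect_identical(attr(via_dknn, "method"), "dknn")
  }
})

test_that("all-zero weights give an empty AD at every iteration", {
  train <- random_set(20, 2, seed = 51)
  ext <- random_set(10, 2, seed = 52)
  p <- rdn_profile(train, rep(0, 20), list(e = ext), k_max = 6)
  expect_true(all(p$n_included_cum == 0))
  expect_true(all(is.na(p$accuracy_cum)))
})

test_that("fit guards reject out-of-contract inputs", {
  train <- random_set(10, 2, seed = 61)
  expect_error(rdn(train, k_max = 10), "smaller")
  expect_error(rdn(train, weights = rep(0.5, 3), k_max = 5), "per training")
  expect_error(rdn(train, weights = rep(2, 10), k_max = 5), "\\[0, 1\\]")
  fit <- rdn(train, k_max = 5)
  ext <- random_set(5, 2, seed = 62)
  ext$correct <- NULL
  expect_error(ad_profile_rdn(fit, list(e = ext)), "correct")
})
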