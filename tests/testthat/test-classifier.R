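make_clouds <- function(n, seed0 = 100) {
  lapply(seq_len(n), function(k)
    generate_fresh_cloud(cabernet_shape(), 250, rng_seed = seed0 + k))
}

test_that("similarity matrices match entry-wise ICP recomputation", {
  clouds <- preprocess_clouds(make_clouds(5))
  M <- build_train_matrix(clouds)
  expect_identical(dim(M), c(5L, 5L))
  expect_identical(diag(M), rep(0, 5))
  for (i in 1:5) for (j in 1:5) {
    if (i != j)
      expect_identical(M[i, j], icp(clouds[[i]], clouds[[j]])$mse)
  }
  TE <- build_test_matrix(clouds[1:2], clouds)
  expect_identical(dim(TE), c(2L, 5L))
  expect_identical(TE[1, 2], M[1, 2])
  expect_lt(TE[1, 1], 1e-12)            # self-pair recomputed, near zero
  expect_error(build_train_matrix(clouds[1]),
               class = "carposort_parameter_error")
  expect_error(build_test_matrix(list(), clouds),
               class = "carposort_empty_input_error")
})

test_that("duplicated clouds give a vanishing off-diagonal", {
  cl <- preprocess_clouds(make_clouds(1))[[1]]
  M <- build_train_matrix(list(cl, cl))
  expect_lt(max(M), 1e-12)
})

test_that("train-column z-scoring carries over to test rows", {
  set.seed(1)
  M <- matrix(rexp(30), 6, 5)
  M[, 3] <- 2                           # constant column
  params <- fit_normalizer(M)
  Z <- apply_normalizer(M, params)
  expect_equal(colMeans(Z), rep(0, 5), tolerance = 1e-9)
  expect_equal(apply(Z[, -3], 2, sd), rep(1, 4), tolerance = 1e-9)
  expect_identical(Z[, 3], rep(0, 6))
  # a test row equal to a train row normalizes identically
  Zt <- apply_normalizer(M[c(2, 4), , drop = FALSE], params)
  expect_equal(Zt, Z[c(2, 4), ], tolerance = 1e-12)
  expect_error(apply_normalizer(M[, 1:3], params),
               class = "carposort_parameter_error")
})

test_that("LDA separates tight clusters and respects the rank bound", {
  set.seed(2)
  centers <- matrix(rnorm(50, sd = 8), 5, 10)
  X <- centers[rep(1:5, each = 12), ] + matrix(rnorm(600, sd = 0.3), 60)
  y <- rep(letters[1:5], each = 12)
  m <- lda_fit(X, y, gamma = 1e-3)
  expect_identical(ncol(m$projection), 4L)
  expect_identical(lda_predict(m, X), y)
  # held-out draws from the same clusters
  Xh <- centers[rep(1:5, each = 20), ] + matrix(rnorm(1000, sd = 0.3), 100)
  expect_gte(mean(lda_predict(m, Xh) == rep(letters[1:5], each = 20)),
             0.95)
  expect_error(lda_fit(X, rep("a", 60)),
               class = "carposort_parameter_error")
  expect_error(lda_fit(X, y, gamma = -1),
               class = "carposort_parameter_error")
  expect_error(lda_predict(m, X[, 1:3]),
               class = "carposort_parameter_error")
})

test_that("permuted labels yield chance-level training accuracy", {
  set.seed(3)
  X <- matrix(rnorm(80 * 5), 80, 5)     # two identically distributed classes
  y <- sample(rep(c("a", "b"), each = 40))
  m <- lda_fit(X, y, gamma = 1e-3)
  acc <- mean(lda_predict(m, X) == y)
  # 99% binomial band around 0.5 at n = 80, widened for training optimism
  expect_lt(abs(acc - 0.5), 0.2)
})

test_that("LDA agrees with an independent implementation when well-posed", {
  skip_if_not_installed("MASS")
  set.seed(4)
  centers <- matrix(c(0, 0, 6, 0, 0, 6), 3, 2, byrow = TRUE)
  X <- centers[rep(1:3, each = 15), ] + matrix(rnorm(90, sd = 1), 45)
  y <- rep(c("a", "b", "c"), each = 15)
  ours <- lda_predict(lda_fit(X, y, gamma = 1e-6), X)
  ref <- as.character(predict(MASS::lda(X, grouping = factor(y)), X)$class)
  expect_identical(ours, ref)
})

test_that("ties in centroid distance go to the first training label", {
  X <- rbind(c(-1, 0), c(-1, 0.1), c(1, 0), c(1, -0.1))
  y <- c("b", "b", "a", "a")            # first label encountered is "b"
  m <- lda_fit(X, y, gamma = 1e-3)
  expect_identical(lda_predict(m, matrix(c(0, 0), 1)), "b")
})

test_that("the tournament accumulates sessions reproducibly", {
  model <- table2_model()
  cond <- charring_condition(200, 2)
  vars <- default_varieties()[c("Cabernet Sauvignon", "V98")]
  pools <- lapply(1:2, function(k)
    generate_seed_batch(vars[[k]], 5, cond, model, n_points = 250,
                        rng_seed = 30 + k))
  train <- preprocess_clouds(c(unclass(pools[[1]]), unclass(pools[[2]])))
  labels <- rep(names(vars), each = 5)
  test <- preprocess_clouds(generate_seed_batch(
    vars[[1]], 4, cond, model, n_points = 250, rng_seed = 40))
  te_labels <- rep(names(vars)[1], 4)

  cache <- pairwise_mse_matrix(c(train, test))
  r1 <- tournament(train, labels, test, te_labels, n_sessions = 4,
                   rng_seed = 5, mse_cache = cache)
  # cached and recomputed sessions are identical
  r2 <- tournament(train, labels, test, te_labels, n_sessions = 4,
                   rng_seed = 5)
  expect_identical(r1, r2)
  # reproducible from the seed, sensitive to it
  r3 <- tournament(train, labels, test, te_labels, n_sessions = 4,
                   rng_seed = 5, mse_cache = cache)
  expect_identical(r1, r3)

  # a single session is its own accumulation
  r4 <- tournament(train, labels, test, te_labels, n_sessions = 1,
                   rng_seed = 5, mse_cache = cache)
  expect_identical(length(r4$per_session_accuracy), 1L)
  expect_identical(r4$accumulative_accuracy, r4$per_session_accuracy[1])
  expect_identical(r4$per_session_accuracy[1], r1$per_session_accuracy[1])

  # confusion conservation: every classified pip lands in exactly one cell
  expect_identical(sum(r1$confusion_counts), 4L * 4L)
  expect_equal(unname(rowSums(r1$confusion_counts)[names(vars)[1]]), 16)
  # accumulative accuracy is the overall correct fraction
  expect_equal(r1$accumulative_accuracy, mean(r1$per_session_accuracy),
               tolerance = 1e-12)
  # two well-separated varieties classify perfectly at mild charring
  expect_identical(r1$accumulative_accuracy, 1)
})

test_that("the calibrated panel classifies mild-charred tests accurately", {
  model <- table2_model()
  cond <- charring_condition(200, 2)
  vars <- default_varieties()
  pools <- lapply(seq_along(vars), function(k)
    generate_seed_batch(vars[[k]], 10, cond, model, n_points = 300,
                        rng_seed = derive_seed(1, 100 + k)))
  train <- preprocess_clouds(do.call(c, lapply(pools, unclass)))
  labels <- rep(names(vars), each = 10)
  test <- preprocess_clouds(generate_seed_batch(
    vars[["Cabernet Sauvignon"]], 20, cond, model, n_points = 300,
    rng_seed = derive_seed(1, 201)))
  res <- tournament(train, labels, test,
                    rep("Cabernet Sauvignon", 20), n_sessions = 25,
                    rng_seed = 1)
  expect_gte(res$accumulative_accuracy, 0.9)
})
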