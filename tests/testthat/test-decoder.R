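test_that("zero data with a positive penalty gives the zero solution", {
  set.seed(1)
  M <- matrix(rbinom(60, 1, 0.3), 12, 5)
  x <- solve_lasso(M, rep(0, 12), lambda = 0.25)
  expect_equal(as.numeric(x), rep(0, 5))
})

test_that("identity designs are solved by exact soft thresholding", {
  x <- solve_lasso(diag(4), c(10, 0, 0, 0), lambda = 0.25)
  expect_equal(as.numeric(x), c(9.75, 0, 0, 0), tolerance = 1e-8)
  x2 <- solve_lasso(diag(3), c(5, -2, 0.1), lambda = 0.25)
  expect_equal(as.numeric(x2), c(4.75, -1.75, 0), tolerance = 1e-8)
})

test_that("noiseless sparse recovery matches the exhaustive-support oracle", {
  set.seed(2)
  for (rep in 1:8) {
    n <- sample(10:20, 1)
    k <- sample(1:3, 1)
    T_ <- 12
    # distinct design columns keep the best support identifiable
    repeat {
      M <- matrix(rbinom(T_ * n, 1, 0.3), T_, n)
      if (!anyDuplicated(t(M))) break
    }
    sup <- sort(sample(n, k))
    x_true <- numeric(n)
    x_true[sup] <- runif(k, 0.5, 1.5) * sample(c(-1, 1), k, replace = TRUE)
    y <- drop(M %*% x_true)
    fit <- solve_lasso(M, y, lambda = 1e-4, tol = 1e-10)
    got <- sort(which(abs(fit) > 1e-3))
    oracle <- best_sparse_support(M, y, k)
    expect_equal(got, oracle)
    expect_equal(as.numeric(fit)[sup], x_true[sup], tolerance = 1e-2)
  }
})

test_that("the solver agrees with an independent lasso implementation", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  T_ <- 40; n <- 25
  M <- matrix(rbinom(T_ * n, 1, 0.3), T_, n)
  x_true <- numeric(n); x_true[c(3, 11, 20)] <- c(2, -1.5, 1)
  y <- drop(M %*% x_true) + rnorm(T_, 0, 0.3)
  for (lam in c(0.5, 2)) {
    mine <- solve_lasso(M, y, lam, tol = 1e-10)
    gl <- glmnet::glmnet(M, y, alpha = 1, lambda = lam / T_,
                         standardize = FALSE, intercept = FALSE,
                         thresh = 1e-14)
    expect_equal(as.numeric(mine), as.numeric(gl$beta), tolerance = 1e-5)
  }
  # sign-constrained route against glmnet box limits
  e_idx <- 1:15; i_idx <- 16:25
  mine <- solve_sign_constrained(M, y, 0.5, e_idx, i_idx, tol = 1e-10)
  lower <- ifelse(seq_len(n) %in% e_idx, 0, -Inf)
  upper <- ifelse(seq_len(n) %in% e_idx, Inf, 0)
  gl <- glmnet::glmnet(M, y, alpha = 1, lambda = 0.5 / T_,
                       standardize = FALSE, intercept = FALSE,
                       lower.limits = lower, upper.limits = upper,
                       thresh = 1e-14)
  expect_equal(as.numeric(mine), as.numeric(gl$beta), tolerance = 1e-5)
})

test_that("basis pursuit honours the residual bound and its limits", {
  set.seed(4)
  fx <- make_linear_fixture(20, 12, 0.1, noise_sd = 0)
  # epsilon at the data norm: zero is feasible and L1-minimal
  x0 <- solve_basis_pursuit(fx$M, fx$y, epsilon = sqrt(sum(fx$y^2)))
  expect_equal(as.numeric(x0), rep(0, 20))
  # noiseless, epsilon = 0: exact recovery matching the lasso limit
  x <- solve_basis_pursuit(fx$M, fx$y, epsilon = 0)
  expect_equal(as.numeric(x), fx$x_true, tolerance = 1e-4)
  # the L1 norm is non-increasing in epsilon
  eps_grid <- c(0.01, 0.5, 1, 2, 4)
  l1 <- vapply(eps_grid, function(e)
    attr(solve_basis_pursuit(fx$M, fx$y, e), "l1_norm"), numeric(1))
  expect_true(all(diff(l1) <= 1e-8))
})

test_that("sign constraints bind exactly and cost objective value", {
  set.seed(5)
  T_ <- 30; n <- 12
  M <- matrix(rbinom(T_ * n, 1, 0.3), T_, n)
  x_true <- runif(n, 0, 1)  # all nonnegative
  y <- drop(M %*% x_true) + rnorm(T_, 0, 0.1)
  un <- solve_lasso(M, y, 0.5, tol = 1e-10)
  if (all(un >= 0)) {
    co <- solve_sign_constrained(M, y, 0.5, e_idx = 1:n, i_idx = integer(0),
                                 tol = 1e-10)
    expect_equal(as.numeric(co), as.numeric(un), tolerance = 1e-7)
  }
  # an inhibitory cell never gets a positive estimate
  co2 <- solve_sign_constrained(M, y, 0.5, e_idx = 2:n, i_idx = 1L,
                                tol = 1e-10)
  expect_lte(co2[1], 1e-12)
  # restricting the feasible set cannot improve the objective
  expect_gte(attr(co2, "objective") + 1e-9, attr(un, "objective"))
})

test_that("cell types are classified by magnitude-weighted column sums", {
  x_hat <- cbind(c(0.2, 0, 0.4), c(0.1, -0.9, 0), c(0, 0, 0))
  expect_equal(classify_cell_types(x_hat),
               c("excitatory", "inhibitory", "excitatory"))
})

test_that("relative thresholding keeps weights above 1% of the maximum", {
  x_hat <- matrix(c(1.0, 0.02, 0.005, 0), 2, 2)
  adj <- threshold_weights(x_hat, 0.01)
  expect_equal(as.vector(adj), c(1L, 1L, 0L, 0L))
  expect_equal(threshold_weights(matrix(0, 3, 3)), matrix(0L, 3, 3))
  # scale invariance
  expect_equal(threshold_weights(10 * x_hat, 0.01), adj)
  # per-neuron reference uses each row's own maximum
  x2 <- rbind(c(10, 0.5), c(0.05, 0.0004))
  expect_equal(threshold_weights(x2, 0.01, per_neuron = TRUE),
               rbind(c(1L, 1L), c(1L, 0L)))
})

test_that("declared connections are non-increasing in the penalty", {
  set.seed(6)
  fx <- make_linear_fixture(30, 20, 0.15, noise_sd = 0.4)
  counts <- vapply(c(0.05, 0.25, 1, 4, 16), function(lam) {
    fit <- solve_lasso(fx$M, fx$y, lam, tol = 1e-10)
    sum(threshold_weights(matrix(fit, 1), 0.01))
  }, numeric(1))
  violations <- sum(diff(counts) > 0)
  expect_lte(violations, 1)
  if (any(diff(counts) > 0)) expect_lte(max(diff(counts)), 1)
})

test_that("decoding a measurement set fills every neuron's row", {
  set.seed(7)
  n_obs <- 12; T_ <- 30
  M <- generate_stimulation_matrix(T_, n_obs, 0.3)
  W <- matrix(0, n_obs, n_obs)
  W[cbind(sample(n_obs, 8, TRUE), sample(n_obs, 8, TRUE))] <- runif(8, 1, 2)
  diag(W) <- 0
  y <- M %*% t(W)
  ms <- structure(list(y = y, excluded = M == 1L), class = "measurement_set")
  dec <- decode_connectivity(ms, M, lambda = 1e-3)
  expect_equal(dim(dec$x_hat), c(n_obs, n_obs))
  expect_true(all(diag(dec$x_hat) == 0))
  expect_true(all(dec$diagnostics$status == "optimal"))
  # inferred-sign mode never yields a mixed-sign presynaptic column
  dec2 <- decode_connectivity(ms, M, lambda = 1e-3,
                              mode = "inferred_sign_constrained")
  for (j in seq_len(n_obs)) {
    col <- dec2$x_hat[, j]
    expect_true(all(col >= -1e-9) || all(col <= 1e-9))
  }
})

test_that("the sequential baseline recovers a noiseless map exactly", {
  set.seed(8)
  n <- 10
  W <- matrix(0, n, n)
  W[cbind(sample(n, 6), sample(n, 6))] <- c(2, -3, 1.5, 0.8, -1, 2.5)
  diag(W) <- 0
  M <- diag(n)[sample(n), ]
  storage.mode(M) <- "integer"
  # responses proportional to the presynaptic column, constant factor 0.5
  y <- 0.5 * M %*% t(W)
  ms <- structure(list(y = y, excluded = M == 1L), class = "measurement_set")
  x_hat <- siso_baseline(ms, M)
  expect_equal(x_hat, 0.5 * W, tolerance = 1e-12, ignore_attr = TRUE)
  adj <- threshold_weights(x_hat, 0.01)
  expect_equal(adj, (W != 0) * 1L, ignore_attr = TRUE)
  # one trial per cell is required and enforced
  expect_error(siso_baseline(ms, matrix(1L, n, n)), "one stimulated cell")
  # zero responses give zero weights
  ms0 <- structure(list(y = 0 * y, excluded = M == 1L),
                   class = "measurement_set")
  expect_true(all(siso_baseline(ms0, M) == 0))
})
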