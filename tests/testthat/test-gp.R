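test_that("kernels are monotone, bounded and positive semidefinite", {
  r <- seq(0, 10, by = 0.1)
  for (kind in c("exponential", "matern52")) {
    k <- kernel_eval(r, kind, sigma_f = 1.3, length_scale = 0.8)
    expect_equal(k[1], 1.3^2)
    expect_true(all(diff(k) <= 0))
    expect_true(all(k > 0))
  }
  expect_error(kernel_eval(-1, "exponential"), "nonnegative")
  set.seed(11)
  for (i in 1:10) {
    X <- matrix(rnorm(8 * 3), 8, 3)
    D <- as.matrix(dist(X))
    for (kind in c("exponential", "matern52")) {
      K <- kernel_eval(D, kind, 1, 0.7)
      expect_gte(min(eigen(K, symmetric = TRUE,
                           only.values = TRUE)$values), -1e-8)
    }
  }
})

test_that("log marginal likelihood matches the dense-determinant oracle", {
  set.seed(21)
  for (i in 1:5) {
    n <- 6
    X <- matrix(rnorm(n * 2), n, 2)
    y <- rnorm(n)
    for (kind in c("exponential", "matern52")) {
      for (basis in c("constant", "linear")) {
        fit <- fit_gp(X, y, kind, basis, sigma_f = 1.1, length_scale = 0.9,
                      sigma_y = 0.3, standardize = FALSE)
        expect_equal(fit$lml, oracle_lml(X, y, kind, basis, 1.1, 0.9, 0.3),
                     tolerance = 1e-8)
        expect_equal(log_marginal_likelihood(fit, X, y), fit$lml,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("likelihood penalizes over-noising beyond the residual scale", {
  set.seed(2)
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  lml <- sapply(c(1, 5, 25, 125), function(sy)
    fit_gp(X, y, "matern52", "constant", sigma_f = 1, length_scale = 1,
           sigma_y = sy, standardize = FALSE)$lml)
  expect_true(all(diff(lml) < 0))
})

test_that("constant labels collapse to the basis coefficient", {
  X <- matrix(rnorm(30), 15, 2)
  y <- rep(4.2, 15)
  fit <- fit_gp(X, y, "matern52", "constant")
  pr <- predict(fit, matrix(rnorm(10), 5, 2))
  expect_equal(pr$mean, rep(4.2, 5), tolerance = 1e-6)
})

test_that("vanishing signal variance reduces to the linear GLS fit", {
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2)
  y <- drop(2 + X %*% c(1.5, -0.7) + rnorm(20, 0, 0.1))
  fit <- fit_gp(X, y, "exponential", "linear", sigma_f = 1e-8,
                length_scale = 1, sigma_y = 0.1, standardize = FALSE)
  ols <- lm(y ~ X)
  Xq <- matrix(rnorm(10), 5, 2)
  pr <- predict(fit, Xq)
  expect_equal(pr$mean, drop(cbind(1, Xq) %*% coef(ols)), tolerance = 1e-4)
})

test_that("prediction is linear in the labels at fixed hyperparameters", {
  set.seed(5)
  X <- matrix(rnorm(24), 12, 2)
  y1 <- rnorm(12); y2 <- rnorm(12)
  Xq <- matrix(rnorm(8), 4, 2)
  pr <- function(y) predict(fit_gp(X, y, "matern52", "linear", sigma_f = 1,
                                   length_scale = 1.2, sigma_y = 0.2,
                                   standardize = FALSE), Xq)$mean
  expect_equal(pr(y1 + y2), pr(y1) + pr(y2), tolerance = 1e-9)
  expect_equal(pr(3 * y1), 3 * pr(y1), tolerance = 1e-9)
})

test_that("far from the data the posterior reverts to the basis", {
  set.seed(6)
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  fit <- fit_gp(X, y, "exponential", "linear", sigma_f = 1,
                length_scale = 0.5, sigma_y = 0.1, standardize = FALSE)
  Xfar <- matrix(50 + rnorm(4), 2, 2)
  pr <- predict(fit, Xfar)
  basis_only <- drop(cbind(1, Xfar) %*% fit$beta)
  expect_equal(pr$mean, basis_only, tolerance = 1e-6)
  expect_gte(min(pr$sd), fit$sigma_f)   # at least the prior signal sd
})

test_that("hyperparameter estimation recovers the length scale", {
  # data drawn from the prior: l recovered within a factor of 2 in >= 80%
  set.seed(31)
  true_l <- 1.5
  hits <- 0
  reps <- 20
  for (i in 1:reps) {
    n <- 150
    X <- matrix(rnorm(n * 2), n, 2)
    K <- kernel_eval(as.matrix(dist(X)), "matern52", 1, true_l)
    diag(K) <- 1 + 1e-8
    y <- drop(t(chol(K)) %*% rnorm(n)) + rnorm(n, 0, 0.1)
    fit <- fit_gp(X, y, "matern52", "constant", seed = i)
    # compare in standardized units (X columns are ~unit scale already)
    if (fit$length_scale > true_l / 2 && fit$length_scale < true_l * 2) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / reps, 0.8)
})

test_that("model serialization round-trips predictions exactly", {
  set.seed(8)
  X <- matrix(rnorm(30), 15, 2)
  y <- rnorm(15)
  fit <- fit_gp(X, y, "matern52", "linear", seed = 3)
  js <- gp_to_json(fit)
  fit2 <- gp_from_json(js)
  Xq <- matrix(rnorm(12), 6, 2)
  p1 <- predict(fit, Xq); p2 <- predict(fit2, Xq)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-10)
  expect_equal(p1$sd, p2$sd, tolerance = 1e-8)
})

test_that("degenerate fits fail loudly", {
  X <- matrix(rnorm(6), 3, 2)
  expect_error(fit_gp(X, rnorm(3), "exponential", "linear"),
               "at least")
})
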