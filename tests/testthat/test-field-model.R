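test_that("kernel evaluates the exponentiated-quadratic closed form", {
  kp <- kernel_params(1, 1)
  # zero distance gives the signal variance for any hyperparameters
  expect_equal(kernel_eval(c(0.3, -1), c(0.3, -1), kernel_params(7, 0.2)), 49)
  # unit distance at unit hyperparameters: exp(-1/2)
  expect_equal(kernel_eval(c(0, 0), c(1, 0), kp), exp(-0.5), tolerance = 1e-12)
  # symmetric in its arguments and monotone decreasing in distance
  a <- c(0.4, 2.2); b <- c(3.1, 0.7)
  expect_equal(kernel_eval(a, b, kp), kernel_eval(b, a, kp))
  d <- seq(0, 20, by = 0.5)
  vals <- vapply(d, function(dd) kernel_eval(c(0, 0), c(dd, 0), kp), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], 1e-12)
  expect_error(kernel_params(-1, 1), "positive")
  expect_error(kernel_params(1, 0), "positive")
})

test_that("posterior reduces to the prior with no data and interpolates one point", {
  kp <- kernel_params(2, 1.5)
  prior <- gp_posterior(gp_model(NULL, NULL, kp), rbind(c(0, 0), c(4, 1)))
  expect_equal(prior$mean, c(0, 0))
  expect_equal(prior$variance, c(4, 4))
  # one noise-free training pair: exact interpolation, zero variance
  m <- gp_model(c(1, 2), 37.5, kp, noise_power = 0)
  p <- gp_posterior(m, c(1, 2))
  expect_equal(p$mean, 37.5, tolerance = 1e-8)
  expect_lt(p$variance, 1e-6)
})

test_that("two-point posterior matches the explicit 2x2 solve", {
  kp <- kernel_params(3, 0.8)
  Xa <- rbind(c(0, 0), c(1, 0.5))
  ya <- c(2, -1)
  np <- 0.3
  for (xq in list(c(0.2, 0.1), c(2, 2), c(0.5, 0.25))) {
    oracle <- dense_gp_moments(Xa, ya, rbind(xq), kp, np)
    got <- gp_posterior(gp_model(Xa, ya, kp, np), xq)
    expect_equal(got$mean, oracle$mean, tolerance = 1e-10)
    expect_equal(got$variance, oracle$variance, tolerance = 1e-10)
  }
})

test_that("batch predictions equal per-point predictions", {
  kp <- kernel_params(2, 1)
  Xa <- rand_loci(8, seed = 11)
  ya <- draw_gp(Xa, kp, 0.1, seed = 12)
  m <- gp_model(Xa, ya, kp, 0.1)
  Xq <- rand_loci(5, seed = 13)
  batch <- gp_posterior(m, Xq)
  for (i in 1:5) {
    one <- gp_posterior(m, Xq[i, ])
    expect_equal(batch$mean[i], one$mean)
    expect_equal(batch$variance[i], one$variance)
  }
})

test_that("posterior variance matches the dense Schur-complement oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    kp <- kernel_params(runif(1, 0.5, 5), runif(1, 0.3, 2))
    np <- runif(1, 0, 0.5)
    n <- sample(2:10, 1)
    Xa <- rand_loci(n, seed = 100 + seed)
    ya <- rnorm(n)
    Xq <- rand_loci(4, seed = 200 + seed)
    oracle <- dense_gp_moments(Xa, ya, Xq, kp, np)
    got <- gp_posterior(gp_model(Xa, ya, kp, np), Xq)
    expect_equal(got$variance, oracle$variance, tolerance = 1e-8)
    expect_equal(got$mean, oracle$mean, tolerance = 1e-8)
  }
})

test_that("posterior variance never increases when a training point is added", {
  kp <- kernel_params(2, 1)
  np <- 0.05
  Xq <- rand_loci(20, seed = 31)
  for (seed in 1:3) {
    Xa <- rand_loci(6, seed = 40 + seed)
    ya <- draw_gp(Xa, kp, np, seed = 50 + seed)
    v1 <- gp_posterior(gp_model(Xa, ya, kp, np), Xq)$variance
    xnew <- rand_loci(1, seed = 60 + seed)
    v2 <- gp_posterior(gp_model(rbind(Xa, xnew), c(ya, 0), kp, np), Xq)$variance
    expect_true(all(v2 <= v1 + 1e-10))
  }
})

test_that("predictive mean is invariant under permutation of training rows", {
  kp <- kernel_params(1.5, 0.7)
  Xa <- rand_loci(9, seed = 71)
  ya <- draw_gp(Xa, kp, 0.2, seed = 72)
  Xq <- rand_loci(6, seed = 73)
  p1 <- gp_posterior(gp_model(Xa, ya, kp, 0.2), Xq)
  set.seed(74); perm <- sample(9)
  p2 <- gp_posterior(gp_model(Xa[perm, ], ya[perm], kp, 0.2), Xq)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-9)
  expect_equal(p1$variance, p2$variance, tolerance = 1e-9)
})

test_that("noise-free posterior interpolates all training values", {
  kp <- kernel_params(2, 1.2)
  Xa <- rand_loci(10, seed = 81)
  ya <- draw_gp(Xa, kp, 0, seed = 82)
  m <- gp_model(Xa, ya, kp, noise_power = 0)
  p <- gp_posterior(m, Xa)
  expect_equal(p$mean, ya, tolerance = 1e-6)
})

test_that("marginal likelihood matches the dense Gaussian log-density", {
  # 1 point at its mean: -2 log density = log(2*pi*v)
  kp <- kernel_params(2, 1)
  m1 <- gp_model(c(0, 0), 0, kp, 0.5)
  v <- 4 + 0.5 + 1e-8 * 4
  expect_equal(neg_log_marginal_likelihood(m1), log(2 * pi * v), tolerance = 1e-12)
  # general case: direct multivariate-normal -2 log density via solve/det
  for (seed in 1:4) {
    set.seed(seed)
    kp <- kernel_params(runif(1, 0.5, 3), runif(1, 0.4, 2))
    np <- runif(1, 0.01, 1)
    X <- rand_loci(7, seed = 90 + seed)
    y <- rnorm(7)
    Kn <- kernel_eval(X, X, kp) + diag(np + 1e-8 * kp$signal_scale^2, 7)
    dense <- drop(t(y) %*% solve(Kn, y)) + determinant(Kn)$modulus[1] +
      7 * log(2 * pi)
    expect_equal(neg_log_marginal_likelihood(gp_model(X, y, kp, np)), dense,
                 tolerance = 1e-9)
  }
})

test_that("quadratic term of the evidence scales with the square of the data", {
  kp <- kernel_params(1.5, 1)
  X <- rand_loci(6, seed = 95)
  y <- draw_gp(X, kp, 0.3, seed = 96)
  nll1 <- neg_log_marginal_likelihood(gp_model(X, y, kp, 0.3))
  nll10 <- neg_log_marginal_likelihood(gp_model(X, 10 * y, kp, 0.3))
  Kn <- kernel_eval(X, X, kp) + diag(0.3 + 1e-8 * kp$signal_scale^2, 6)
  quad <- drop(t(y) %*% solve(Kn, y))
  expect_equal(nll10 - nll1, 99 * quad, tolerance = 1e-8)
})

test_that("hyperparameter fitting recovers a known bandwidth and is deterministic", {
  X <- rand_loci(200, seed = 301)
  y <- draw_gp(X, kernel_params(2, 1.0), 0.01, seed = 302)
  f1 <- fit_hyperparameters(X, y, restarts = 3, seed = 5)
  expect_gt(f1$kernel$bandwidth, 0.5)
  expect_lt(f1$kernel$bandwidth, 2.0)
  f2 <- fit_hyperparameters(X, y, restarts = 3, seed = 5)
  expect_identical(f1$kernel, f2$kernel)
  expect_identical(f1$noise_power, f2$noise_power)
})

test_that("constant-zero data drives the signal scale to its lower bound", {
  X <- rand_loci(12, seed = 311)
  f <- fit_hyperparameters(X, rep(0, 12), restarts = 2, seed = 1)
  expect_lt(f$kernel$signal_scale, 1e-4)
})

test_that("degenerate inputs raise informative errors", {
  kp <- kernel_params(1, 1)
  expect_error(gp_model(rbind(c(0, 0)), c(NA), kp), "non-finite")
  expect_error(gp_model(rbind(c(0, 0), c(1, 1)), c(1, 2, 3), kp), "equal")
  expect_error(fit_hyperparameters(rbind(c(0, 0), c(0, 0), c(0, 0)),
                                   c(1, 2, 3)), "distinct")
  expect_error(neg_log_marginal_likelihood(gp_model(NULL, NULL, kp)),
               "at least one")
})
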