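test_that("gaussian entropy matches its closed form and log law", {
  expect_equal(gaussian_entropy(1 / (2 * pi)), 0.5, tolerance = 1e-12)
  v <- c(0.1, 1, 7, 300)
  expect_equal(gaussian_entropy(2 * v) - gaussian_entropy(v),
               rep(log(2) / 2, 4), tolerance = 1e-12)
  expect_true(all(diff(gaussian_entropy(v)) > 0))
  expect_error(gaussian_entropy(0), "positive")
  expect_error(gaussian_entropy(-1), "positive")
})

test_that("gaussian entropy matches a Monte-Carlo differential-entropy estimate", {
  set.seed(42)
  sd0 <- 3.7
  x <- rnorm(1e6, mean = 5, sd = sd0)
  mc <- -mean(log(dnorm(x, 5, sd0)))   # MC estimate of E[-log p]
  expect_equal(gaussian_entropy(sd0^2), mc, tolerance = 0.01)
})

test_that("GPE scores are the posterior variances and ignore amplitudes", {
  kp <- kernel_params(2.5, 0.8)
  # empty selected set: every candidate scores the prior variance
  m0 <- gp_model(NULL, NULL, kp)
  cand <- rand_loci(15, seed = 801)
  s0 <- score_gpe(m0, cand)
  expect_equal(s0$score, rep(kp$signal_scale^2, 15))
  # coincident with a noise-free training locus: score ~ 0
  Xa <- rand_loci(5, seed = 802)
  ya <- draw_gp(Xa, kp, 0, seed = 803)
  m <- gp_model(Xa, ya, kp, 0)
  expect_lt(score_gpe(m, Xa[3, , drop = FALSE])$score, 1e-6)
  # agreement with gp_posterior on random instances
  s <- score_gpe(m, cand)
  expect_equal(s$score, gp_posterior(m, cand)$variance, tolerance = 1e-12)
  # geometry only: permuting the amplitudes leaves scores unchanged
  set.seed(804); m2 <- gp_model(Xa, sample(ya), kp, 0)
  expect_equal(score_gpe(m2, cand)$score, s$score, tolerance = 1e-12)
})

test_that("MI scores match dense brute-force evaluation on a 5x5 grid", {
  kp <- kernel_params(2, 1.2)
  np <- 0.1
  g <- expand.grid(x1 = seq(0, 4, 1), x2 = seq(0, 4, 1))
  U <- as_loci(g)
  sel <- c(1, 7, 13, 25)
  Xa <- U[sel, , drop = FALSE]
  ya <- draw_gp(Xa, kp, np, seed = 811)
  m <- gp_model(Xa, ya, kp, np)
  cand_idx <- setdiff(seq_len(25), sel)
  cand <- U[cand_idx, , drop = FALSE]
  got <- score_mi(m, cand, U)
  jit <- 1e-8 * kp$signal_scale^2
  for (k in seq_along(cand_idx)) {
    ell <- cand_idx[k]
    num <- dense_gp_moments(Xa, ya, U[ell, , drop = FALSE], kp, np)$variance
    bar <- setdiff(seq_len(25), c(sel, ell))
    Xbar <- U[bar, , drop = FALSE]
    den <- dense_gp_moments(Xbar, rep(0, length(bar)),
                            U[ell, , drop = FALSE], kp, np)$variance
    expect_equal(got$score[k], num / den, tolerance = 1e-8)
  }
})

test_that("MI limits: isolated candidate scores ~1, selected locus scores ~0", {
  kp <- kernel_params(2, 0.5)
  # candidate far from the selected set and from the rest of the universe
  Xa <- rbind(c(0, 0), c(0, 1))
  far <- c(40, 40)
  U <- rbind(Xa, far, c(1, 0))
  m <- gp_model(Xa, c(1, 2), kp, 0.01)
  s <- score_mi(m, rbind(far), U)
  expect_equal(s$score, 1, tolerance = 1e-6)
  # candidate coincident with a selected locus (noise-free): numerator ~ 0
  m0 <- gp_model(Xa, c(1, 2), kp, 0)
  s0 <- score_mi(m0, Xa[1, , drop = FALSE], rbind(Xa, c(3, 3), c(4, 4)))
  expect_lt(s0$score, 1e-6)
  expect_error(score_mi(m, rbind(c(99, 99)), U), "universe must contain")
})

test_that("amplitude-space scores match the dense Schur complement on estimates", {
  set.seed(821)
  est_sel <- c(100, 2500, 40, 800)
  est_uni <- runif(40, 0, 3000)
  am <- amplitude_kernel_model(est_sel, est_uni)
  kp <- am$kernel
  jit <- 1e-8 * kp$signal_scale^2
  Ktilde <- kernel_eval(est_sel, est_sel, kp, scalar = TRUE) +
    diag(jit, 4)
  cand <- c(0, 55, 790, 2500, 1500)
  got <- score_gpe_mu(am, cand)
  for (k in seq_along(cand)) {
    kv <- kernel_eval(est_sel, cand[k], kp, scalar = TRUE)
    dense <- kp$signal_scale^2 - drop(t(kv) %*% solve(Ktilde, kv))
    # relative to the prior variance scale (scores at duplicates are ~0)
    expect_lt(abs(got$score[k] - dense), 1e-8 * kp$signal_scale^2)
  }
  # a candidate estimate equal to a selected-site estimate scores ~ 0
  expect_lt(got$score[cand == 2500], 1e-6 * kp$signal_scale^2)
  # an estimate far beyond the amplitude bandwidth reverts to the prior
  far <- score_gpe_mu(am, max(est_uni) + 1e6)$score
  expect_equal(far, kp$signal_scale^2, tolerance = 1e-6)
})

test_that("WGPE scores equal latent_mean^2 * latent_variance componentwise", {
  kp <- kernel_params(3, 0.7)
  Xa <- rand_loci(6, seed = 831)
  y <- runif(6, 0, 2000)
  wm <- warped_gp(gp_model(Xa, warp(y), kp, 0.05))
  cand <- rand_loci(30, seed = 832)
  s <- score_wgpe(wm, cand)
  lp <- gp_posterior(wm$latent_model, cand)
  expect_identical(s$score, lp$mean^2 * lp$variance)
  # noise-free training locus scores ~0 (jitter floor), far null region ~0;
  # both negligible against the best candidate score
  wm0 <- warped_gp(gp_model(Xa, warp(y), kp, 0))
  top <- max(score_wgpe(wm0, cand)$score)
  expect_lt(score_wgpe(wm0, Xa[1, , drop = FALSE])$score, 1e-5 * top)
  far <- score_wgpe(wm, rbind(c(100, 100)))
  expect_lt(far$score, 1e-10)
})

test_that("greedy argmax equals exhaustive one-step search for every criterion", {
  kp <- kernel_params(2, 1)
  np <- 0.05
  for (seed in 1:3) {
    Xa <- rand_loci(5, seed = 840 + seed)
    y <- abs(draw_gp(Xa, kp, np, seed = 850 + seed)) * 300
    cand <- rand_loci(25, seed = 860 + seed)
    m <- gp_model(Xa, y, kp, np)
    # GPE: brute-force maximization of the dense conditional variance
    v <- dense_gp_moments(Xa, y, cand, kp, np)$variance
    expect_equal(pick_argmax(score_gpe(m, cand)), which.max(v))
    # WGPE: brute force on mu_z^2 sigma_z^2
    wm <- warped_gp(gp_model(Xa, warp(y), kp, np))
    dz <- dense_gp_moments(Xa, warp(y), cand, kp, np)
    expect_equal(pick_argmax(score_wgpe(wm, cand)),
                 which.max(dz$mean^2 * dz$variance))
    # GPE_mu: brute force over the amplitude-space joint
    est_sel <- gp_posterior(m, Xa)$mean
    est_cand <- gp_posterior(m, cand)$mean
    am <- amplitude_kernel_model(est_sel, est_cand)
    jit <- 1e-8 * am$kernel$signal_scale^2
    Kt <- kernel_eval(est_sel, est_sel, am$kernel, scalar = TRUE) + diag(jit, 5)
    brute <- vapply(est_cand, function(e) {
      kv <- kernel_eval(est_sel, e, am$kernel, scalar = TRUE)
      am$kernel$signal_scale^2 - drop(t(kv) %*% solve(Kt, kv))
    }, numeric(1))
    expect_equal(pick_argmax(score_gpe_mu(am, est_cand)), which.max(brute))
  }
})

test_that("entropy seeks the edges once the interior is sampled", {
  kp <- kernel_params(1, 2)
  # interior sampled; fresh symmetric candidate grid: argmax lies on a corner
  Xa <- rbind(c(3, 3))
  m <- gp_model(Xa, 0, kp, 0)
  g <- expand.grid(x1 = seq(0, 6, 1.5), x2 = seq(0, 6, 1.5))
  cand <- as_loci(g)
  best <- cand[pick_argmax(score_gpe(m, cand)), ]
  expect_true(all(best %in% c(0, 6)))
})
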