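# shared fixtures: everything is generated in code at test time

# seeded random loci on [0, side]^2
rand_loci <- function(n, seed, side = 6) {
  set.seed(seed)
  cbind(x1 = runif(n, 0, side), x2 = runif(n, 0, side))
}

# the standard single-bump test field (~11% excitable area at 50 uV)
bump_oracle <- function() synth_field(default_field_spec())

# draw a GP realization at loci X (chol of the noise-augmented Gram)
draw_gp <- function(X, params, noise_power, seed) {
  set.seed(seed)
  K <- kernel_eval(X, X, params) + diag(noise_power + 1e-10, nrow(X))
  drop(t(chol(K)) %*% rnorm(nrow(X)))
}

# dense brute-force GP conditional moments via explicit solve(); the
# independent oracle for posterior/Schur-complement checks
dense_gp_moments <- function(Xa, ya, Xq, params, noise_power) {
  jit <- 1e-8 * params$signal_scale^2
  Kaa <- kernel_eval(Xa, Xa, params) + diag(noise_power + jit, nrow(Xa))
  Kaq <- kernel_eval(Xa, Xq, params)
  if (!is.matrix(Kaq)) Kaq <- matrix(Kaq, nrow(Xa), nrow(Xq))
  Kqq <- rep(params$signal_scale^2, nrow(Xq))
  W <- solve(Kaa, Kaq)
  list(mean = unname(drop(crossprod(Kaq, solve(Kaa, ya)))),
       variance = unname(Kqq - colSums(Kaq * W)))
}
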