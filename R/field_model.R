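#' Exponentiated-quadratic kernel hyperparameters
#'
#' The spatial covariance of the MEP field is modelled with an isotropic
#' exponentiated-quadratic (squared-exponential) kernel
#' \deqn{\kappa(a, b) = s^2 \exp(-\|a-b\|^2 / (2 h^2))}
#' with signal scale \eqn{s} (uV in observation space, unitless in the warped
#' latent space) and bandwidth \eqn{h} (cm).
#'
#' @param signal_scale Strictly positive signal standard deviation.
#' @param bandwidth Strictly positive kernel bandwidth (cm, or uV for the
#'   amplitude-space kernel).
#' @return Object of class `"kernel_params"`.
#' @export
kernel_params <- function(signal_scale, bandwidth) {
  if (!is.numeric(signal_scale) || length(signal_scale) != 1L ||
      !is.finite(signal_scale) || signal_scale <= 0)
    stop("signal_scale must be a single strictly positive number")
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
      !is.finite(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be a single strictly positive number")
  structure(list(signal_scale = signal_scale, bandwidth = bandwidth),
            class = "kernel_params")
}

#' Evaluate the exponentiated-quadratic kernel
#'
#' @param a,b Loci coercible via [as_loci()] (or numeric vectors for the
#'   amplitude-space kernel, see `scalar`).
#' @param params A [kernel_params()].
#' @param scalar If `TRUE`, `a` and `b` are vectors of scalar inputs (used by
#'   the amplitude-space criterion) rather than 2-D loci.
#' @return Cross-kernel matrix `length(a)` x `length(b)` (dropped to a scalar
#'   for single pairs).
#' @examples
#' kernel_eval(c(0, 0), c(1, 0), kernel_params(1, 1))  # exp(-0.5)
#' @export
kernel_eval <- function(a, b, params, scalar = FALSE) {
  stopifnot(inherits(params, "kernel_params"))
  if (scalar) {
    d2 <- outer(as.numeric(a), as.numeric(b), "-")^2
  } else {
    d2 <- cross_dist2(as_loci(a), as_loci(b))
  }
  K <- params$signal_scale^2 * exp(-d2 / (2 * params$bandwidth^2))
  if (length(K) == 1L) as.numeric(K) else K
}

# relative jitter added to the Gram diagonal before factorization
.gp_jitter <- function(params) 1e-8 * params$signal_scale^2

#' Gaussian-process model of a spatial MEP field
#'
#' Conditions a zero-mean GP prior with exponentiated-quadratic kernel on
#' observed (locus, value) pairs under i.i.d. Gaussian observation noise.
#' The noise-augmented Gram matrix \eqn{K_{AA} + \sigma_\eta^2 I} is
#' Cholesky-factorized once at construction and cached; a relative jitter of
#' `1e-8 * signal_scale^2` is always added to the diagonal for conditioning.
#'
#' @param loci Training loci (n x 2, cm); may be empty (0 rows) for the prior.
#' @param values Training MEP values (uV), length n.
#' @param kernel A [kernel_params()].
#' @param noise_power Observation noise variance \eqn{\sigma_\eta^2 \ge 0}
#'   (uV^2).
#' @return Object of class `"gp_model"`.
#' @seealso [gp_posterior()], [neg_log_marginal_likelihood()],
#'   [fit_hyperparameters()]
#' @export
gp_model <- function(loci, values, kernel, noise_power = 0) {
  stopifnot(inherits(kernel, "kernel_params"))
  if (!is.numeric(noise_power) || length(noise_power) != 1L ||
      !is.finite(noise_power) || noise_power < 0)
    stop("noise_power must be a single non-negative number")
  if (is.null(loci) || (is.matrix(loci) && nrow(loci) == 0L) ||
      length(values) == 0L) {
    X <- matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("x1", "x2")))
    y <- numeric(0)
  } else {
    X <- as_loci(loci)
    y <- as.numeric(values)
  }
  if (nrow(X) != length(y))
    stop("number of training loci must equal number of training values")
  if (length(y) && any(!is.finite(y)))
    stop("training values contain non-finite entries")
  m <- structure(list(loci = X, values = y, kernel = kernel,
                      noise_power = noise_power,
                      L = NULL, alpha = NULL),
                 class = "gp_model")
  n <- nrow(X)
  if (n > 0L) {
    K <- kernel_eval(X, X, kernel)
    if (n == 1L) K <- matrix(K, 1L, 1L)
    Kn <- K + diag(noise_power + .gp_jitter(kernel), n)
    U <- tryCatch(chol(Kn), error = function(e)
      stop("Cholesky factorization of K_AA + sigma_eta^2*I failed (matrix ",
           "singular after jitter): ", conditionMessage(e)))
    m$L <- U                       # upper-triangular, Kn = t(U) %*% U
    m$alpha <- backsolve(U, forwardsolve(t(U), y))
  }
  m
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf(
    "GP field model: %d training loci | signal_scale %.4g, bandwidth %.4g cm, noise_power %.4g\n",
    nrow(x$loci), x$kernel$signal_scale, x$kernel$bandwidth, x$noise_power))
  invisible(x)
}

#' GP predictive distribution at query loci
#'
#' Posterior mean and variance of the latent field at each query locus:
#' \deqn{\hat\psi_{\ell|A} = \kappa_{A\ell}^\top (K_{AA}+\sigma_\eta^2 I)^{-1} y_A}
#' \deqn{s^2_{\ell|A} = \kappa_{\ell\ell} - \kappa_{A\ell}^\top (K_{AA}+\sigma_\eta^2 I)^{-1} \kappa_{A\ell}}
#' With no training data this is the prior: mean 0, variance
#' \eqn{\kappa(x,x)}.
#'
#' @param model A [gp_model()].
#' @param query Query loci coercible via [as_loci()].
#' @return Data frame with one row per query and columns `mean` (uV) and
#'   `variance` (uV^2, clipped below at 0).
#' @export
gp_posterior <- function(model, query) {
  stopifnot(inherits(model, "gp_model"))
  Xq <- as_loci(query)
  kdiag <- rep(model$kernel$signal_scale^2, nrow(Xq))
  if (nrow(model$loci) == 0L) {
    return(data.frame(mean = rep(0, nrow(Xq)), variance = kdiag))
  }
  Kx <- kernel_eval(model$loci, Xq, model$kernel)
  if (!is.matrix(Kx)) Kx <- matrix(Kx, nrow(model$loci), nrow(Xq))
  mu <- drop(crossprod(Kx, model$alpha))
  w <- forwardsolve(t(model$L), Kx)
  v <- kdiag - colSums(w^2)
  v[v < 0] <- 0
  data.frame(mean = as.numeric(mu), variance = v)
}

#' Negative log marginal likelihood of a GP model
#'
#' The Gaussian negative log evidence of the training values under the
#' noise-augmented Gram matrix \eqn{K_n = K_{AA} + \sigma_\eta^2 I}, on the
#' \eqn{-2\ln} scale:
#' \deqn{y_A^\top K_n^{-1} y_A + \ln|K_n| + N \ln 2\pi.}
#'
#' @param model A [gp_model()] with at least one training point.
#' @return Numeric scalar.
#' @export
neg_log_marginal_likelihood <- function(model) {
  stopifnot(inherits(model, "gp_model"))
  n <- nrow(model$loci)
  if (n < 1L) stop("marginal likelihood needs at least one training point")
  quad <- sum(model$values * model$alpha)
  logdet <- 2 * sum(log(diag(model$L)))
  quad + logdet + n * log(2 * pi)
}

# seeded log-uniform multi-start ranges from data-scale heuristics
.fit_start_ranges <- function(X, y) {
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy <= 0) sdy <- 1e-4
  n <- nrow(X)
  if (n >= 2L) {
    idx <- if (n > 200L) sample.int(n, 200L) else seq_len(n)
    d2 <- cross_dist2(X[idx, , drop = FALSE], X[idx, , drop = FALSE])
    med <- stats::median(sqrt(d2[upper.tri(d2)]))
    if (!is.finite(med) || med <= 0) med <- 1
  } else med <- 1
  list(signal = sdy * c(1e-2, 1e2),
       band = med * c(1e-2, 1e2),
       noise_sd = sdy * c(1e-3, 1))
}

#' Fit GP hyperparameters by maximum marginal likelihood
#'
#' Minimizes [neg_log_marginal_likelihood()] over log-parameterized
#' `(signal_scale, bandwidth, noise_sd)` with `L-BFGS-B`, restarting from a
#' seeded log-uniform design over data-scale heuristic ranges (signal scale
#' around `sd(y)`, bandwidth around the median pairwise distance). The noise
#' power is fitted jointly with the kernel parameters unless `fixed_noise` is
#' given. Deterministic for a given seed.
#'
#' @param loci Training loci (>= 3 distinct).
#' @param values Training values (uV).
#' @param restarts Number of random restarts (>= 1).
#' @param seed Integer seed for restart draws.
#' @param init Optional `list(kernel =, noise_power =)` warm start tried
#'   before the random restarts.
#' @param fixed_noise Optional fixed noise power; when given, only the two
#'   kernel parameters are optimized.
#' @return The fitted [gp_model()].
#' @export
fit_hyperparameters <- function(loci, values, restarts = 5L, seed = 1L,
                                init = NULL, fixed_noise = NULL) {
  X <- as_loci(loci)
  y <- as.numeric(values)
  if (any(!is.finite(y))) stop("training values contain non-finite entries")
  if (nrow(unique(X)) < 3L) stop("need at least 3 distinct training loci")
  rng <- .local_rng(seed)
  ranges <- rng$with(.fit_start_ranges(X, y))

  fit_noise <- is.null(fixed_noise)
  d2 <- cross_dist2(X, X)        # reused across all objective evaluations
  n <- nrow(X)
  obj <- function(par) {
    sc <- exp(par[1]); bw <- exp(par[2])
    np <- if (fit_noise) exp(par[3])^2 else fixed_noise
    Kn <- sc^2 * exp(-d2 / (2 * bw^2)) + diag(np + 1e-8 * sc^2, n)
    U <- tryCatch(chol(Kn), error = function(e) NULL)
    if (is.null(U)) return(1e10)
    alpha <- backsolve(U, forwardsolve(t(U), y))
    v <- sum(y * alpha) + 2 * sum(log(diag(U))) + n * log(2 * pi)
    if (!is.finite(v)) 1e10 else v
  }

  lower <- log(c(max(ranges$signal[1] * 1e-2, 1e-8),
                 ranges$band[1] * 1e-1,
                 max(ranges$noise_sd[1] * 1e-2, 1e-8)))
  upper <- log(c(ranges$signal[2] * 1e2, ranges$band[2] * 1e1,
                 ranges$noise_sd[2] * 1e2))
  npar <- if (fit_noise) 3L else 2L

  starts <- list()
  if (!is.null(init)) {
    s0 <- log(c(init$kernel$signal_scale, init$kernel$bandwidth,
                sqrt(max(init$noise_power, 1e-16))))
    starts[[length(starts) + 1L]] <- s0[seq_len(npar)]
  }
  # deterministic data-scale anchors tried before the random restarts
  sdy <- sqrt(ranges$signal[1] * ranges$signal[2])   # geometric mid = sd(y)
  medd <- sqrt(ranges$band[1] * ranges$band[2])      # median pairwise distance
  for (anchor in list(c(sdy, medd / 4, sdy * 1e-2),
                      c(sdy, medd, sdy * 1e-1))) {
    starts[[length(starts) + 1L]] <- log(anchor)[seq_len(npar)]
  }
  runi <- rng$with({
    lapply(seq_len(restarts), function(i) {
      c(log(exp(stats::runif(1, log(ranges$signal[1]), log(ranges$signal[2])))),
        log(exp(stats::runif(1, log(ranges$band[1]), log(ranges$band[2])))),
        log(exp(stats::runif(1, log(ranges$noise_sd[1]), log(ranges$noise_sd[2])))))[seq_len(npar)]
    })
  })
  starts <- c(starts, runi)

  best <- NULL
  best_val <- Inf
  n_ok <- 0L
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B",
                   lower = lower[seq_len(npar)], upper = upper[seq_len(npar)],
                   control = list(maxit = 200L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    if (fit$value < best_val) {
      best_val <- fit$value
      best <- fit$par
    }
  }
  if (is.null(best))
    stop("all ", length(starts), " hyperparameter restarts failed to converge")
  sc <- exp(best[1]); bw <- exp(best[2])
  np <- if (fit_noise) exp(best[3])^2 else fixed_noise
  gp_model(X, y, kernel_params(sc, bw), np)
}

# Run `expr` under a private RNG stream without disturbing the caller's RNG.
.local_rng <- function(seed) {
  state <- NULL
  force(seed)
  first <- TRUE
  list(with = function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    if (first) {
      set.seed(seed)
      first <<- FALSE
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
    res <- expr
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    res
  })
}
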