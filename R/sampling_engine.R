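#' Sampling-run state
#'
#' The trajectory object every sampling strategy returns: the acquired
#' samples in selection order (initial design tagged `iteration == 0`),
#' bookkeeping for the candidate set, and the run's seed/budget so any
#' result can be re-derived.
#'
#' @param samples Data frame with columns `x1`, `x2` (cm), `mep_uv` (uV),
#'   `iteration` (0 for the initial design) and `criterion_score`.
#' @param method Strategy label.
#' @param budget Total sample budget N.
#' @param initial_count Size of the initial design.
#' @param seed Root seed of the run (NA for deterministic strategies).
#' @param status `"ok"` or `"early-stop"`.
#' @param log Character vector of per-run notes (e.g. degenerate-density
#'   fallbacks).
#' @return Object of class `"sampling_state"`.
#' @export
sampling_state <- function(samples, method, budget, initial_count,
                           seed = NA_integer_, status = "ok",
                           log = character(0)) {
  stopifnot(is.data.frame(samples),
            all(c("x1", "x2", "mep_uv", "iteration", "criterion_score")
                %in% names(samples)))
  structure(list(samples = samples, method = method, budget = budget,
                 initial_count = initial_count, seed = seed,
                 status = status, log = log),
            class = "sampling_state")
}

#' @export
print.sampling_state <- function(x, ...) {
  cat(sprintf("%s run: %d/%d stimuli (%d initial), status %s\n",
              x$method, nrow(x$samples), x$budget, x$initial_count, x$status))
  invisible(x)
}

# initial-design data frame from (loci, values)
.initial_samples <- function(loci, values) {
  X <- as_loci(loci)
  data.frame(x1 = X[, 1], x2 = X[, 2], mep_uv = as.numeric(values),
             iteration = 0L, criterion_score = NA_real_)
}

#' Uniform initial design over a domain
#'
#' The n x n lattice (boundary included) used as the common initial design
#' A0 for the active strategies, queried against the oracle.
#'
#' @param oracle A [field_oracle()].
#' @param n_per_side Lattice side (default 6, i.e. |A0| = 36).
#' @return Data frame of initial samples (iteration 0).
#' @export
initial_design <- function(oracle, n_per_side = 6L) {
  d <- oracle$domain
  x1 <- seq(d$x1min, d$x1max, length.out = n_per_side)
  x2 <- seq(d$x2min, d$x2max, length.out = n_per_side)
  X <- cbind(x1 = rep(x1, each = n_per_side), x2 = rep(x2, n_per_side))
  .initial_samples(X, query_oracle(oracle, X))
}

# refit cadence: every iteration while n <= 100, then every 5th
.should_refit <- function(n_samples, iter) {
  n_samples <= 100L || iter %% 5L == 0L
}

#' Greedy entropy-based active sampling
#'
#' The greedy loop shared by the three entropy criteria: at each iteration
#' score every remaining candidate locus, stimulate the argmax (ties to the
#' lowest index), append the observed MEP, and refresh the field model.
#' The field estimate is the GP posterior mean for `GPE`/`GPE_mu` and the
#' warped-GP observation-space mean for `WGPE`. Hyperparameters are refit
#' every iteration up to 100 samples and every 5th iteration beyond that,
#' warm-started from the previous optimum; between refits the posterior is
#' still updated with the new sample.
#'
#' @param oracle A [field_oracle()].
#' @param initial Initial design: data frame of samples (e.g.
#'   [initial_design()]), or `NULL` to use the default 6 x 6 lattice.
#' @param candidates Candidate loci matrix, or `NULL` for a lattice at
#'   `candidate_pitch` over the oracle domain.
#' @param budget Total number of stimuli N (including the initial design).
#' @param method `"GPE"`, `"GPE_mu"` or `"WGPE"`.
#' @param seed Integer seed (restart draws in hyperparameter fits).
#' @param candidate_pitch Pitch of the default candidate lattice, cm
#'   (default 0.2 = 2 mm).
#' @param restarts Hyperparameter restarts per refresh.
#' @return A [sampling_state()].
#' @export
run_entropy_sampling <- function(oracle, initial = NULL, candidates = NULL,
                                 budget = 256L,
                                 method = c("GPE", "GPE_mu", "WGPE"),
                                 seed = 1L, candidate_pitch = 0.2,
                                 restarts = 2L) {
  method <- match.arg(method)
  stopifnot(inherits(oracle, "field_oracle"))
  if (is.null(initial)) initial <- initial_design(oracle)
  if (is.null(candidates))
    candidates <- domain_lattice(oracle$domain, candidate_pitch)$loci
  V <- as_loci(candidates)
  samples <- initial
  n0 <- nrow(samples)
  if (budget > n0 + nrow(V))
    stop("budget exceeds initial design plus candidate set")
  if (budget < n0) stop("budget smaller than the initial design")
  available <- !locus_match(V, as_loci(samples))
  status <- "ok"
  model <- NULL   # gp_model (GPE/GPE_mu) or warped_gp (WGPE)
  warm <- NULL
  iter <- 0L

  refit <- function(warm_start) {
    X <- as_loci(samples)
    y <- samples$mep_uv
    if (nrow(unique(X)) < 3L) {
      # too few loci for marginal-likelihood fitting: domain-scale defaults
      d <- oracle$domain
      bw <- ((d$x1max - d$x1min) + (d$x2max - d$x2min)) / 12
      yy <- if (method == "WGPE") warp(y) else y
      sc <- max(stats::sd(yy), max(abs(yy)), 1e-3, na.rm = TRUE)
      m <- gp_model(X, yy, kernel_params(sc, bw), 1e-6 * sc^2)
      return(if (method == "WGPE") warped_gp(m) else m)
    }
    if (method == "WGPE") {
      fit_warped(X, y, restarts = restarts, seed = seed, init = warm_start)
    } else {
      fit_hyperparameters(X, y, restarts = restarts, seed = seed,
                          init = warm_start)
    }
  }
  update_data <- function(m) {
    # keep hyperparameters, recondition on the enlarged training set
    X <- as_loci(samples)
    if (method == "WGPE") {
      lm <- m$latent_model
      warped_gp(gp_model(X, warp(samples$mep_uv), lm$kernel, lm$noise_power))
    } else {
      gp_model(X, samples$mep_uv, m$kernel, m$noise_power)
    }
  }
  model <- if (nrow(samples) < budget) refit(NULL) else NULL

  while (nrow(samples) < budget) {
    iter <- iter + 1L
    if (!any(available)) {
      status <- "early-stop"
      warning("candidate set exhausted before reaching the budget")
      break
    }
    Vav <- V[available, , drop = FALSE]
    scores <- switch(method,
      GPE = score_gpe(model, Vav),
      WGPE = score_wgpe(model, Vav),
      GPE_mu = {
        est_sel <- gp_posterior(model, as_loci(samples))$mean
        est_V <- gp_posterior(model, Vav)$mean
        amp <- amplitude_kernel_model(est_sel, est_V)
        score_gpe_mu(amp, est_V)
      })
    pick <- pick_argmax(scores)
    xstar <- Vav[pick, , drop = FALSE]
    ystar <- query_oracle(oracle, xstar)
    samples <- rbind(samples, data.frame(
      x1 = xstar[1, 1], x2 = xstar[1, 2], mep_uv = ystar,
      iteration = iter, criterion_score = scores$score[scores$candidate_index == pick]))
    available[which(available)[pick]] <- FALSE
    if (.should_refit(nrow(samples), iter)) {
      lm <- if (method == "WGPE") model$latent_model else model
      warm <- list(kernel = lm$kernel, noise_power = lm$noise_power)
      model <- refit(warm)
    } else {
      model <- update_data(model)
    }
  }
  st <- sampling_state(samples, method = method, budget = budget,
                       initial_count = n0, seed = seed, status = status)
  attr(st, "model") <- model
  st
}

#' Uniform-grid baseline (UGRID)
#'
#' The ceil(sqrt(N)) x ceil(sqrt(N)) boundary-to-boundary lattice over the
#' domain, truncated to the first N nodes in row-major order.
#'
#' @param oracle A [field_oracle()].
#' @param budget Number of stimuli N.
#' @return A [sampling_state()] (all samples at iterations 1..N).
#' @export
run_uniform_grid <- function(oracle, budget) {
  stopifnot(inherits(oracle, "field_oracle"), budget >= 1L)
  m <- ceiling(sqrt(budget))
  d <- oracle$domain
  x1 <- seq(d$x1min, d$x1max, length.out = m)
  x2 <- seq(d$x2min, d$x2max, length.out = m)
  X <- cbind(x1 = rep(x1, each = m), x2 = rep(x2, m))[seq_len(budget), , drop = FALSE]
  y <- query_oracle(oracle, X)
  samples <- data.frame(x1 = X[, 1], x2 = X[, 2], mep_uv = y,
                        iteration = seq_len(budget),
                        criterion_score = NA_real_)
  sampling_state(samples, method = "UGRID", budget = budget,
                 initial_count = 0L)
}

#' Uniform-random baseline (URAND)
#'
#' i.i.d. uniform stimulation loci over the domain rectangle.
#'
#' @param oracle A [field_oracle()].
#' @param budget Number of stimuli N.
#' @param seed Integer seed.
#' @return A [sampling_state()].
#' @export
run_uniform_random <- function(oracle, budget, seed = 1L) {
  stopifnot(inherits(oracle, "field_oracle"), budget >= 1L)
  d <- oracle$domain
  rng <- .local_rng(seed)
  X <- rng$with(cbind(x1 = stats::runif(budget, d$x1min, d$x1max),
                      x2 = stats::runif(budget, d$x2min, d$x2max)))
  y <- query_oracle(oracle, X)
  samples <- data.frame(x1 = X[, 1], x2 = X[, 2], mep_uv = y,
                        iteration = seq_len(budget),
                        criterion_score = NA_real_)
  sampling_state(samples, method = "URAND", budget = budget,
                 initial_count = 0L, seed = seed)
}

#' Normalized warped-GP mean as a sampling density
#'
#' Treats the (non-negative) mean field as an unnormalized probability
#' density over the domain: \eqn{\hat p(x) = \mu(x) / \int \mu(x') dx'}.
#' The normalizer comes from double trapezoidal quadrature on a fine lattice
#' (default 0.5 mm); the same lattice supplies the supremum used for the
#' accept-reject envelope (with a 1.1 safety factor). Density evaluations at
#' arbitrary loci use the mean field directly, not a lattice interpolant.
#'
#' @param model Mean-field source accepted by [field_mean()] (typically a
#'   `"warped_gp"`).
#' @param domain A [domain_rect()].
#' @param pitch Quadrature lattice pitch in cm (default 0.05).
#' @return Object of class `"sampled_density"`, or an error if the field is
#'   degenerate (non-positive normalizer); callers typically fall back to a
#'   uniform density in that case.
#' @export
build_sampled_density <- function(model, domain, pitch = 0.05) {
  lat <- domain_lattice(domain, pitch)
  v <- field_mean(model, lat$loci)
  v[v < 0] <- 0
  z <- matrix(v, nrow = length(lat$x1), ncol = length(lat$x2), byrow = TRUE)
  normalizer <- .trapz2(lat$x1, lat$x2, z)
  if (!is.finite(normalizer) || normalizer <= 0)
    stop("degenerate field: mean integrates to a non-positive normalizer")
  sup <- max(v) / normalizer
  structure(list(model = model, domain = domain, normalizer = normalizer,
                 envelope = 1.1 * sup, pitch = pitch),
            class = "sampled_density")
}

#' Evaluate a sampled density
#' @param density A `"sampled_density"`.
#' @param loci Query loci.
#' @return Density values (1/cm^2).
#' @export
density_eval <- function(density, loci) {
  v <- field_mean(density$model, loci)
  v[v < 0] <- 0
  v / density$normalizer
}

#' Uniform density over a domain (degenerate-field fallback)
#' @param domain A [domain_rect()].
#' @return A `"sampled_density"` that is constant `1/area`.
#' @export
uniform_density <- function(domain) {
  S <- domain_area(domain)
  structure(list(model = function(X) rep(1, nrow(X)),
                 domain = domain, normalizer = S,
                 envelope = 1.1 / S, pitch = NA_real_),
            class = "sampled_density")
}

#' Accept-reject draws from a sampled density
#'
#' Proposes uniformly over the domain rectangle and accepts with probability
#' \eqn{\hat p(x) / M}, where M is the density's envelope constant. Draws are
#' made in vectorized batches; the proposal loop is guarded at `1e6`
#' proposals, beyond which an envelope error is raised (the envelope is too
#' small or the density degenerate).
#'
#' @param density A `"sampled_density"`.
#' @param n Number of draws.
#' @return n x 2 matrix of loci. Consumes the current RNG stream; seed with
#'   `set.seed()` (or run inside a strategy, which manages its own stream).
#' @export
accept_reject_draw <- function(density, n = 1L) {
  stopifnot(inherits(density, "sampled_density"), n >= 1L)
  d <- density$domain
  M <- density$envelope
  if (!is.finite(M) || M <= 0) stop("invalid accept-reject envelope")
  out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("x1", "x2")))
  got <- 0L
  proposed <- 0L
  batch <- max(256L, min(8192L, ceiling(n * 2)))
  while (got < n) {
    if (proposed >= 1e6)
      stop("accept-reject guard exceeded 1e6 proposals: envelope too small ",
           "or degenerate density")
    X <- cbind(stats::runif(batch, d$x1min, d$x1max),
               stats::runif(batch, d$x2min, d$x2max))
    u <- stats::runif(batch)
    p <- density_eval(density, X)
    if (any(p > M * (1 + 1e-9)))
      stop("density exceeds its accept-reject envelope")
    acc <- which(u < p / M)
    proposed <- proposed + batch
    if (length(acc)) {
      take <- acc[seq_len(min(length(acc), n - got))]
      out[got + seq_along(take), ] <- X[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  out
}

#' Adaptive GP random sampling (GPRS)
#'
#' Grid-free closed loop: at each iteration draw a stimulation locus from
#' the current normalized warped-GP mean density by accept-reject, query the
#' oracle there, append the sample, and refresh the warped GP and density.
#' While the fitted mean field is degenerate (e.g. all observed MEPs are
#' null) the draw falls back to a uniform density over the domain and the
#' fallback is logged, so on a null field the strategy behaves exactly like
#' uniform random sampling.
#'
#' @param oracle A [field_oracle()].
#' @param initial Initial design data frame (nonempty), or `NULL` for the
#'   default 6 x 6 lattice.
#' @param budget Total number of stimuli N (including the initial design).
#' @param seed Integer root seed for the run (density draws and restart
#'   draws derive from it).
#' @param density_pitch Quadrature pitch for the density normalizer, cm.
#' @param restarts Hyperparameter restarts per refresh.
#' @return A [sampling_state()].
#' @export
run_gprs <- function(oracle, initial = NULL, budget = 256L, seed = 1L,
                     density_pitch = 0.05, restarts = 2L) {
  stopifnot(inherits(oracle, "field_oracle"))
  if (is.null(initial)) initial <- initial_design(oracle)
  samples <- initial
  n0 <- nrow(samples)
  if (n0 < 1L) stop("GPRS needs a nonempty initial design")
  if (budget < n0) stop("budget smaller than the initial design")
  draw_rng <- .local_rng(seed)
  fit_seed <- seed + 1000L
  log <- character(0)
  status <- "ok"
  iter <- 0L
  model <- NULL
  warm <- NULL

  refresh <- function(warm_start) {
    X <- as_loci(samples)
    if (nrow(unique(X)) < 3L) {
      d <- oracle$domain
      bw <- ((d$x1max - d$x1min) + (d$x2max - d$x2min)) / 12
      z <- warp(samples$mep_uv)
      sc <- max(stats::sd(z), max(abs(z)), 1e-3, na.rm = TRUE)
      return(warped_gp(gp_model(X, z, kernel_params(sc, bw), 1e-6 * sc^2)))
    }
    fit_warped(X, samples$mep_uv, restarts = restarts,
               seed = fit_seed, init = warm_start)
  }
  density <- NULL
  if (nrow(samples) < budget) {
    model <- refresh(NULL)
    density <- tryCatch(build_sampled_density(model, oracle$domain,
                                              pitch = density_pitch),
                        error = function(e) NULL)
  }

  while (nrow(samples) < budget) {
    iter <- iter + 1L
    if (is.null(density)) {
      log <- c(log, sprintf("iteration %d: degenerate density, uniform draw", iter))
      den <- uniform_density(oracle$domain)
    } else den <- density
    xstar <- draw_rng$with(accept_reject_draw(den, 1L))
    ystar <- query_oracle(oracle, xstar)
    samples <- rbind(samples, data.frame(
      x1 = xstar[1, 1], x2 = xstar[1, 2], mep_uv = ystar,
      iteration = iter, criterion_score = NA_real_))
    if (.should_refit(nrow(samples), iter)) {
      lm <- model$latent_model
      warm <- list(kernel = lm$kernel, noise_power = lm$noise_power)
      model <- refresh(warm)
    } else {
      lm <- model$latent_model
      model <- warped_gp(gp_model(as_loci(samples), warp(samples$mep_uv),
                                  lm$kernel, lm$noise_power))
    }
    density <- tryCatch(build_sampled_density(model, oracle$domain,
                                              pitch = density_pitch),
                        error = function(e) NULL)
  }
  st <- sampling_state(samples, method = "GPRS", budget = budget,
                       initial_count = n0, seed = seed, status = status,
                       log = log)
  attr(st, "model") <- model
  st
}
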