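#' Differential entropy of a Gaussian
#'
#' \deqn{H = \tfrac12 \log(2\pi\sigma^2) + \tfrac12} in nats; monotone
#' increasing in the variance, so maximizing posterior variance and
#' maximizing conditional entropy pick the same locus.
#'
#' @param variance Strictly positive variance(s).
#' @return Entropy in nats.
#' @export
gaussian_entropy <- function(variance) {
  variance <- as.numeric(variance)
  if (any(!is.finite(variance)) || any(variance <= 0))
    stop("variance must be strictly positive")
  0.5 * log(2 * pi * variance) + 0.5
}

# assemble the standard score data frame
.scores_df <- function(score) {
  data.frame(candidate_index = seq_along(score), score = as.numeric(score))
}

#' GP-entropy (GPE) acquisition scores
#'
#' The spatial-entropy criterion: each candidate is scored by the GP
#' posterior variance \eqn{s^2_{\ell|A}} at its locus. The score depends only
#' on the geometry of the selected loci (and the kernel), never on the
#' observed amplitudes, which is why this criterion spreads stimuli evenly
#' and drifts to the edges of the sampling region.
#'
#' @param model A [gp_model()].
#' @param candidates Candidate loci.
#' @return Data frame with columns `candidate_index`, `score`.
#' @export
score_gpe <- function(model, candidates) {
  .scores_df(gp_posterior(model, candidates)$variance)
}

#' Mutual-information (MI) acquisition scores
#'
#' Scores each candidate by the ratio of its posterior variance given the
#' selected set A to its posterior variance given the rest of the universe
#' \eqn{\bar A = V \setminus (A \cup \ell)}:
#' \deqn{\delta^{MI}_\ell = \frac{\kappa_{\ell\ell} - \kappa_{A\ell}^\top K_{AA}^{-1}\kappa_{A\ell}}
#'                              {\kappa_{\ell\ell} - \kappa_{\bar A\ell}^\top K_{\bar A\bar A}^{-1}\kappa_{\bar A\ell}}}
#' All solves use the model's noise/jitter-augmented Gram matrices. A
#' candidate whose complement set is empty scores `-Inf` (never selected);
#' a denominator below `1e-12` signals a degenerate universe and errors.
#'
#' @param model A [gp_model()] (its training loci are the selected set A).
#' @param candidates Candidate loci (subset of the universe).
#' @param universe All loci under consideration (must cover candidates and
#'   the selected set).
#' @return Data frame with columns `candidate_index`, `score`.
#' @export
score_mi <- function(model, candidates, universe) {
  stopifnot(inherits(model, "gp_model"))
  Xc <- as_loci(candidates)
  Xu <- as_loci(universe)
  if (!all(locus_match(Xc, Xu, tol = 1e-7)))
    stop("universe must contain every candidate locus")
  num <- gp_posterior(model, Xc)$variance
  free <- !locus_match(Xu, model$loci, tol = 1e-6)
  score <- numeric(nrow(Xc))
  for (i in seq_len(nrow(Xc))) {
    keep <- free & !locus_match(Xu, Xc[i, , drop = FALSE], tol = 1e-6)
    Xbar <- Xu[keep, , drop = FALSE]
    if (nrow(Xbar) == 0L) {
      score[i] <- -Inf
      next
    }
    mbar <- gp_model(Xbar, rep(0, nrow(Xbar)), model$kernel, model$noise_power)
    den <- gp_posterior(mbar, Xc[i, , drop = FALSE])$variance
    if (den < 1e-12)
      stop("MI denominator below 1e-12 at candidate ", i,
           ": degenerate universe (complement set determines the candidate)")
    score[i] <- num[i] / den
  }
  .scores_df(score)
}

#' Amplitude-space kernel model for the GPE_mu criterion
#'
#' The amplitude-based criterion places an exponentiated-quadratic kernel on
#' the current field *estimates* \eqn{\hat\psi} (scalars, uV) rather than on
#' loci. Its hyperparameters are set by the median heuristic: bandwidth =
#' median absolute pairwise difference of the candidate-set estimates, signal
#' variance = their sample variance (with small positive floors for the
#' degenerate all-equal case).
#'
#' @param est_selected Field estimates at the selected loci (uV).
#' @param est_universe Field estimates over the candidate universe (uV), used
#'   for the median-heuristic hyperparameters.
#' @return Object of class `"amp_kernel_model"` with the kernel, the selected
#'   estimates and the factorized amplitude Gram matrix.
#' @export
amplitude_kernel_model <- function(est_selected, est_universe) {
  est_selected <- as.numeric(est_selected)
  est_universe <- as.numeric(est_universe)
  if (any(!is.finite(c(est_selected, est_universe))))
    stop("amplitude estimates must be finite")
  dif <- abs(outer(est_universe, est_universe, "-"))
  bw <- stats::median(dif[upper.tri(dif)])
  if (!is.finite(bw) || bw <= 0) bw <- 1e-6
  sv <- stats::var(est_universe)
  if (!is.finite(sv) || sv <= 0) sv <- 1e-12
  kp <- kernel_params(sqrt(sv), bw)
  n <- length(est_selected)
  U <- NULL
  if (n > 0L) {
    K <- kernel_eval(est_selected, est_selected, kp, scalar = TRUE)
    if (!is.matrix(K)) K <- matrix(K, n, n)
    U <- chol(K + diag(.gp_jitter(kp), n))
  }
  structure(list(kernel = kp, est_selected = est_selected, L = U),
            class = "amp_kernel_model")
}

#' Amplitude-entropy (GPE_mu) acquisition scores
#'
#' Conditional variance in amplitude space: the kernel inputs are the
#' estimated MEP values \eqn{\hat\psi}, not loci, so the criterion seeks
#' amplitudes unlike those already sampled (pure exploitation of amplitude
#' variation, no spatial exploration).
#'
#' @param amp_model An [amplitude_kernel_model()].
#' @param est_candidates Field estimate(s) at the candidate loci (uV).
#' @return Data frame with columns `candidate_index`, `score`.
#' @export
score_gpe_mu <- function(amp_model, est_candidates) {
  stopifnot(inherits(amp_model, "amp_kernel_model"))
  est_candidates <- as.numeric(est_candidates)
  kp <- amp_model$kernel
  kdiag <- rep(kp$signal_scale^2, length(est_candidates))
  if (length(amp_model$est_selected) == 0L) return(.scores_df(kdiag))
  Kx <- kernel_eval(amp_model$est_selected, est_candidates, kp, scalar = TRUE)
  if (!is.matrix(Kx))
    Kx <- matrix(Kx, length(amp_model$est_selected), length(est_candidates))
  w <- forwardsolve(t(amp_model$L), Kx)
  v <- kdiag - colSums(w^2)
  v[v < 0] <- 0
  .scores_df(v)
}

#' Warped-GP entropy (WGPE) acquisition scores
#'
#' The observation-space predictive variance of the warped GP,
#' \eqn{\delta_\ell = \mu_{z\ell|A}^2 \sigma_{z\ell|A}^2}: large only where
#' the model expects both high amplitude and high uncertainty, which is what
#' gives this criterion its exploration-exploitation balance. In unexplored
#' null-response regions the latent mean reverts to 0 and the score vanishes
#' no matter how uncertain the model is there.
#'
#' @param model A `"warped_gp"`.
#' @param candidates Candidate loci.
#' @return Data frame with columns `candidate_index`, `score`.
#' @export
score_wgpe <- function(model, candidates) {
  .scores_df(warped_posterior(model, candidates)$variance)
}

#' Greedy argmax over acquisition scores
#'
#' Ties break to the lowest candidate index for reproducibility.
#'
#' @param scores Data frame from a `score_*` function.
#' @return The winning `candidate_index`.
#' @export
pick_argmax <- function(scores) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0L)
  if (all(!is.finite(scores$score) & scores$score == -Inf))
    stop("all candidates scored -Inf; nothing selectable")
  scores$candidate_index[which.max(scores$score)]
}
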