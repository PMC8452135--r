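#' Square-root warping between MEP space and latent space
#'
#' MEP amplitudes are non-negative, which a plain GP cannot guarantee. The
#' field is therefore modelled in a latent space reached through the
#' square-root warp \eqn{z = g(y) = \sqrt{2y}} with inverse
#' \eqn{y = g^{-1}(z) = z^2/2}. `unwarp(warp(y)) == y` for all `y >= 0`;
#' `unwarp` inverts `warp` only on the image of `warp` (`z >= 0`), since
#' `unwarp` is even in `z`.
#'
#' Negative inputs down to `-1e-9` uV are treated as floating-point dust from
#' upstream interpolation and clipped to 0; anything more negative is an
#' error, since true negative MEP amplitudes indicate corrupt data.
#'
#' @param y Non-negative MEP amplitudes (uV).
#' @param z Latent values.
#' @return `warp()` returns latent values; `unwarp()` returns non-negative
#'   amplitudes (uV).
#' @examples
#' unwarp(warp(4))  # 4
#' unwarp(4)        # 8: unwarp alone is not the identity off warp's image
#' @export
warp <- function(y) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("MEP values must be finite")
  if (any(y < -1e-9)) stop("negative MEP amplitude below tolerance: corrupt data")
  y[y < 0] <- 0
  sqrt(2 * y)
}

#' @rdname warp
#' @export
unwarp <- function(z) {
  z <- as.numeric(z)
  z^2 / 2
}

#' Warped GP model of a non-negative MEP field
#'
#' Fits a GP to the square-root-warped amplitudes `z = warp(y)`; because the
#' warp is fixed, its Jacobian contributes a hyperparameter-independent
#' constant to the evidence and fitting reduces to ordinary marginal-likelihood
#' maximization in the latent space.
#'
#' @inheritParams fit_hyperparameters
#' @param values Non-negative MEP amplitudes (uV).
#' @return Object of class `"warped_gp"` with element `latent_model`
#'   (a [gp_model()] on the warped values).
#' @export
fit_warped <- function(loci, values, restarts = 5L, seed = 1L,
                       init = NULL, fixed_noise = NULL) {
  z <- warp(values)
  latent <- fit_hyperparameters(loci, z, restarts = restarts, seed = seed,
                                init = init, fixed_noise = fixed_noise)
  structure(list(latent_model = latent, warp_id = "sqrt"),
            class = "warped_gp")
}

#' Construct a warped GP from an already-fitted latent model
#'
#' @param latent_model A [gp_model()] fitted on warped values.
#' @return Object of class `"warped_gp"`.
#' @export
warped_gp <- function(latent_model) {
  stopifnot(inherits(latent_model, "gp_model"))
  structure(list(latent_model = latent_model, warp_id = "sqrt"),
            class = "warped_gp")
}

#' @export
print.warped_gp <- function(x, ...) {
  cat("warped GP (square-root link) over latent model:\n")
  print(x$latent_model)
  invisible(x)
}

#' Warped-GP predictive distribution in observation space
#'
#' Latent moments come from the GP posterior; the observation-space moments
#' follow from linearizing the inverse warp \eqn{y = z^2/2} at the latent
#' posterior mean:
#' \deqn{\mu_{y} = \tfrac12 \mu_{z}^2, \qquad \sigma^2_{y} = \mu_{z}^2 \sigma^2_{z}.}
#' The predictive mean is therefore non-negative by construction, and both
#' observation-space moments vanish wherever the latent mean is 0 (unexplored
#' null-response territory), whatever the latent variance.
#'
#' @param model A `"warped_gp"`.
#' @param query Query loci coercible via [as_loci()].
#' @return Data frame with columns `latent_mean`, `latent_variance`,
#'   `mean` (uV) and `variance` (uV^2).
#' @export
warped_posterior <- function(model, query) {
  stopifnot(inherits(model, "warped_gp"))
  post <- gp_posterior(model$latent_model, query)
  data.frame(latent_mean = post$mean,
             latent_variance = post$variance,
             mean = post$mean^2 / 2,
             variance = post$mean^2 * post$variance)
}
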