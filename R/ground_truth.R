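#' Queryable ground-truth MEP field
#'
#' A `field_oracle` stands in for the subject's cortex during closed-loop
#' simulation: it returns a deterministic non-negative MEP amplitude (uV) for
#' any scalp locus inside its domain. Sampling strategies interact with
#' oracles only through [query_oracle()].
#'
#' @param query Function taking an n x 2 locus matrix and returning n
#'   non-negative amplitudes (uV).
#' @param domain A [domain_rect()].
#' @param provenance `"synthetic"` or `"surrogate-from-samples"`.
#' @return Object of class `"field_oracle"`.
#' @export
field_oracle <- function(query, domain, provenance = "synthetic") {
  stopifnot(is.function(query), inherits(domain, "domain_rect"))
  structure(list(query = query, domain = domain, provenance = provenance),
            class = "field_oracle")
}

#' Query a field oracle at loci
#' @param oracle A [field_oracle()].
#' @param loci Loci coercible via [as_loci()].
#' @return Numeric vector of MEP amplitudes (uV).
#' @export
query_oracle <- function(oracle, loci) {
  stopifnot(inherits(oracle, "field_oracle"))
  as.numeric(oracle$query(as_loci(loci)))
}

#' @export
print.field_oracle <- function(x, ...) {
  cat(sprintf("field oracle (%s) over ", x$provenance))
  print(x$domain)
  invisible(x)
}

#' Synthetic MEP-field specification
#'
#' A sum of (possibly rotated, anisotropic) Gaussian bumps over a constant
#' background:
#' \deqn{\psi(x) = b + \sum_i A_i \exp\{-\tfrac12 (x-c_i)^\top \Sigma_i^{-1} (x-c_i)\}}
#' emulating a focal cortical muscle representation: sharply concentrated
#' excitable subregion, null response elsewhere.
#'
#' @param bumps List of bumps, each a list with `center` (length-2, cm),
#'   `amplitude` (uV, >= 0), `spread` (length-2 axis SDs in cm, > 0) and
#'   optional `rotation` (radians).
#' @param background Constant background amplitude (uV, >= 0).
#' @param domain A [domain_rect()].
#' @return Object of class `"synthetic_field_spec"`.
#' @export
synthetic_field_spec <- function(bumps, background = 0,
                                 domain = domain_rect(0, 6, 0, 6)) {
  stopifnot(is.list(bumps), background >= 0)
  for (b in bumps) {
    stopifnot(length(b$center) == 2L, b$amplitude >= 0,
              length(b$spread) == 2L, all(b$spread > 0))
  }
  structure(list(bumps = bumps, background = background, domain = domain),
            class = "synthetic_field_spec")
}

#' Default single-bump hand-muscle field
#'
#' One dominant excitable bump (peak 3000 uV, isotropic 0.4 cm spread) on a
#' null background over a 6 x 6 cm scalp patch. With the 50 uV response
#' threshold this field's excitable region covers about 11% of the domain,
#' mimicking the sparse focal representation of an intrinsic hand muscle.
#'
#' @param center Bump center (cm).
#' @param amplitude Peak amplitude (uV).
#' @param spread Axis SDs (cm).
#' @return A `"synthetic_field_spec"`.
#' @export
default_field_spec <- function(center = c(2.6, 3.4), amplitude = 3000,
                               spread = c(0.4, 0.4)) {
  synthetic_field_spec(
    bumps = list(list(center = center, amplitude = amplitude,
                      spread = spread, rotation = 0)),
    background = 0,
    domain = domain_rect(0, 6, 0, 6))
}

#' Build a deterministic oracle from a synthetic field specification
#'
#' @param spec A [synthetic_field_spec()] (or arguments forwarded to it).
#' @return A [field_oracle()] with provenance `"synthetic"`.
#' @export
synth_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  bumps <- spec$bumps
  background <- spec$background
  fn <- function(X) {
    v <- rep(background, nrow(X))
    for (b in bumps) {
      rot <- if (is.null(b$rotation)) 0 else b$rotation
      R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2L, 2L)
      D <- sweep(X, 2L, b$center) %*% R
      q <- (D[, 1] / b$spread[1])^2 + (D[, 2] / b$spread[2])^2
      v <- v + b$amplitude * exp(-q / 2)
    }
    v
  }
  field_oracle(fn, spec$domain, provenance = "synthetic")
}

#' Analytic volume of a synthetic field over the plane
#'
#' Each bump integrates to \eqn{2\pi A s_1 s_2}; the background contributes
#' `background * area(domain)`. Used as a closed-form check against
#' [map_volume()].
#'
#' @param spec A [synthetic_field_spec()].
#' @return Volume in uV cm^2.
#' @export
synth_field_volume <- function(spec) {
  v <- spec$background * domain_area(spec$domain)
  for (b in spec$bumps)
    v <- v + 2 * pi * b$amplitude * b$spread[1] * b$spread[2]
  v
}

# thin-plate spline scattered interpolant: exact at (deduplicated) samples
.tps_fit <- function(X, y) {
  agg <- stats::aggregate(list(y = y), by = list(x1 = X[, 1], x2 = X[, 2]), FUN = mean)
  X <- cbind(agg$x1, agg$x2)
  y <- agg$y
  n <- nrow(X)
  r2 <- cross_dist2(X, X)
  Phi <- ifelse(r2 > 0, 0.5 * r2 * log(r2), 0)
  P <- cbind(1, X)
  A <- rbind(cbind(Phi + diag(1e-10 * max(abs(Phi)) + 1e-12, n), P),
             cbind(t(P), matrix(0, 3L, 3L)))
  coef <- solve(A, c(y, numeric(3L)))
  list(X = X, w = coef[seq_len(n)], a = coef[n + 1:3])
}

.tps_predict <- function(fit, Xq) {
  r2 <- cross_dist2(Xq, fit$X)
  Phi <- ifelse(r2 > 0, 0.5 * r2 * log(r2), 0)
  drop(Phi %*% fit$w) + fit$a[1] + fit$a[2] * Xq[, 1] + fit$a[3] * Xq[, 2]
}

#' Ground-truth surrogate from recorded MEP samples
#'
#' Two-step construction of an accessible ground-truth function from pooled
#' mapping data: (1) scattered-data interpolation of the samples onto a
#' regular lattice (default 3.75 mm pitch), clipping negative interpolation
#' artifacts to zero and filling loci outside the convex hull of the samples
#' with zero (null response; extrapolating MEPs is unsafe); (2) a warped-GP
#' fit to the lattice, whose predictive mean becomes the oracle. The
#' scattered interpolant is a thin-plate spline (exact at the sample loci).
#'
#' @param samples Data frame with columns `x1_cm`/`x2_cm`/`mep_uv` (or
#'   `x1`/`x2` plus `mep_uv`).
#' @param domain A [domain_rect()].
#' @param pitch Lattice pitch for step 1, cm (default 0.375 = 3.75 mm).
#' @param restarts,seed Passed to [fit_warped()].
#' @param max_outside Maximum tolerated fraction of lattice nodes outside the
#'   sample convex hull before a coverage error is raised.
#' @return A [field_oracle()] with provenance `"surrogate-from-samples"`;
#'   attribute `"model"` carries the fitted `"warped_gp"` for diagnostics.
#' @export
build_surrogate <- function(samples, domain, pitch = 0.375,
                            restarts = 3L, seed = 1L, max_outside = 0.10) {
  X <- as_loci(samples)
  y <- .sample_values(samples)
  if (nrow(X) < 10L) stop("need at least 10 samples to build a surrogate")
  if (any(y < 0)) stop("negative MEP amplitudes in surrogate samples")
  lat <- domain_lattice(domain, pitch)
  hull <- X[grDevices::chull(X), , drop = FALSE]
  # inflate the hull marginally so lattice nodes exactly on its boundary
  # (samples on the domain edge) count as covered
  ctr <- colMeans(hull)
  hull <- sweep(sweep(hull, 2L, ctr) * (1 + 1e-9), 2L, ctr, "+")
  inside <- as.logical(mgcv::in.out(rbind(hull, hull[1L, ]), lat$loci))
  frac_out <- mean(!inside)
  if (frac_out > max_outside)
    stop(sprintf(paste0("samples do not span the domain: %.0f%% of lattice ",
                        "nodes lie outside their convex hull (max %.0f%%)"),
                 100 * frac_out, 100 * max_outside))
  fit <- .tps_fit(X, y)
  z <- numeric(nrow(lat$loci))
  z[inside] <- .tps_predict(fit, lat$loci[inside, , drop = FALSE])
  z[z < 0] <- 0
  wgp <- fit_warped(lat$loci, z, restarts = restarts, seed = seed)
  fn <- function(Xq) {
    pmax(warped_posterior(wgp, Xq)$mean, 0)
  }
  out <- field_oracle(fn, domain, provenance = "surrogate-from-samples")
  attr(out, "model") <- wgp
  out
}

# amplitude column from a sample table
.sample_values <- function(samples) {
  if (is.data.frame(samples)) {
    for (nm in c("mep_uv", "mep", "y")) {
      if (nm %in% names(samples)) return(as.numeric(samples[[nm]]))
    }
  }
  stop("sample table needs an amplitude column (mep_uv)")
}

#' Wrap an oracle with trial-to-trial MEP variability
#'
#' Physiological MEP amplitudes fluctuate multiplicatively from trial to
#' trial; the `"lognormal"` model multiplies each queried value by
#' \eqn{\exp(\sigma Z)}, \eqn{Z \sim N(0,1)} (median factor 1, so the sample
#' median at a locus stays at the base value). Noise draws come from a
#' private RNG stream seeded at construction, so the wrapped oracle produces
#' an identical query sequence when rebuilt with the same seed.
#'
#' @param base A [field_oracle()].
#' @param noise_model `"none"` or `"lognormal"`.
#' @param sigma Log-scale SD (>= 0) for the lognormal model.
#' @param seed Integer seed for the private noise stream.
#' @return A [field_oracle()].
#' @export
noisy_oracle <- function(base, noise_model = c("none", "lognormal"),
                         sigma = 0.5, seed = 1L) {
  stopifnot(inherits(base, "field_oracle"))
  noise_model <- match.arg(noise_model)
  if (noise_model == "none") return(base)
  if (sigma < 0) stop("sigma must be non-negative")
  rng <- .local_rng(seed)
  fn <- function(X) {
    v <- base$query(X)
    fac <- rng$with(exp(sigma * stats::rnorm(length(v))))
    v * fac
  }
  field_oracle(fn, base$domain, provenance = base$provenance)
}
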