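#' Normalized mean squared error between two maps
#'
#' \deqn{NMSE(\psi, \hat\psi) = \|\psi - \hat\psi\|_2^2 / \|\psi\|_2^2}
#' computed over vectors of field values sampled on the same (dense) test
#' lattice. An estimate that is identically zero scores exactly 1.
#'
#' @param truth Ground-truth field values.
#' @param estimate Estimated field values (same length).
#' @return Non-negative scalar.
#' @export
nmse <- function(truth, estimate) {
  truth <- as.numeric(truth)
  estimate <- as.numeric(estimate)
  if (length(truth) != length(estimate))
    stop("truth and estimate must have equal length")
  denom <- sum(truth^2)
  if (denom == 0) stop("NMSE undefined: ground truth is identically zero")
  sum((truth - estimate)^2) / denom
}

# validate a lattice-field triple (x1 axis, x2 axis, z matrix)
.check_lattice_field <- function(x1, x2, z) {
  if (!is.matrix(z) || nrow(z) != length(x1) || ncol(z) != length(x2))
    stop("field must be a matrix with dim (length(x1), length(x2)): ",
         "non-rectangular lattice")
  if (is.unsorted(x1, strictly = TRUE) || is.unsorted(x2, strictly = TRUE))
    stop("lattice axes must be strictly increasing")
  invisible(TRUE)
}

# double trapezoidal integral of z over the x1 x x2 lattice
.trapz2 <- function(x1, x2, z) {
  inner <- apply(z, 1L, function(row) pracma::trapz(x2, row))
  pracma::trapz(x1, inner)
}

#' Map volume by double trapezoidal integration
#'
#' @param x1,x2 Strictly increasing lattice axis coordinates (cm).
#' @param z Field values, matrix `length(x1)` x `length(x2)` (uV).
#' @return Volume in uV cm^2.
#' @export
map_volume <- function(x1, x2, z) {
  .check_lattice_field(x1, x2, z)
  .trapz2(x1, x2, z)
}

#' Map area of the supra-threshold region
#'
#' Double trapezoidal integral of the indicator `z > threshold`. The default
#' 50 uV threshold is the standard MEP response criterion used for resting
#' motor threshold determination.
#'
#' @inheritParams map_volume
#' @param threshold Response threshold in uV.
#' @return Area in cm^2.
#' @export
map_area <- function(x1, x2, z, threshold = 50) {
  .check_lattice_field(x1, x2, z)
  .trapz2(x1, x2, (z > threshold) * 1)
}

#' Amplitude-weighted center of gravity of a map
#'
#' \deqn{COG_k = \sum_i z_i x_{k,i} / \sum_i z_i} over lattice nodes.
#'
#' @inheritParams map_volume
#' @return Named numeric vector `c(cog_x1, cog_x2)` in cm.
#' @export
cog <- function(x1, x2, z) {
  .check_lattice_field(x1, x2, z)
  tot <- sum(z)
  if (tot <= 0) stop("COG undefined: field has non-positive total mass")
  c(cog_x1 = sum(rowSums(z) * x1) / tot,
    cog_x2 = sum(colSums(z) * x2) / tot)
}

#' Standard map features of a field on a lattice
#'
#' @inheritParams map_area
#' @return Data frame with columns `volume`, `area`, `cog_x1`, `cog_x2`.
#' @export
map_features <- function(x1, x2, z, threshold = 50) {
  cg <- cog(x1, x2, z)
  data.frame(volume = map_volume(x1, x2, z),
             area = map_area(x1, x2, z, threshold),
             cog_x1 = unname(cg[1]), cog_x2 = unname(cg[2]))
}

#' Evaluate a field source on a regular lattice
#'
#' Convenience bridge between oracles/models and the lattice metrics: returns
#' the axis vectors and the value matrix of the source's mean field.
#'
#' @param object A [field_oracle()], `"warped_gp"`, or [gp_model()].
#' @param domain A [domain_rect()].
#' @param pitch Lattice pitch in cm (default 0.05 = 0.5 mm, the dense test
#'   lattice).
#' @return List with `x1`, `x2`, `z` suitable for [map_volume()] etc.
#' @export
field_on_lattice <- function(object, domain, pitch = 0.05) {
  lat <- domain_lattice(domain, pitch)
  v <- field_mean(object, lat$loci)
  list(x1 = lat$x1, x2 = lat$x2,
       z = matrix(v, nrow = length(lat$x1), ncol = length(lat$x2),
                  byrow = TRUE))
}

#' Mean field value of a model or oracle at loci
#' @param object A [field_oracle()], `"warped_gp"`, [gp_model()], or plain
#'   function of an n x 2 locus matrix.
#' @param loci Query loci.
#' @return Numeric vector of field values.
#' @export
field_mean <- function(object, loci) UseMethod("field_mean")

#' @export
field_mean.field_oracle <- function(object, loci) query_oracle(object, loci)

#' @export
field_mean.warped_gp <- function(object, loci)
  warped_posterior(object, loci)$mean

#' @export
field_mean.gp_model <- function(object, loci) gp_posterior(object, loci)$mean

#' @export
field_mean.function <- function(object, loci) as.numeric(object(as_loci(loci)))

#' Fraction of stimuli landing in the excitable region
#'
#' The fraction of a run's stimulation loci whose *oracle* value exceeds the
#' response threshold — the standard measure of how well a strategy
#' concentrates stimuli in the region of interest. By default the initial
#' design (iteration 0) is excluded so the figure reflects only the loci the
#' strategy itself chose; set `skip_initial = FALSE` to count every stimulus.
#'
#' @param state A `"sampling_state"` from one of the `run_*` strategies.
#' @param oracle The [field_oracle()] to evaluate loci against.
#' @param threshold Response threshold in uV (default 50).
#' @param skip_initial Exclude the initial design from the count.
#' @return Fraction in `[0, 1]`.
#' @export
roi_fraction <- function(state, oracle, threshold = 50, skip_initial = TRUE) {
  stopifnot(inherits(state, "sampling_state"))
  s <- state$samples
  if (skip_initial) s <- s[s$iteration > 0L, , drop = FALSE]
  if (nrow(s) == 0L) stop("no stimuli left after excluding the initial design")
  truth <- query_oracle(oracle, s)
  mean(truth > threshold)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) over the absolute mean;
#' scale-invariant under positive scaling.
#'
#' @param values Numeric vector with nonzero mean.
#' @return Non-negative scalar.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  stats::sd(values) / abs(m)
}
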