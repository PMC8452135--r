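#' Axis-aligned scalp-plane rectangle
#'
#' Defines the rectangular region of the projected scalp plane (in cm) over
#' which mapping takes place. Coordinates follow the motor-mapping convention:
#' `x1` rostral-caudal, `x2` medial-lateral.
#'
#' @param x1min,x1max Rostral-caudal extent in cm.
#' @param x2min,x2max Medial-lateral extent in cm.
#' @return An object of class `"domain_rect"`.
#' @examples
#' domain_rect(0, 6, 0, 6)
#' @export
domain_rect <- function(x1min, x1max, x2min, x2max) {
  stopifnot(is.numeric(x1min), is.numeric(x1max), is.numeric(x2min),
            is.numeric(x2max), x1max > x1min, x2max > x2min)
  structure(list(x1min = x1min, x1max = x1max,
                 x2min = x2min, x2max = x2max),
            class = "domain_rect")
}

#' @export
print.domain_rect <- function(x, ...) {
  cat(sprintf("scalp domain: x1 [%g, %g] cm, x2 [%g, %g] cm (%g cm^2)\n",
              x$x1min, x$x1max, x$x2min, x$x2max, domain_area(x)))
  invisible(x)
}

#' Area of a domain rectangle in cm^2
#' @param domain A [domain_rect()].
#' @return Numeric scalar, cm^2.
#' @export
domain_area <- function(domain) {
  (domain$x1max - domain$x1min) * (domain$x2max - domain$x2min)
}

#' Test whether loci fall inside a domain rectangle
#' @param loci Loci coercible via [as_loci()].
#' @param domain A [domain_rect()].
#' @param tol Boundary tolerance in cm.
#' @return Logical vector, one entry per locus.
#' @export
in_domain <- function(loci, domain, tol = 1e-9) {
  X <- as_loci(loci)
  X[, 1] >= domain$x1min - tol & X[, 1] <= domain$x1max + tol &
    X[, 2] >= domain$x2min - tol & X[, 2] <= domain$x2max + tol
}

#' Coerce loci to an n x 2 coordinate matrix
#'
#' Accepts a numeric length-2 vector (a single locus), an n x 2 matrix, or a
#' data frame with columns `x1`/`x2` (or `x1_cm`/`x2_cm`).
#'
#' @param x Loci in any accepted form.
#' @return Numeric matrix with columns `x1`, `x2` (cm).
#' @export
as_loci <- function(x) {
  if (is.data.frame(x)) {
    nm <- names(x)
    if (all(c("x1", "x2") %in% nm)) {
      X <- cbind(x$x1, x$x2)
    } else if (all(c("x1_cm", "x2_cm") %in% nm)) {
      X <- cbind(x$x1_cm, x$x2_cm)
    } else {
      stop("data frame loci need columns x1/x2 or x1_cm/x2_cm")
    }
  } else if (is.matrix(x)) {
    if (ncol(x) != 2L) stop("locus matrix must have 2 columns")
    X <- x
  } else if (is.numeric(x) && length(x) == 2L) {
    X <- matrix(x, nrow = 1L)
  } else {
    stop("cannot interpret loci; give a length-2 vector, n x 2 matrix or data frame")
  }
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) stop("loci contain non-finite coordinates")
  colnames(X) <- c("x1", "x2")
  X
}

#' Regular lattice over a domain rectangle
#'
#' Lattice nodes include the domain boundary; the node spacing along each axis
#' is the largest spacing not exceeding `pitch` that divides the side exactly.
#'
#' @param domain A [domain_rect()].
#' @param pitch Target node spacing in cm.
#' @return List with `x1`, `x2` (axis node vectors) and `loci`
#'   (matrix of all nodes, `x2` varying fastest).
#' @export
domain_lattice <- function(domain, pitch) {
  stopifnot(pitch > 0)
  n1 <- max(2L, ceiling((domain$x1max - domain$x1min) / pitch) + 1L)
  n2 <- max(2L, ceiling((domain$x2max - domain$x2min) / pitch) + 1L)
  x1 <- seq(domain$x1min, domain$x1max, length.out = n1)
  x2 <- seq(domain$x2min, domain$x2max, length.out = n2)
  loci <- cbind(x1 = rep(x1, each = length(x2)), x2 = rep(x2, times = length(x1)))
  list(x1 = x1, x2 = x2, loci = loci)
}

# squared Euclidean cross-distances between two locus sets
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# rows of `loci` that coincide (within tol) with any row of `ref`
locus_match <- function(loci, ref, tol = 1e-6) {
  if (is.null(ref) || nrow(ref) == 0L) return(rep(FALSE, nrow(loci)))
  d2 <- cross_dist2(as_loci(loci), as_loci(ref))
  apply(d2, 1L, min) <= tol^2
}
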