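# Periodic-geometry primitives. Internal units: nm, ns, amu, kcal/mol, K.

#' Gas constant in kcal/(mol K)
#'
#' The value used throughout for Boltzmann inversion and density-based
#' potentials of mean force, so that all printed energies are in kcal/mol.
#' @export
R_KCAL <- 1.987204e-3

#' Minimum-image displacement under orthorhombic periodic boundaries
#'
#' Returns the displacement from `a` to `b` mapped into the primary image,
#' i.e. each component lies in `[-L/2, L/2)` for the corresponding box edge
#' `L`.  Its Euclidean norm is the minimum-image distance.
#'
#' @param a,b numeric length-3 points (nm), or matrices with one point per
#'   row (both the same dimension, or one of them a single point).
#' @param box orthorhombic box edge lengths, numeric length 3 (nm).
#' @return displacement vector (or matrix of row displacements), nm.
#' @examples
#' minimum_image_displacement(c(0.5, 0, 0), c(19.5, 0, 0), c(20, 20, 11))
#' @export
minimum_image_displacement <- function(a, b, box) {
  stopifnot(all(box > 0))
  if (is.matrix(a) || is.matrix(b)) {
    if (!is.matrix(a)) a <- matrix(a, nrow = nrow(b), ncol = 3, byrow = TRUE)
    if (!is.matrix(b)) b <- matrix(b, nrow = nrow(a), ncol = 3, byrow = TRUE)
    d <- b - a
    for (k in 1:3) d[, k] <- d[, k] - box[k] * floor(d[, k] / box[k] + 0.5)
    return(d)
  }
  d <- b - a
  d - box * floor(d / box + 0.5)
}

#' Minimum-image distance between points
#'
#' @inheritParams minimum_image_displacement
#' @return distance in nm (vector if inputs are matrices).
#' @export
minimum_image_distance <- function(a, b, box) {
  d <- minimum_image_displacement(a, b, box)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

# All-pairs minimum-image distance matrix for points given as rows of x.
min_image_dist_matrix <- function(x, box) {
  n <- nrow(x)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(x[, k], x[, k], `-`)
    dk <- dk - box[k] * floor(dk / box[k] + 0.5)
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

# Wrap coordinates (vector or one column) into [0, L).
wrap_coord <- function(z, L) z - L * floor(z / L)

#' Unwrap a bonded chain across periodic boundaries
#'
#' Rebuilds a molecule stored with wrapped coordinates by minimum-image
#' chaining along the bonded sequence: each particle is placed at the
#' minimum-image position relative to its predecessor, so the molecule is
#' whole afterwards (possibly outside the primary box).
#'
#' @param coords matrix of particle coordinates in bonded order (rows, nm).
#' @param box box edge lengths (nm).
#' @return unwrapped coordinate matrix, same dimensions.
#' @export
unwrap_chain <- function(coords, box) {
  n <- nrow(coords)
  if (n <= 1L) return(coords)
  out <- coords
  for (i in 2:n) {
    step <- minimum_image_displacement(out[i - 1L, ], coords[i, ], box)
    out[i, ] <- out[i - 1L, ] + step
  }
  out
}
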