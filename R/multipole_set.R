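# Containers for the classical environment: a multipolar distribution of
# static charges, dipoles and traceless quadrupoles on (possibly) polarizable
# sites, and bare point-charge distributions standing in for QM densities.

#' Create a multipolar site set
#'
#' A `multipole_set` describes the classical environment: static charges,
#' dipoles and traceless quadrupoles placed on sites, each carrying an
#' isotropic polarizability. Two exclusion-pair lists control which static
#' pair contributions are removed (or scaled) when assembling the two
#' induction fields used by the dual induced-dipole formulation
#' (the "p" and "d" field sets of AMOEBA-style force fields).
#'
#' @param positions numeric n x 3 matrix of site positions (Bohr).
#' @param charges numeric vector of static charges (a.u.), default zeros.
#' @param dipoles numeric n x 3 matrix of static dipoles (a.u.), default zeros.
#' @param quadrupoles numeric n x 3 x 3 array of traceless static quadrupoles
#'   (a.u., Buckingham convention), default zeros.
#' @param alphas numeric vector of isotropic polarizabilities (Bohr^3, >= 0).
#' @param exclude_p,exclude_d integer m x 2 matrices (or NULL) of site-index
#'   pairs whose static contribution is scaled in the p-field / d-field;
#'   stored symmetrically.
#' @param scale_p,scale_d numeric scale factors applied to the excluded pairs
#'   (0 = fully removed), recycled to the number of pairs.
#' @param damping Thole-style exponential damping parameter for the
#'   dipole-dipole interaction, or `NULL` (default) for undamped tensors.
#' @return an object of class `multipole_set`.
#' @export
multipole_set <- function(positions, charges = NULL, dipoles = NULL,
                          quadrupoles = NULL, alphas = NULL,
                          exclude_p = NULL, exclude_d = NULL,
                          scale_p = 0, scale_d = 0, damping = NULL) {
  positions <- as_position_matrix(positions)
  n <- nrow(positions)
  if (is.null(charges)) charges <- numeric(n)
  if (is.null(alphas)) alphas <- numeric(n)
  stopifnot(length(charges) == n, length(alphas) == n)
  if (any(alphas < 0)) stop("polarizabilities must be >= 0")
  if (is.null(dipoles)) dipoles <- matrix(0, n, 3)
  dipoles <- matrix(as.numeric(dipoles), n, 3)
  if (is.null(quadrupoles)) quadrupoles <- array(0, c(n, 3, 3))
  stopifnot(identical(dim(quadrupoles), c(n, 3L, 3L)) ||
            identical(dim(quadrupoles), as.integer(c(n, 3, 3))))
  for (i in seq_len(n)) {
    q <- quadrupoles[i, , ]
    if (max(abs(q - t(q))) > 1e-12) stop("quadrupole ", i, " not symmetric")
    if (abs(sum(diag(q))) > 1e-12) stop("quadrupole ", i, " not traceless")
  }
  ex_p <- normalize_exclusions(exclude_p, scale_p, n)
  ex_d <- normalize_exclusions(exclude_d, scale_d, n)
  structure(list(positions = positions, charges = as.numeric(charges),
                 dipoles = dipoles, quadrupoles = quadrupoles,
                 alphas = as.numeric(alphas),
                 exclude_p = ex_p, exclude_d = ex_d,
                 damping = damping),
            class = "multipole_set")
}

as_position_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("positions must be an n x 3 matrix")
  storage.mode(x) <- "double"
  x
}

# store exclusion pairs symmetrically (i<j once, applied both ways)
normalize_exclusions <- function(pairs, scale, n) {
  if (is.null(pairs) || NROW(pairs) == 0)
    return(list(pairs = matrix(integer(0), 0, 2), scale = numeric(0)))
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (any(pairs < 1) || any(pairs > n)) stop("exclusion pair index out of range")
  if (any(pairs[, 1] == pairs[, 2])) stop("self-pairs are excluded implicitly")
  scale <- rep_len(as.numeric(scale), nrow(pairs))
  key <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  dup <- duplicated(key)
  list(pairs = key[!dup, , drop = FALSE], scale = scale[!dup])
}

#' @export
print.multipole_set <- function(x, ...) {
  n <- nrow(x$positions)
  cat("multipole_set:", n, "sites,", sum(x$alphas > 0), "polarizable\n")
  cat("  total static charge:", format(sum(x$charges)), "a.u.\n")
  invisible(x)
}

#' Number of sites in a multipole set
#' @param m a `multipole_set`.
#' @return integer site count.
#' @export
n_sites <- function(m) nrow(m$positions)

#' Create a point-charge source distribution
#'
#' `source_charges` stands in for a QM charge density: a set of point charges
#' tagged by what density they represent. Transition densities integrate to
#' zero; state and difference densities may carry net charge.
#'
#' @param positions numeric n x 3 matrix (Bohr).
#' @param values numeric charges (a.u.).
#' @param kind one of `"state"`, `"transition"`, `"difference"`.
#' @return an object of class `source_charges`.
#' @export
source_charges <- function(positions, values,
                           kind = c("state", "transition", "difference")) {
  kind <- match.arg(kind)
  positions <- as_position_matrix(positions)
  stopifnot(length(values) == nrow(positions))
  structure(list(positions = positions, values = as.numeric(values),
                 kind = kind),
            class = "source_charges")
}

#' @export
print.source_charges <- function(x, ...) {
  cat("source_charges [", x$kind, "]: ", length(x$values), " charges, sum ",
      format(sum(x$values)), "\n", sep = "")
  invisible(x)
}
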