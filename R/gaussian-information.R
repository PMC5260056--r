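# Determinants below this floor are treated as numerically degenerate and
# replaced by the floor so that genome-scale runs never abort on a singular
# covariance (collinear genes, duplicated probes).
DET_FLOOR <- 1e-12

#' Unbiased sample covariance of a variables-by-observations matrix
#'
#' Rows are variables (genes), columns observations (experimental
#' conditions). The denominator is `observations - 1`.
#'
#' @param data Numeric matrix, variables in rows, observations in columns.
#' @return Symmetric covariance matrix with one row/column per variable.
#' @examples
#' sample_covariance(matrix(c(1, 2, 3), nrow = 1))  # variance 1
#' @export
sample_covariance <- function(data) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  if (!is.numeric(data)) stop("expression data must be numeric", call. = FALSE)
  if (ncol(data) < 2L) {
    stop("at least 2 observations are required to estimate a covariance",
         call. = FALSE)
  }
  if (nrow(data) < 1L) stop("at least 1 variable is required", call. = FALSE)
  if (!all(is.finite(data))) {
    stop("expression data contains non-finite values", call. = FALSE)
  }
  cv <- stats::cov(t(data))
  # cov() is symmetric up to rounding; enforce it exactly so determinant
  # identities hold bit-for-bit regardless of evaluation order
  (cv + t(cv)) / 2
}

#' Differential entropy of a multivariate Gaussian, in nats
#'
#' Computes `0.5 * log((2*pi*e)^d * det(C))` where `d` is the dimension of
#' the covariance matrix `C`. A zero-dimensional variable set has entropy 0
#' (its determinant is taken to be 1), which makes the order-0 conditional
#' mutual information reduce exactly to plain mutual information.
#'
#' @param cov Symmetric covariance matrix (or a single variance).
#' @return Entropy in nats.
#' @export
gaussian_entropy <- function(cov) {
  if (length(cov) == 0L) return(0)
  if (!is.matrix(cov)) cov <- matrix(cov, 1L, 1L)
  d <- nrow(cov)
  dt <- det(cov)
  if (dt <= DET_FLOOR) {
    stop("covariance matrix is numerically degenerate (determinant <= ",
         format(DET_FLOOR), ")", call. = FALSE)
  }
  0.5 * (d * log(2 * pi * exp(1)) + log(dt))
}

# Floored determinant of a covariance submatrix; empty set -> 1 so the
# unconditioned case falls out of the same ratio. Indices are sorted so the
# determinant is bit-identical however the caller orders the variable set,
# which makes CMI(x, y | z) exactly symmetric in x and y.
.subdet <- function(cov, idx) {
  if (length(idx) == 0L) return(list(det = 1, degenerate = FALSE))
  idx <- sort(idx)
  dt <- det(cov[idx, idx, drop = FALSE])
  if (dt < DET_FLOOR) list(det = DET_FLOOR, degenerate = TRUE)
  else list(det = dt, degenerate = FALSE)
}

# Core determinant-ratio CMI on a precomputed covariance matrix.
# Returns the value in nats with attribute "degenerate" when any
# determinant had to be floored.
gauss_cmi_cov <- function(cov, x, y, z = integer(0)) {
  x <- as.integer(x); y <- as.integer(y); z <- as.integer(z)
  if (length(x) != 1L || length(y) != 1L) {
    stop("x and y must each be a single variable index", call. = FALSE)
  }
  if (x == y) stop("x and y must differ", call. = FALSE)
  if (x %in% z || y %in% z) {
    stop("conditioning set must not contain x or y", call. = FALSE)
  }
  if (anyDuplicated(z)) stop("conditioning indices must be unique", call. = FALSE)
  if (cov[x, x] <= 0 || cov[y, y] <= 0) {
    warning("zero-variance gene in MI/CMI query; returning 0", call. = FALSE)
    return(structure(0, degenerate = TRUE))
  }
  xz <- .subdet(cov, c(x, z))
  yz <- .subdet(cov, c(y, z))
  zz <- .subdet(cov, z)
  xyz <- .subdet(cov, c(x, y, z))
  val <- 0.5 * (log(xz$det) + log(yz$det) - log(zz$det) - log(xyz$det))
  if (val < 0) val <- 0  # tiny negatives from rounding are clamped
  degen <- xz$degenerate || yz$degenerate || zz$degenerate || xyz$degenerate
  if (degen) structure(val, degenerate = TRUE) else val
}

#' Mutual information of two Gaussian variables from a covariance matrix
#'
#' Returns `0.5 * log(|C(X)| * |C(Y)| / |C(X,Y)|)` in nats, which for a
#' bivariate Gaussian equals `-0.5 * log(1 - rho^2)`. Zero-variance
#' variables yield 0 with a warning; near-singular determinants are floored
#' at `1e-12` rather than aborting.
#'
#' @param cov Covariance matrix covering at least variables `x` and `y`.
#' @param x,y Integer indices of the two variables (must differ).
#' @return Mutual information in nats (non-negative).
#' @examples
#' cv <- matrix(c(1, 0.5, 0.5, 1), 2)
#' mutual_information(cv, 1, 2)  # -0.5 * log(1 - 0.25)
#' @export
mutual_information <- function(cov, x, y) {
  gauss_cmi_cov(cov, x, y, integer(0))
}

#' Conditional mutual information of two genes given a conditioning set
#'
#' Estimates CMI under the Gaussian assumption from an expression matrix via
#' the covariance determinant ratio
#' `0.5 * log(|C(X,Z)| * |C(Y,Z)| / (|C(Z)| * |C(X,Y,Z)|))`.
#' With an empty conditioning set this equals [mutual_information()].
#'
#' @param expr Numeric matrix, genes in rows, conditions in columns.
#' @param x,y Row indices of the two genes.
#' @param z Integer vector of conditioning row indices (may be empty).
#' @return CMI in nats (non-negative); carries attribute `degenerate = TRUE`
#'   when a determinant had to be floored.
#' @export
conditional_mutual_information <- function(expr, x, y, z = integer(0)) {
  x <- as.integer(x); y <- as.integer(y); z <- as.integer(z)
  vars <- c(x, y, z)
  if (any(vars < 1L) || any(vars > nrow(expr))) {
    stop("variable index out of range for the expression matrix", call. = FALSE)
  }
  if (x == y) stop("x and y must differ", call. = FALSE)
  if (x %in% z || y %in% z) {
    stop("conditioning set must not contain x or y", call. = FALSE)
  }
  if (anyDuplicated(z)) stop("conditioning indices must be unique", call. = FALSE)
  # canonical (sorted) variable order keeps the covariance, and hence every
  # determinant, identical under x/y exchange
  svars <- sort(vars)
  cv <- sample_covariance(expr[svars, , drop = FALSE])
  gauss_cmi_cov(cv, match(x, svars), match(y, svars), match(z, svars))
}
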