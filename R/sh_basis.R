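#' Number of even-degree real spherical-harmonic coefficients
#'
#' Diffusion MRI signals are antipodally symmetric, so only even degrees
#' carry signal. For a maximum degree `lmax` the even-degree real basis has
#' `(lmax + 1) * (lmax + 2) / 2` functions (15 for `lmax = 4`).
#'
#' @param lmax Even, non-negative maximum SH degree.
#' @return Integer number of basis functions.
#' @export
sh_n_coeffs <- function(lmax) {
  stopifnot(length(lmax) == 1, lmax >= 0, lmax %% 2 == 0)
  as.integer((lmax + 1L) * (lmax + 2L) / 2L)
}

#' Degree and order of each coefficient channel
#'
#' Channels are ordered by degree l = 0, 2, ..., lmax and, within a degree,
#' by order m = -l, ..., l (the descriptive-set ordering used by MRtrix-style
#' tools).
#'
#' @param lmax Even maximum degree.
#' @return data.frame with columns `l` and `m`, one row per channel.
#' @export
sh_index_table <- function(lmax) {
  ls <- seq(0L, lmax, by = 2L)
  do.call(rbind, lapply(ls, function(l) data.frame(l = l, m = seq(-l, l))))
}

# Associated Legendre values P_l^m(x) for m = 0..l (Condon-Shortley phase
# as returned by pracma::legendre).
.assoc_legendre <- function(l, x) {
  if (l == 0L) return(matrix(1, nrow = 1L, ncol = length(x)))
  p <- pracma::legendre(l, x)
  if (is.null(dim(p))) p <- matrix(p, ncol = length(x))
  p
}

#' Real even-degree spherical-harmonic design matrix
#'
#' Evaluates the orthonormal real SH basis (even degrees only) at unit
#' directions. Convention: for order m > 0 the function is
#' `sqrt(2) * N_l^m * P_l^m(cos(theta)) * cos(m*phi)`, for m < 0 the
#' corresponding sine term, and for m = 0 the zonal harmonic, with
#' `N_l^m = sqrt((2l+1)/(4*pi) * (l-m)!/(l+m)!)`. The degree-0 function is
#' the constant `1 / (2*sqrt(pi))`.
#'
#' @param directions Numeric matrix (n x 3) of unit vectors (rows).
#' @param lmax Even maximum degree.
#' @return Numeric matrix (n x M) with M = [sh_n_coeffs()].
#' @export
sh_basis <- function(directions, lmax) {
  directions <- .as_direction_matrix(directions)
  m_tot <- sh_n_coeffs(lmax)
  n <- nrow(directions)
  z <- pmin(pmax(directions[, 3], -1), 1)
  phi <- atan2(directions[, 2], directions[, 1])
  B <- matrix(0, n, m_tot)
  col <- 1L
  for (l in seq(0L, lmax, by = 2L)) {
    P <- .assoc_legendre(l, z)
    for (m in seq(-l, l)) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      if (m < 0) {
        B[, col] <- sqrt(2) * nrm * P[am + 1L, ] * sin(am * phi)
      } else if (m == 0) {
        B[, col] <- nrm * P[1L, ]
      } else {
        B[, col] <- sqrt(2) * nrm * P[am + 1L, ] * cos(am * phi)
      }
      col <- col + 1L
    }
  }
  B
}

#' Evaluate an SH-represented function at directions
#'
#' @param coeffs Numeric vector of length M, or matrix (M x k) of k
#'   coefficient vectors.
#' @param directions Unit direction matrix (n x 3).
#' @param lmax Even maximum degree; inferred from `coeffs` when missing.
#' @return Numeric vector (n) or matrix (n x k) of function values.
#' @export
sh_synthesize <- function(coeffs, directions, lmax = NULL) {
  if (is.null(dim(coeffs))) coeffs <- matrix(coeffs, ncol = 1L)
  if (is.null(lmax)) lmax <- .lmax_from_m(nrow(coeffs))
  out <- sh_basis(directions, lmax) %*% coeffs
  if (ncol(out) == 1L) drop(out) else out
}

.lmax_from_m <- function(m) {
  for (l in seq(0L, 40L, by = 2L)) if (sh_n_coeffs(l) == m) return(l)
  stop("not a valid even-degree SH coefficient count: ", m)
}

.as_direction_matrix <- function(directions) {
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3L)
  storage.mode(directions) <- "double"
  directions
}

#' Quasi-uniform unit directions (Fibonacci lattice)
#'
#' Deterministic, well-spread point set on the sphere or half-sphere; used
#' for gradient schemes of simulated acquisitions and as the collocation set
#' when constructing SH rotation operators.
#'
#' @param n Number of directions.
#' @param hemisphere If TRUE, points are folded to the z >= 0 half-sphere
#'   (adequate for antipodally symmetric signals).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n, hemisphere = FALSE) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  ga <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- ga * (seq_len(n) - 1)
  d <- cbind(r * cos(th), r * sin(th), z)
  if (hemisphere) {
    flip <- d[, 3] < 0
    d[flip, ] <- -d[flip, ]
  }
  d
}
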