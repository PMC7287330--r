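#' Ishigami test function
#'
#' \code{sin(x1) + a sin^2(x2) + b x3^4 sin(x1)} on [-pi, pi]^3; the
#' standard benchmark for variance-based sensitivity estimators because its
#' Sobol indices are available in closed form
#' (\code{\link{ishigamiIndices}}).
#'
#' @param x 3-column matrix (or 3-vector) of points in [-pi, pi]^3.
#' @param a,b constants; the usual benchmark uses a = 7, b = 0.1.
#' @return numeric vector of function values.
#' @examples
#' ishigami(c(pi / 2, 0, 0))
#' @export
ishigami <- function(x, a = 7, b = 0.1) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sin(x[, 1]) + a * sin(x[, 2])^2 + b * x[, 3]^4 * sin(x[, 1])
}

#' Closed-form Sobol indices of the Ishigami function
#'
#' Analytic variance decomposition: with
#' \code{V = a^2/8 + b pi^4/5 + b^2 pi^8/18 + 1/2},
#' \code{S1 = (1/2)(1 + b pi^4/5)^2 / V}, \code{S2 = (a^2/8)/V},
#' \code{S3 = 0} and the only interaction is the (1,3) pair.
#'
#' @param a,b Ishigami constants.
#' @return list with \code{S1} (length 3), \code{ST} (length 3), \code{S2}
#'   (3 x 3 upper-triangular matrix) and the total variance \code{V}.
#' @examples
#' ishigamiIndices()$S1
#' @export
ishigamiIndices <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  S2 <- matrix(0, 3, 3)
  S2[1, 3] <- V13 / V
  list(S1 = c(V1, V2, 0) / V,
       ST = c((V1 + V13) / V, V2 / V, V13 / V),
       S2 = S2, V = V)
}

#' Sobol g-function
#'
#' \code{prod_j (|4 x_j - 2| + a_j) / (1 + a_j)} on the unit cube; large
#' \code{a_j} make dimension j inert. First-order indices are available in
#' closed form (\code{\link{sobolGIndices}}).
#'
#' @param x D-column matrix (or D-vector) of points in [0, 1]^D.
#' @param a non-negative constants, one per dimension.
#' @return numeric vector of function values.
#' @examples
#' sobolG(rep(0.5, 4), a = c(0, 1, 4.5, 9))
#' @export
sobolG <- function(x, a) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(a))
    ewStop("ew_dimension_error", "length(a) must match the point dimension")
  g <- sweep(abs(4 * x - 2), 2, a, "+")
  g <- sweep(g, 2, 1 + a, "/")
  apply(g, 1, prod)
}

#' Closed-form Sobol indices of the g-function
#'
#' With \code{v_j = 1 / (3 (1 + a_j)^2)}: total variance
#' \code{V = prod(1 + v_j) - 1}, first-order \code{S1_j = v_j / V} and
#' total \code{ST_j = v_j prod_{k != j} (1 + v_k) / V}.
#'
#' @param a non-negative constants.
#' @return list with \code{S1}, \code{ST} and total variance \code{V}.
#' @examples
#' sobolGIndices(c(0, 1, 4.5, 9))$S1
#' @export
sobolGIndices <- function(a) {
  v <- 1 / (3 * (1 + a)^2)
  V <- prod(1 + v) - 1
  ST <- vapply(seq_along(a), function(j) v[j] * prod(1 + v[-j]), 0) / V
  list(S1 = v / V, ST = ST, V = V)
}
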