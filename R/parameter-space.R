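#' Construct a ParameterSpace
#'
#' @param names ordered character vector of parameter names.
#' @param lower,upper numeric vectors of per-dimension bounds (physical
#'   units), `lower < upper` elementwise.
#' @return a \linkS4class{ParameterSpace}.
#' @examples
#' parameterSpace(c("a", "b"), c(0, -1), c(1, 1))
#' @export
parameterSpace <- function(names, lower, upper) {
  new("ParameterSpace", names = as.character(names),
      lower = as.numeric(lower), upper = as.numeric(upper))
}

#' Default input box of the rat LV mechanics simulator
#'
#' The eight mechanics parameters in their conventional order: end-diastolic
#' pressure p (kPa), aortic pressure ap (kPa), aortic characteristic
#' impedance z (mmHg s ml^-1), tissue stiffness c1 (kPa), calcium
#' sensitivity ca50 (uM), cross-bridge binding rate kxb (ms^-1), Ca-TnC
#' unbinding rate koff (ms^-1) and maximal cellular force Tref (kPa).
#' Ranges are physiologically plausible rat values chosen for the shipped
#' 0D simulator; they are configuration, not measurements.
#'
#' @return a \linkS4class{ParameterSpace} with the 8 canonical dimensions.
#' @examples
#' defaultParameterSpace()
#' @export
defaultParameterSpace <- function() {
  parameterSpace(
    names = c("p", "ap", "z", "c1", "ca50", "kxb", "koff", "Tref"),
    lower = c(0.5, 8,  0.5, 1, 0.4, 0.02, 0.03, 60),
    upper = c(2.5, 16, 5.0, 5, 1.2, 0.10, 0.25, 200))
}

#' @describeIn parameterSpace parameter names, in order.
#' @param space a \linkS4class{ParameterSpace}.
#' @export
paramNames <- function(space) space@names

#' @describeIn parameterSpace per-dimension lower bounds.
#' @export
lowerBounds <- function(space) setNames(space@lower, space@names)

#' @describeIn parameterSpace per-dimension upper bounds.
#' @export
upperBounds <- function(space) setNames(space@upper, space@names)

#' @describeIn parameterSpace number of dimensions.
#' @export
numParams <- function(space) length(space@names)

setMethod("show", "ParameterSpace", function(object) {
  cat("ParameterSpace with", length(object@names), "dimensions\n")
  df <- data.frame(lower = object@lower, upper = object@upper,
                   row.names = object@names)
  print(df)
})

# affine maps between the physical box and the unit cube; all design and
# emulator internals work on [0,1]^D
toUnit <- function(space, X) {
  X <- asPointMatrix(space, X)
  sweep(sweep(X, 2, space@lower, "-"), 2, space@upper - space@lower, "/")
}

fromUnit <- function(space, U) {
  U <- as.matrix(U)
  X <- sweep(sweep(U, 2, space@upper - space@lower, "*"), 2, space@lower, "+")
  colnames(X) <- space@names
  X
}

# accept a single named/unnamed point or an n x D matrix
asPointMatrix <- function(space, X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(space@names))
    ewStop("ew_dimension_error", "point dimension does not match the space")
  if (!is.null(colnames(X)) && all(space@names %in% colnames(X)))
    X <- X[, space@names, drop = FALSE]
  colnames(X) <- space@names
  X
}

#' Construct an ExperimentalDesign
#'
#' Usually produced by the design generators; exposed for constructing
#' designs from externally computed points.
#'
#' @param points n x D matrix of points in physical units.
#' @param space the \linkS4class{ParameterSpace} the points live in.
#' @param scheme generating scheme label.
#' @param seed integer seed recorded with the design.
#' @param acceptanceRate proposal acceptance rate (rejection-type schemes).
#' @param exhausted TRUE when the proposal budget ran out short of target.
#' @return an \linkS4class{ExperimentalDesign}.
#' @export
experimentalDesign <- function(points, space, scheme = "lhd", seed = 0L,
                               acceptanceRate = 1, exhausted = FALSE) {
  points <- asPointMatrix(space, points)
  new("ExperimentalDesign", points = points, scheme = scheme,
      seed = as.integer(seed), space = space,
      acceptanceRate = acceptanceRate, exhausted = exhausted)
}

#' @describeIn experimentalDesign the design points (n x D matrix).
#' @param design an \linkS4class{ExperimentalDesign}.
#' @export
designPoints <- function(design) design@points

#' @describeIn experimentalDesign number of points in the design.
#' @export
designSize <- function(design) nrow(design@points)

setMethod("show", "ExperimentalDesign", function(object) {
  cat(sprintf("ExperimentalDesign: %d points x %d dims, scheme '%s', seed %d\n",
              nrow(object@points), ncol(object@points), object@scheme,
              object@seed))
  if (object@scheme %in% c("rejection", "cloud"))
    cat(sprintf("  acceptance rate %.3f%s\n", object@acceptanceRate,
                if (object@exhausted) " (proposal budget exhausted)" else ""))
})
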