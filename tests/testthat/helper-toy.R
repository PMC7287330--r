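# toy 2-parameter analytic "simulator" producing SummarizedExperiment
# batches compatible with trainingView(), for exercising the wave machinery
# without the heart model

toySpace <- function() parameterSpace(c("p", "ap"), c(0, 0), c(1, 1))

# funcs: named list of functions of an n x 2 matrix returning n values;
# failWhen: optional predicate marking rows as failed simulations
makeToySimulator <- function(space, funcs, failWhen = NULL) {
  function(X) {
    X <- as.matrix(X)
    colnames(X) <- paramNames(space)
    n <- nrow(X)
    Y <- vapply(funcs, function(f) f(X), numeric(n))
    if (n == 1) Y <- matrix(Y, 1, dimnames = list(NULL, names(funcs)))
    status <- rep("ok", n)
    if (!is.null(failWhen)) status[failWhen(X)] <- "no_ejection"
    feats <- t(Y)
    feats[, status != "ok"] <- NA_real_
    SummarizedExperiment::SummarizedExperiment(
      assays = list(features = feats),
      colData = S4Vectors::DataFrame(X, status = status),
      metadata = list(space = space,
                      counts = c(ok = sum(status == "ok"),
                                 no_ejection = sum(status != "ok"),
                                 numerical_failure = 0L)))
  }
}

toyFuncs <- list(
  EDV = function(X) 100 + 60 * X[, 1] + 25 * X[, 2]^2 + 10 * X[, 1] * X[, 2],
  PeakP = function(X) 10 + 8 * sin(2 * X[, 1]) - 5 * X[, 2])

midPoint <- function(space) {
  setNames((lowerBounds(space) + upperBounds(space)) / 2, paramNames(space))
}
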