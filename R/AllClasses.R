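#' ParameterSpace: a box-shaped input domain
#'
#' An axis-aligned box in parameter space: ordered parameter names with
#' per-dimension lower and upper bounds in physical units. All designs,
#' emulators and history-matching runs are defined relative to one of these.
#'
#' @slot names character, ordered parameter identifiers.
#' @slot lower numeric, per-dimension lower bounds.
#' @slot upper numeric, per-dimension upper bounds.
#' @export
setClass("ParameterSpace",
  representation(names = "character", lower = "numeric", upper = "numeric"))

setValidity("ParameterSpace", function(object) {
  n <- length(object@names)
  if (length(object@lower) != n || length(object@upper) != n)
    return("names, lower and upper must have equal length")
  if (n < 1) return("at least one dimension required")
  if (anyDuplicated(object@names)) return("parameter names must be unique")
  if (!all(is.finite(object@lower)) || !all(is.finite(object@upper)))
    return("bounds must be finite")
  if (!all(object@lower < object@upper))
    return("lower bound must be strictly below upper bound in every dimension")
  TRUE
})

#' ExperimentalDesign: a set of points in a ParameterSpace
#'
#' A matrix of design points (rows) in physical units, together with the
#' generating scheme, the seed and the space they were drawn in.
#'
#' @slot points numeric matrix, n x D, columns named after the parameters.
#' @slot scheme character, one of "lhd", "saltelli", "rejection", "cloud".
#' @slot seed integer seed used to generate the design.
#' @slot space the \linkS4class{ParameterSpace} the points live in.
#' @slot acceptanceRate numeric, proposal acceptance rate for rejection-type
#'   schemes (1 for unconditional schemes).
#' @slot exhausted logical, TRUE when a rejection-type scheme ran out of
#'   proposal budget before reaching its target size.
#' @export
setClass("ExperimentalDesign",
  representation(points = "matrix", scheme = "character", seed = "integer",
                 space = "ParameterSpace", acceptanceRate = "numeric",
                 exhausted = "logical"),
  prototype(acceptanceRate = 1, exhausted = FALSE))

setValidity("ExperimentalDesign", function(object) {
  if (nrow(object@points) < 1) return("design must contain at least one point")
  if (ncol(object@points) != length(object@space@names))
    return("point dimension does not match the parameter space")
  if (!identical(colnames(object@points), object@space@names))
    return("design columns must be named after the space parameters")
  tol <- 1e-9 * (object@space@upper - object@space@lower)
  inside <- sweep(object@points, 2, object@space@lower - tol, ">=") &
            sweep(object@points, 2, object@space@upper + tol, "<=")
  if (!all(inside)) return("design points must lie inside the space box")
  if (!object@scheme %in% c("lhd", "saltelli", "rejection", "cloud"))
    return("unknown design scheme")
  TRUE
})

#' SimProtocol: fixed constants of the 0D heart simulator
#'
#' Everything the simulator needs beyond the eight mechanics parameters:
#' pacing, integration step, calcium-transient shape, mitral/Windkessel
#' circuit constants and the passive/active pressure-law constants. These
#' are protocol constants, not tunable inputs, so that the simulator maps
#' exactly eight parameters to twelve features.
#'
#' @slot pacingHz pacing frequency (Hz).
#' @slot beats number of beats integrated; features use the final beat only.
#' @slot dt integration step (ms); adjusted at construction to divide the
#'   cycle length exactly.
#' @slot caDia diastolic calcium level (uM).
#' @slot caAmp calcium transient amplitude above baseline (uM).
#' @slot caTau time-to-peak of the calcium pulse (ms).
#' @slot rMitral mitral filling resistance (kPa ms uL^-1).
#' @slot rPeriph Windkessel peripheral resistance (kPa ms uL^-1).
#' @slot cArt Windkessel arterial compliance (uL kPa^-1).
#' @slot v0 reference (unstressed) LV volume (uL).
#' @slot passiveBeta exponent of the passive pressure-volume law.
#' @slot forceScale scaling from cellular tension to ventricular pressure.
#' @export
setClass("SimProtocol",
  representation(pacingHz = "numeric", beats = "numeric", dt = "numeric",
                 caDia = "numeric", caAmp = "numeric", caTau = "numeric",
                 rMitral = "numeric", rPeriph = "numeric", cArt = "numeric",
                 v0 = "numeric", passiveBeta = "numeric",
                 forceScale = "numeric"))

setValidity("SimProtocol", function(object) {
  if (object@pacingHz <= 0) return("pacing frequency must be positive")
  if (object@beats < 1) return("at least one beat required")
  cyc <- 1000 / object@pacingHz
  if (abs(cyc / object@dt - round(cyc / object@dt)) > 1e-8)
    return("dt must divide the cycle length")
  if (any(c(object@caTau, object@rMitral, object@rPeriph, object@cArt,
            object@v0, object@dt) <= 0))
    return("time constants, resistances, compliance and v0 must be positive")
  TRUE
})

#' LVTransients: final-beat pressure/volume traces of one simulation
#'
#' @slot time uniform time grid over the final beat (ms, starting at 0).
#' @slot pressure LV pressure trace (kPa).
#' @slot volume LV volume trace (uL).
#' @slot events named vector of valve event times (ms): mitral_close,
#'   aortic_open, aortic_close, mitral_open; NA when the event did not occur.
#' @slot flowIntegral time-integral of aortic flow over ejection (uL).
#' @slot status "ok", "no_ejection" or "numerical_failure".
#' @export
setClass("LVTransients",
  representation(time = "numeric", pressure = "numeric", volume = "numeric",
                 events = "numeric", flowIntegral = "numeric",
                 status = "character"))

setValidity("LVTransients", function(object) {
  if (!object@status %in% c("ok", "no_ejection", "numerical_failure"))
    return("unknown status")
  if (length(object@time) != length(object@pressure) ||
      length(object@time) != length(object@volume))
    return("time, pressure and volume must have equal length")
  if (object@status == "ok") {
    ev <- object@events
    if (any(!is.finite(ev))) return("status ok requires all four valve events")
    if (is.unsorted(ev)) return("valve events must be ordered mc<=ao<=ac<=mo")
    if (any(object@volume <= 0)) return("volume must stay positive")
  }
  TRUE
})

#' GPEmulator: a per-feature probabilistic surrogate
#'
#' Universal-kriging style emulator: a polynomial mean function fitted by
#' least squares, plus a zero-mean anisotropic GP fitted to the residuals by
#' maximum marginal likelihood. Inputs are scaled to the unit cube and the
#' output is standardised internally; predictions are back-transformed.
#'
#' @slot featureName name of the emulated output.
#' @slot kernel "squared_exponential", "matern32" or "matern52".
#' @slot degree polynomial mean degree (1, 2 or 3).
#' @slot beta mean-function coefficients (on scaled data).
#' @slot lengthscales per-dimension GP lengthscales (unit-cube scale).
#' @slot sigf2 GP signal variance (scaled-output units).
#' @slot sign2 nugget variance (scaled-output units).
#' @slot logLik attained log marginal likelihood of the residual GP.
#' @slot space input \linkS4class{ParameterSpace} (defines the unit-cube map).
#' @slot Xunit retained training inputs on the unit cube.
#' @slot resid retained mean-function residuals (scaled output).
#' @slot alpha K^-1 resid, cached for prediction.
#' @slot L upper Cholesky factor of the training covariance.
#' @slot Kinv inverse training covariance, cached for batched predictive
#'   variances.
#' @slot yCenter,yScale output standardisation constants.
#' @slot cvR2 mean 5-fold cross-validated R-squared of the selected spec
#'   (NA when selection was not run).
#' @export
setClass("GPEmulator",
  representation(featureName = "character", kernel = "character",
                 degree = "numeric", beta = "numeric",
                 lengthscales = "numeric", sigf2 = "numeric",
                 sign2 = "numeric", logLik = "numeric",
                 space = "ParameterSpace", Xunit = "matrix",
                 resid = "numeric", alpha = "numeric", L = "matrix",
                 Kinv = "matrix",
                 yCenter = "numeric", yScale = "numeric", cvR2 = "numeric"))

setValidity("GPEmulator", function(object) {
  if (!object@kernel %in% c("squared_exponential", "matern32", "matern52"))
    return("unknown kernel")
  if (!object@degree %in% 1:3) return("mean degree must be 1, 2 or 3")
  if (any(object@lengthscales <= 0)) return("lengthscales must be positive")
  if (object@sigf2 < 0 || object@sign2 < 0)
    return("variances must be non-negative")
  TRUE
})

#' EmulatorBank: independent emulators for several output features
#'
#' @slot emulators named list of \linkS4class{GPEmulator} objects.
#' @export
setClass("EmulatorBank", representation(emulators = "list"))

setValidity("EmulatorBank", function(object) {
  if (!all(vapply(object@emulators, is, TRUE, class2 = "GPEmulator")))
    return("all elements must be GPEmulator objects")
  if (is.null(names(object@emulators)) || anyDuplicated(names(object@emulators)))
    return("emulators must be uniquely named by feature")
  TRUE
})

#' TargetSet: observed feature means and standard deviations to match
#'
#' @slot features names of the matched features (a subset of the canonical
#'   twelve; EF is never matched directly because it is derived from
#'   EDV and ESV).
#' @slot mean observed per-feature means.
#' @slot sd observation standard deviations (strictly positive).
#' @export
setClass("TargetSet",
  representation(features = "character", mean = "numeric", sd = "numeric"))

setValidity("TargetSet", function(object) {
  n <- length(object@features)
  if (length(object@mean) != n || length(object@sd) != n)
    return("features, mean and sd must have equal length")
  if (any(object@sd <= 0)) return("observation SDs must be strictly positive")
  if (!all(object@features %in% featureNames()))
    return("matched features must be among the canonical twelve")
  if ("EF" %in% object@features)
    return("EF is derived from EDV and ESV and is never matched directly")
  if (anyDuplicated(object@features)) return("duplicate matched feature")
  TRUE
})

#' HistoryMatchRun: the result of a wave-based history-matching run
#'
#' @slot waves per-wave diagnostics: cutoff, test-set size, NROY size,
#'   non-implausible fraction of the wave's testing set, simulations
#'   attempted/succeeded, training size, and the cumulative NROY volume
#'   fraction relative to the initial box (product of per-wave fractions).
#' @slot nroy final NROY point cloud (physical units).
#' @slot emulators final-wave \linkS4class{EmulatorBank}.
#' @slot space the input \linkS4class{ParameterSpace}.
#' @slot targets the matched \linkS4class{TargetSet}.
#' @slot cutoffFinal implausibility cutoff of the final wave.
#' @slot audit list of exact counters: simulator calls, emulator evaluations.
#' @slot seed master seed of the run.
#' @export
setClass("HistoryMatchRun",
  representation(waves = "data.frame", nroy = "matrix",
                 emulators = "EmulatorBank", space = "ParameterSpace",
                 targets = "TargetSet", cutoffFinal = "numeric",
                 audit = "list", seed = "integer"))

#' SobolResult: variance-based sensitivity indices for one output
#'
#' @slot feature name of the analysed output.
#' @slot S1 first-order indices (length D).
#' @slot S2 second-order indices (D x D matrix, upper triangle filled).
#' @slot ST total-effect indices (length D).
#' @slot higherOrder interactions of order three and above:
#'   sum(ST) - sum(S1) - 2 sum(S2), since each pairwise index enters two
#'   total effects (raw, may be slightly negative from estimator noise).
#' @slot totalVariance sample variance of the model output over the design.
#' @slot nBase Saltelli base sample size used.
#' @slot seed seed used for the design.
#' @export
setClass("SobolResult",
  representation(feature = "character", S1 = "numeric", S2 = "matrix",
                 ST = "numeric", higherOrder = "numeric",
                 totalVariance = "numeric", nBase = "numeric",
                 seed = "integer"))
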