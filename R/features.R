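#' Canonical left-ventricular feature names
#'
#' The twelve organ-scale features extracted from the final-beat volume and
#' pressure transients, in their canonical order: the first seven
#' characterise the volume curve, the last five the pressure curve.
#'
#' @return character vector of length 12.
#' @examples
#' featureNames()
#' @export
featureNames <- function() {
  c("EDV", "ESV", "EF", "IVCT", "ET", "IVRT", "Tdiast",
    "PeakP", "Tpeak", "ESP", "maxdP", "mindP")
}

#' Feature units, aligned with \code{\link{featureNames}}
#' @return named character vector of units.
#' @export
featureUnits <- function() {
  setNames(c("uL", "uL", "%", "ms", "ms", "ms", "ms",
             "kPa", "ms", "kPa", "kPa/ms", "kPa/ms"), featureNames())
}

# linear interpolation of a trace at an (interpolated) event time
traceAt <- function(t, y, t0) {
  i <- findInterval(t0, t, all.inside = TRUE)
  w <- (t0 - t[i]) / (t[i + 1] - t[i])
  (1 - w) * y[i] + w * y[i + 1]
}

#' Extract the 12 LV features from a final-beat transient
#'
#' Volumes are read at the valve events: EDV at mitral closure, ESV at
#' aortic closure (end-systole). Phase durations are differences of the
#' event times; diastolic time is the complement of the three systolic
#' phases within the cycle. Pressure magnitudes are the trace maximum
#' (PeakP, with Tpeak its time from cycle start, first maximiser on ties),
#' the pressure at aortic closure (ESP) and the extrema of the centred
#' finite-difference dP/dt (one-sided at the endpoints).
#'
#' @param tr an \linkS4class{LVTransients} with status "ok".
#' @return named numeric vector of length 12 in canonical order.
#' @examples
#' m <- colMeans(rbind(lowerBounds(defaultParameterSpace()),
#'                     upperBounds(defaultParameterSpace())))
#' extractFeatures(simulateHeart(m))
#' @export
extractFeatures <- function(tr) {
  if (!is(tr, "LVTransients"))
    ewStop("ew_feature_error", "extractFeatures expects an LVTransients")
  if (tr@status != "ok")
    ewStop("ew_feature_error",
           sprintf("cannot extract features from a '%s' simulation",
                   tr@status))
  ev <- tr@events
  if (any(!is.finite(ev)))
    ewStop("ew_feature_error", "all four valve events are required")
  extractFeaturesCore(tr@time, tr@pressure, tr@volume, ev)
}

# hot-path extraction on raw traces (no S4 construction)
extractFeaturesCore <- function(t, P, V, ev) {
  cyc <- t[length(t)]
  EDV <- traceAt(t, V, ev[["mitral_close"]])
  ESV <- traceAt(t, V, ev[["aortic_close"]])
  IVCT <- ev[["aortic_open"]] - ev[["mitral_close"]]
  ET <- ev[["aortic_close"]] - ev[["aortic_open"]]
  IVRT <- ev[["mitral_open"]] - ev[["aortic_close"]]
  ipk <- which.max(P)
  dP <- numeric(length(P))
  dt <- t[2] - t[1]
  n <- length(P)
  dP[2:(n - 1)] <- (P[3:n] - P[1:(n - 2)]) / (2 * dt)
  dP[1] <- (P[2] - P[1]) / dt
  dP[n] <- (P[n] - P[n - 1]) / dt
  out <- c(EDV = EDV, ESV = ESV, EF = 100 * (EDV - ESV) / EDV,
           IVCT = IVCT, ET = ET, IVRT = IVRT,
           Tdiast = cyc - IVCT - ET - IVRT,
           PeakP = max(P), Tpeak = t[ipk],
           ESP = traceAt(t, P, ev[["aortic_close"]]),
           maxdP = max(dP), mindP = min(dP))
  out[featureNames()]
}
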