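#' Construct a simulation protocol
#'
#' Returns the fixed constants of the 0D left-ventricle simulator. The
#' integration step is adjusted at construction to the nearest value that
#' divides the cycle length exactly. Defaults are calibrated so that a
#' mid-range parameter point ejects with an ejection fraction between 50
#' and 80 per cent and a peak pressure above the aortic pressure.
#'
#' @param pacingHz pacing frequency (Hz); rat default 6.
#' @param beats number of beats; the first beats are wash-in, features are
#'   read from the final beat only.
#' @param dt requested integration step (ms).
#' @param caDia,caAmp,caTau calcium transient shape: diastolic level (uM),
#'   amplitude (uM) and time-to-peak (ms).
#' @param rMitral mitral filling resistance (kPa ms uL^-1).
#' @param rPeriph,cArt Windkessel peripheral resistance (kPa ms uL^-1) and
#'   arterial compliance (uL kPa^-1).
#' @param v0 unstressed LV volume (uL).
#' @param passiveBeta passive pressure-volume exponent.
#' @param forceScale scaling from cellular tension to cavity pressure.
#' @return a \linkS4class{SimProtocol}.
#' @examples
#' simProtocol()
#' @export
simProtocol <- function(pacingHz = 6, beats = 4, dt = 0.05,
                        caDia = 0.05, caAmp = 1.25, caTau = 18,
                        rMitral = 0.02, rPeriph = 3, cArt = 30,
                        v0 = 250, passiveBeta = 1.8, forceScale = 0.65) {
  cyc <- 1000 / pacingHz
  dt <- cyc / max(1, round(cyc / dt))
  new("SimProtocol", pacingHz = pacingHz, beats = beats, dt = dt,
      caDia = caDia, caAmp = caAmp, caTau = caTau, rMitral = rMitral,
      rPeriph = rPeriph, cArt = cArt, v0 = v0, passiveBeta = passiveBeta,
      forceScale = forceScale)
}

#' @describeIn simProtocol cycle length in ms (1000 / pacing frequency).
#' @param protocol a \linkS4class{SimProtocol}.
#' @export
cycleLength <- function(protocol) 1000 / protocol@pacingHz

setMethod("show", "SimProtocol", function(object) {
  cat(sprintf(
    "SimProtocol: %g Hz pacing (%.2f ms cycle), %g beats, dt %.4g ms\n",
    object@pacingHz, cycleLength(object), object@beats, object@dt))
  cat(sprintf("  Ca: dia %g + amp %g uM, tau %g ms | WK: Rp %g, C %g | v0 %g uL\n",
              object@caDia, object@caAmp, object@caTau, object@rPeriph,
              object@cArt, object@v0))
})

protoVector <- function(protocol) {
  c(cycleLength(protocol), protocol@dt, protocol@beats, protocol@caDia,
    protocol@caAmp, protocol@caTau, protocol@rMitral, protocol@rPeriph,
    protocol@cArt, protocol@v0, protocol@passiveBeta, protocol@forceScale)
}

#' Intracellular calcium transient
#'
#' The fixed calcium drive of the simulator: a skewed pulse
#' \code{caDia + caAmp * (t/tau) * exp(1 - t/tau)} that starts at the
#' diastolic level, peaks at \code{caDia + caAmp} exactly at \code{t = tau}
#' and relaxes back; it repeats every beat.
#'
#' @param t time within the cycle (ms); values outside are wrapped.
#' @param protocol a \linkS4class{SimProtocol}.
#' @return calcium concentration (uM), vectorised over \code{t}.
#' @examples
#' calciumTransient(c(0, 18), simProtocol())
#' @export
calciumTransient <- function(t, protocol = simProtocol()) {
  tl <- t %% cycleLength(protocol)
  protocol@caDia + protocol@caAmp * (tl / protocol@caTau) *
    exp(1 - tl / protocol@caTau)
}

#' Simulate the 0D left ventricle at one parameter point
#'
#' Integrates a time-varying-elastance left ventricle over several beats:
#' Hill-type (n = 2) calcium binding drives an activation state, a first-order
#' cross-bridge stage low-passes it into tension, cavity pressure is the sum
#' of an exponential passive law and a volume-scaled active term, filling is
#' driven by a constant preload through a mitral resistance and ejection
#' feeds a three-element Windkessel whose distal pressure relaxes to the
#' aortic pressure parameter. Only the final beat is returned. Simulation
#' failure is encoded in the status, never raised: "no_ejection" when
#' contraction is insufficient to reach the aortic pressure (the aortic
#' valve never opens in the final beat), "numerical_failure" when the
#' integrator state degenerates.
#'
#' @param m named numeric vector (or 1-row matrix) of the 8 parameters, in
#'   the units of \code{\link{defaultParameterSpace}} (z in mmHg s ml^-1,
#'   converted internally).
#' @param protocol a \linkS4class{SimProtocol}.
#' @return an \linkS4class{LVTransients}.
#' @examples
#' m <- colMeans(rbind(lowerBounds(defaultParameterSpace()),
#'                     upperBounds(defaultParameterSpace())))
#' tr <- simulateHeart(m)
#' tr@status
#' @export
simulateHeart <- function(m, protocol = simProtocol()) {
  m <- asPointMatrix(defaultParameterSpace(), m)[1, ]
  if (any(!is.finite(m)) || any(m <= 0))
    ewStop("ew_sim_error", "all parameters must be strictly positive")
  m["z"] <- mmHgSecPerMl2kPaMsPerUl(m["z"])
  res <- .simulate_lv(as.numeric(m), protoVector(protocol))
  status <- c("ok", "no_ejection", "numerical_failure")[res$status + 1L]
  new("LVTransients", time = res$time, pressure = res$pressure,
      volume = res$volume, events = res$events,
      flowIntegral = res$flowIntegral, status = status)
}

setMethod("show", "LVTransients", function(object) {
  cat(sprintf("LVTransients (%s): %d samples over %.2f ms\n", object@status,
              length(object@time), max(object@time)))
  if (object@status == "ok")
    cat(sprintf("  V [%.1f, %.1f] uL, P [%.2f, %.2f] kPa, events %s ms\n",
                min(object@volume), max(object@volume), min(object@pressure),
                max(object@pressure),
                paste(sprintf("%.1f", object@events), collapse = "/")))
})

#' Run the simulator over a design and collect features
#'
#' One simulation per design point. Failed points (no ejection or numerical
#' failure) carry NA features but stay in the result -- failures are data.
#' The result is a \code{SummarizedExperiment}: the assay holds the 12 x n
#' feature matrix, \code{colData} the parameter values and status.
#'
#' @param design an \linkS4class{ExperimentalDesign} over the 8-parameter
#'   space (or a point matrix).
#' @param protocol a \linkS4class{SimProtocol}.
#' @param space required when \code{design} is a bare matrix.
#' @return a \code{SummarizedExperiment}; \code{metadata()} holds the status
#'   counts and the protocol.
#' @examples
#' d <- latinHypercube(defaultParameterSpace(), 4, seed = 1)
#' se <- simulateBatch(d)
#' table(se$status)
#' @export
simulateBatch <- function(design, protocol = simProtocol(), space = NULL) {
  if (is(design, "ExperimentalDesign")) {
    space <- design@space
    X <- designPoints(design)
  } else {
    if (is.null(space)) space <- defaultParameterSpace()
    X <- asPointMatrix(space, design)
  }
  n <- nrow(X)
  if (n < 1) ewStop("ew_sim_error", "design must be non-empty")
  feats <- matrix(NA_real_, length(featureNames()), n,
                  dimnames = list(featureNames(), NULL))
  status <- character(n)
  pv <- protoVector(protocol)
  zcol <- match("z", colnames(X))
  statusNames <- c("ok", "no_ejection", "numerical_failure")
  for (i in seq_len(n)) {
    m <- X[i, ]
    m[zcol] <- mmHgSecPerMl2kPaMsPerUl(m[zcol])
    res <- .simulate_lv(as.numeric(m), pv)
    status[i] <- statusNames[res$status + 1L]
    if (res$status == 0L)
      feats[, i] <- extractFeaturesCore(res$time, res$pressure, res$volume,
                                        res$events)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feats),
    colData = S4Vectors::DataFrame(X, status = status),
    metadata = list(protocol = protocol, space = space,
                    counts = c(ok = sum(status == "ok"),
                               no_ejection = sum(status == "no_ejection"),
                               numerical_failure =
                                 sum(status == "numerical_failure"))))
}

#' Successful-simulation view of a batch
#'
#' Drops failed simulations and returns the training pair used by the
#' emulators: inputs in physical units and the feature matrix.
#'
#' @param se a \code{SummarizedExperiment} from \code{\link{simulateBatch}}.
#' @return list with \code{X} (n_ok x 8 inputs) and \code{Y} (n_ok x 12
#'   features, points in rows).
#' @export
trainingView <- function(se) {
  ok <- se$status == "ok"
  space <- S4Vectors::metadata(se)$space
  X <- as.matrix(SummarizedExperiment::colData(se)[ok, paramNames(space),
                                                   drop = FALSE])
  Y <- t(SummarizedExperiment::assay(se, "features")[, ok, drop = FALSE])
  list(X = X, Y = Y)
}
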