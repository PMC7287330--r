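# seed discipline: every exported stochastic operation takes an explicit
# seed, runs in a local RNG scope, and restores the caller's stream.

withSeed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-stream seeds derived from one master seed, kept within
# 32-bit integer range so downstream set.seed() always accepts them
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483629)
}

#' Convert impedance from mmHg s per ml to kPa ms per microlitre
#'
#' Aortic characteristic impedance is conventionally quoted in
#' mmHg s ml^-1; the simulator works in kPa, ms and microlitres. The two
#' time/volume rescalings (s to ms, ml to uL) cancel, leaving the pressure
#' conversion 1 mmHg = 0.133322 kPa.
#'
#' @param z numeric vector, impedance in mmHg s ml^-1.
#' @return impedance in kPa ms uL^-1.
#' @examples
#' mmHgSecPerMl2kPaMsPerUl(1)
#' @export
mmHgSecPerMl2kPaMsPerUl <- function(z) z * 0.133322

# stop() with a class so callers can distinguish typed failures
ewStop <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
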