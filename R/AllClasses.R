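#' @import methods
NULL

#' KineticParameters: constants of the aggregation model
#'
#' Holds the constants of the discrete-time aggregation model: the net
#' monomer reproduction rate \eqn{\delta}, the monomer carrying capacity
#' \eqn{\gamma}, the ordered reaction constants \eqn{K_1, \ldots, K_{n-1}}
#' (the constant \eqn{K_i} governs the reaction of a monomer with an
#' \eqn{i}-mer), and the aggregation number \eqn{n}, the number of monomers
#' that make one oligomer.
#'
#' All quantities are dimensionless abundances/rates; the time step is fixed
#' at one unit.
#'
#' @slot delta numeric(1), net monomer reproduction rate per step; > 0.
#' @slot gamma numeric(1), monomer carrying capacity; > 0.
#' @slot K numeric vector of length `n - 1` of reaction constants; all > 0.
#' @slot n integer(1), oligomer aggregation number; >= 3.
#'
#' @seealso [kineticParameters()] for the user constructor.
#' @export
setClass("KineticParameters",
  representation(delta = "numeric", gamma = "numeric",
                 K = "numeric", n = "integer"))

setValidity("KineticParameters", function(object) {
  msg <- character()
  if (length(object@delta) != 1L || !is.finite(object@delta) ||
      object@delta <= 0)
    msg <- c(msg, "'delta' must be a single finite value > 0")
  if (length(object@gamma) != 1L || !is.finite(object@gamma) ||
      object@gamma <= 0)
    msg <- c(msg, "'gamma' must be a single finite value > 0")
  if (length(object@n) != 1L || is.na(object@n) || object@n < 3L)
    msg <- c(msg, "'n' (aggregation number) must be an integer >= 3")
  if (length(object@n) == 1L && !is.na(object@n) && object@n >= 3L &&
      length(object@K) != object@n - 1L)
    msg <- c(msg, sprintf("'K' must have length n - 1 = %d, got %d",
                          object@n - 1L, length(object@K)))
  if (any(!is.finite(object@K)) || any(object@K <= 0))
    msg <- c(msg, "every reaction constant K[i] must be finite and > 0")
  if (length(msg)) msg else TRUE
})

#' AggregateState: species abundances at one time index
#'
#' The state of the aggregation chain at an integer time index: abundances
#' of monomers, dimers, ..., up to the (n-1)-mer, plus a cumulative oligomer
#' accumulator `O`. The accumulator books the mass removed by the final
#' reaction (monomer + (n-1)-mer -> oligomer) so that oligomer production is
#' measurable; it does not feed back into the dynamics.
#'
#' @slot M numeric vector of length `n - 1`; abundances, all >= 0.
#' @slot O numeric(1), cumulative oligomer output; >= 0, non-decreasing in time.
#' @slot t integer(1), time index; >= 0.
#'
#' @seealso [aggregateState()] for the user constructor.
#' @export
setClass("AggregateState",
  representation(M = "numeric", O = "numeric", t = "integer"))

setValidity("AggregateState", function(object) {
  msg <- character()
  if (any(!is.finite(object@M)) || any(object@M < 0))
    msg <- c(msg, "all species abundances M must be finite and >= 0")
  if (length(object@O) != 1L || !is.finite(object@O) || object@O < 0)
    msg <- c(msg, "'O' must be a single finite value >= 0")
  if (length(object@t) != 1L || is.na(object@t) || object@t < 0L)
    msg <- c(msg, "'t' must be a single integer >= 0")
  if (length(msg)) msg else TRUE
})

#' Trajectory: an ordered sequence of states
#'
#' A simulated path of the model: one row per time index, carrying the
#' species abundances and the cumulative oligomer accumulator, together with
#' the [KineticParameters-class] that produced it and the simulation mode.
#'
#' @slot M numeric matrix, one row per time index, `n - 1` columns.
#' @slot O numeric vector of cumulative oligomer output per time index.
#' @slot t integer vector of consecutive time indices.
#' @slot params the [KineticParameters-class] used.
#' @slot mode character(1), `"interacting"` or `"no_interaction"`.
#'
#' @export
setClass("Trajectory",
  representation(M = "matrix", O = "numeric", t = "integer",
                 params = "KineticParameters", mode = "character"))

setValidity("Trajectory", function(object) {
  msg <- character()
  nr <- nrow(object@M)
  if (length(object@O) != nr || length(object@t) != nr)
    msg <- c(msg, "M, O and t must have one entry per time index")
  if (nr > 1L && any(diff(object@t) != 1L))
    msg <- c(msg, "time indices must be consecutive integers")
  if (nr > 1L && any(diff(object@O) < -1e-12))
    msg <- c(msg, "cumulative oligomer output O must be non-decreasing")
  if (ncol(object@M) != object@params@n - 1L)
    msg <- c(msg, "state dimension does not match parameters")
  if (!object@mode %in% c("interacting", "no_interaction"))
    msg <- c(msg, "mode must be 'interacting' or 'no_interaction'")
  if (length(msg)) msg else TRUE
})

#' EquilibriumPoint: a fixed point of the update map
#'
#' @slot M numeric vector of length `n - 1`.
#' @slot kind character(1), `"extinction"` (all-zero point) or
#'   `"coexistence"` (positive point).
#'
#' @export
setClass("EquilibriumPoint",
  representation(M = "numeric", kind = "character"))

setValidity("EquilibriumPoint", function(object) {
  msg <- character()
  if (!object@kind %in% c("extinction", "coexistence"))
    msg <- c(msg, "kind must be 'extinction' or 'coexistence'")
  if (identical(object@kind, "extinction") && any(object@M != 0))
    msg <- c(msg, "extinction point must be the all-zero vector")
  if (identical(object@kind, "coexistence") && object@M[1] <= 0)
    msg <- c(msg, "coexistence point must have M1 > 0")
  if (length(msg)) msg else TRUE
})

#' StabilityReport: eigenvalues, Gershgorin certificate and classification
#'
#' The outcome of local stability analysis at one equilibrium: the Jacobian,
#' its eigenvalues and spectral radius, the Gershgorin disks, the two
#' conditions of the stability theorem (the row-1 sum condition
#' \eqn{\sum_{i \ge 2} K_i < (\delta + 2\gamma K_1)/\gamma} and the
#' monotonicity \eqn{K_{i-1} \le K_i}), the resulting Gershgorin
#' certificate, and the eigenvalue-based classification.
#'
#' @slot which character(1), `"extinction"` or `"coexistence"`.
#' @slot jacobian the analytic Jacobian matrix at the equilibrium.
#' @slot eigenvalues complex vector of Jacobian eigenvalues.
#' @slot spectralRadius numeric(1), max eigenvalue magnitude.
#' @slot disks data.frame of Gershgorin disks (columns `center`, `radius`).
#' @slot sumConditionHolds logical(1), theorem sum condition (strict).
#' @slot sumConditionMargin numeric(1),
#'   \eqn{(\delta + 2\gamma K_1)/\gamma - \sum_{i=2}^{n-1} K_i}
#'   (positive when the condition holds).
#' @slot monotoneKHolds logical(1), \eqn{K_{i-1} \le K_i} for all i.
#' @slot monotoneKBoundary logical(1), TRUE when some \eqn{K_{i-1} = K_i}
#'   exactly (a disk tangent to the unit circle; the certificate defers to
#'   eigenvalues).
#' @slot gershgorinCertified logical(1), TRUE when every disk lies strictly
#'   inside the unit circle.
#' @slot classification character(1), `"stable"`, `"unstable"` or
#'   `"marginal"` from eigenvalue magnitudes.
#'
#' @export
setClass("StabilityReport",
  representation(which = "character", jacobian = "matrix",
                 eigenvalues = "complex", spectralRadius = "numeric",
                 disks = "data.frame",
                 sumConditionHolds = "logical",
                 sumConditionMargin = "numeric",
                 monotoneKHolds = "logical",
                 monotoneKBoundary = "logical",
                 gershgorinCertified = "logical",
                 classification = "character"))

setValidity("StabilityReport", function(object) {
  msg <- character()
  if (abs(object@spectralRadius - max(Mod(object@eigenvalues))) > 1e-12)
    msg <- c(msg, "spectralRadius must equal the max eigenvalue magnitude")
  if (isTRUE(object@gershgorinCertified) &&
      identical(object@classification, "unstable"))
    msg <- c(msg, "a Gershgorin-certified equilibrium cannot be unstable")
  if (length(msg)) msg else TRUE
})

#' ScanResult: stability summaries along a parameter grid
#'
#' @slot which character(1), the swept parameter (`"K1"` or `"delta"`).
#' @slot grid numeric vector, strictly increasing swept values.
#' @slot table data.frame with one row per grid point: the swept value,
#'   equilibrium monomer level `M1star`, theorem flags, destabilization flag
#'   and margin, spectral radius and classification.
#' @slot params the baseline [KineticParameters-class].
#'
#' @export
setClass("ScanResult",
  representation(which = "character", grid = "numeric",
                 table = "data.frame", params = "KineticParameters"))

setValidity("ScanResult", function(object) {
  msg <- character()
  if (length(object@grid) != nrow(object@table))
    msg <- c(msg, "one table row per grid point required")
  if (length(object@grid) > 1L && any(diff(object@grid) <= 0))
    msg <- c(msg, "grid must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' RunConfig: a validated run configuration
#'
#' @slot params the [KineticParameters-class].
#' @slot M0 numeric initial species vector.
#' @slot T integer(1) simulation horizon.
#' @slot seed integer(1) random seed; >= 0.
#' @slot mode character(1), `"interacting"` or `"no_interaction"`.
#'
#' @export
setClass("RunConfig",
  representation(params = "KineticParameters", M0 = "numeric",
                 T = "integer", seed = "integer", mode = "character"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (length(object@M0) != object@params@n - 1L)
    msg <- c(msg, sprintf(
      "initial vector M0 must have length n - 1 = %d, got %d",
      object@params@n - 1L, length(object@M0)))
  if (any(!is.finite(object@M0)) || any(object@M0 < 0))
    msg <- c(msg, "initial abundances M0 must be finite and >= 0")
  if (length(object@T) != 1L || is.na(object@T) || object@T < 0L)
    msg <- c(msg, "'T' must be a single integer >= 0")
  if (length(object@seed) != 1L || is.na(object@seed) || object@seed < 0L)
    msg <- c(msg, "'seed' must be a single nonnegative integer")
  if (!object@mode %in% c("interacting", "no_interaction"))
    msg <- c(msg, "mode must be 'interacting' or 'no_interaction'")
  if (length(msg)) msg else TRUE
})
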