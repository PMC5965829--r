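#' Constructors for model objects
#'
#' `kineticParameters()` builds a validated [KineticParameters-class]:
#' `delta` is the net monomer reproduction rate per step, `gamma` the
#' monomer carrying capacity, `K` the vector of reaction constants
#' \eqn{K_1, \ldots, K_{n-1}}, and `n` the aggregation number (monomers per
#' oligomer, default 6 as is standard for beta-amyloid).
#' `aggregateState()` builds a validated [AggregateState-class].
#'
#' @param delta numeric(1) > 0.
#' @param gamma numeric(1) > 0.
#' @param K numeric vector of length `n - 1`, all entries > 0.
#' @param n integer(1) >= 3; defaults to `length(K) + 1`.
#' @param M numeric vector of species abundances (monomers first), all >= 0.
#' @param O numeric(1) cumulative oligomer output, >= 0.
#' @param t integer(1) time index, >= 0.
#'
#' @return A [KineticParameters-class] or [AggregateState-class] object.
#' @examples
#' p <- kineticParameters(delta = 1, gamma = 100,
#'                        K = c(0.01, 0.02, 0.03, 0.04, 0.05))
#' s <- aggregateState(M = c(10, 0, 0, 0, 0))
#' @export
kineticParameters <- function(delta, gamma, K, n = length(K) + 1L) {
  new("KineticParameters", delta = as.numeric(delta),
      gamma = as.numeric(gamma), K = as.numeric(K), n = as.integer(n))
}

#' @rdname kineticParameters
#' @export
aggregateState <- function(M, O = 0, t = 0L) {
  new("AggregateState", M = as.numeric(M), O = as.numeric(O),
      t = as.integer(t))
}

#' Accessors for model objects
#'
#' Small accessor generics: `netGrowthRate()`, `carryingCapacity()`,
#' `rateConstants()` and `aggregationNumber()` read the slots of a
#' [KineticParameters-class]; `speciesAbundances()`, `oligomerPool()` and
#' `timeIndex()` read an [AggregateState-class] (or, for trajectories, the
#' full matrix/vector); `finalState()` returns the last
#' [AggregateState-class] of a [Trajectory-class]; `equilibriumKind()` reads
#' an [EquilibriumPoint-class]; `spectralRadius()`, `classification()` and
#' `gershgorinCertified()` read a [StabilityReport-class]; `scanTable()`
#' reads a [ScanResult-class].
#'
#' @param x the object.
#' @name accessors
#' @return The corresponding slot value.
NULL

#' @rdname accessors
setMethod("netGrowthRate", "KineticParameters", function(x) x@delta)

#' @rdname accessors
setMethod("carryingCapacity", "KineticParameters", function(x) x@gamma)

#' @rdname accessors
setMethod("rateConstants", "KineticParameters", function(x) x@K)

#' @rdname accessors
setMethod("aggregationNumber", "KineticParameters", function(x) x@n)

#' @rdname accessors
setMethod("speciesAbundances", "AggregateState", function(x) x@M)

#' @rdname accessors
setMethod("oligomerPool", "AggregateState", function(x) x@O)

#' @rdname accessors
setMethod("timeIndex", "AggregateState", function(x) x@t)

#' @rdname accessors
setMethod("speciesAbundances", "Trajectory", function(x) x@M)

#' @rdname accessors
setMethod("oligomerPool", "Trajectory", function(x) x@O)

#' @rdname accessors
setMethod("timeIndex", "Trajectory", function(x) x@t)

#' @rdname accessors
setMethod("speciesAbundances", "EquilibriumPoint", function(x) x@M)

#' @rdname accessors
setMethod("equilibriumKind", "EquilibriumPoint", function(x) x@kind)

#' @rdname accessors
setMethod("finalState", "Trajectory", function(x) {
  i <- nrow(x@M)
  aggregateState(M = x@M[i, ], O = x@O[i], t = x@t[i])
})

#' @rdname accessors
setMethod("spectralRadius", "StabilityReport", function(x) x@spectralRadius)

#' @rdname accessors
setMethod("classification", "StabilityReport", function(x) x@classification)

#' @rdname accessors
setMethod("gershgorinCertified", "StabilityReport",
          function(x) x@gershgorinCertified)

#' @rdname accessors
setMethod("scanTable", "ScanResult", function(x) x@table)

#' @describeIn accessors number of states in a trajectory.
setMethod("length", "Trajectory", function(x) nrow(x@M))

setMethod("show", "KineticParameters", function(object) {
  cat("KineticParameters: n =", object@n,
      "| delta =", object@delta, "| gamma =", object@gamma, "\n")
  cat("  K:", paste(signif(object@K, 6), collapse = ", "), "\n")
})

setMethod("show", "AggregateState", function(object) {
  cat("AggregateState at t =", object@t, "\n")
  cat("  M:", paste(signif(object@M, 6), collapse = ", "),
      "| O =", signif(object@O, 6), "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nrow(object@M), "states (t =", object@t[1], "..",
      object@t[length(object@t)], "), mode =", object@mode, "\n")
  cat("  final M:", paste(signif(object@M[nrow(object@M), ], 6),
                          collapse = ", "),
      "| final O =", signif(object@O[length(object@O)], 6), "\n")
})

setMethod("show", "EquilibriumPoint", function(object) {
  cat("EquilibriumPoint (", object@kind, "): ",
      paste(signif(object@M, 6), collapse = ", "), "\n", sep = "")
})

setMethod("show", "StabilityReport", function(object) {
  cat("StabilityReport for the", object@which, "equilibrium\n")
  cat("  spectral radius:", signif(object@spectralRadius, 8),
      "->", object@classification, "\n")
  cat("  theorem sum condition:", object@sumConditionHolds,
      "(margin", signif(object@sumConditionMargin, 6), ")\n")
  cat("  K monotone:", object@monotoneKHolds,
      if (object@monotoneKBoundary) "(boundary: some K[i-1] == K[i])" else "",
      "\n")
  cat("  Gershgorin certified stable:", object@gershgorinCertified, "\n")
})

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult over", object@which, ":", length(object@grid),
      "grid points in [", min(object@grid), ",", max(object@grid), "]\n")
  print(utils::head(object@table, 5))
  if (nrow(object@table) > 5) cat("  ...\n")
})

#' Coerce a trajectory to a data.frame
#'
#' One row per time index with columns `t`, `M1` .. `M{n-1}`, `O`.
#'
#' @param x a [Trajectory-class].
#' @param ... ignored.
#' @return A data.frame.
#' @export
as.data.frame.Trajectory <- function(x, ...) {
  k <- ncol(x@M)
  df <- data.frame(t = x@t, x@M, O = x@O)
  names(df) <- c("t", paste0("M", seq_len(k)), "O")
  df
}

setMethod("as.data.frame", "Trajectory", as.data.frame.Trajectory)
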