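#' Sweep one parameter and summarize equilibrium and stability
#'
#' Clones the baseline parameters at each grid value of `K1` (catalyst
#' intervention) or `delta` (suppressant intervention) and records, per
#' point, the coexistence monomer level \eqn{M_1^*}, the theorem flags, the
#' Gershgorin certificate, the destabilization flag and margin, and the
#' spectral radius with its eigenvalue classification.
#'
#' @param params baseline [KineticParameters-class].
#' @param which `"K1"` or `"delta"`.
#' @param grid strictly increasing vector of positive values; default
#'   log-spaced over two decades around the baseline value.
#' @return A [ScanResult-class].
#' @examples
#' p <- kineticParameters(1, 100, c(0.01, 0.02, 0.03, 0.04, 0.05))
#' scanParameter(p, "K1", grid = c(0.01, 0.05, 0.1))
#' @export
scanParameter <- function(params, which = c("K1", "delta"), grid = NULL) {
  which <- match.arg(which)
  stopifnot(is(params, "KineticParameters"))
  validObject(params)
  if (is.null(grid)) {
    base <- if (which == "K1") params@K[1] else params@delta
    grid <- 10^seq(log10(base) - 1, log10(base) + 1, length.out = 25)
  }
  grid <- as.numeric(grid)
  if (any(grid <= 0)) stop("grid values must be positive")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  rows <- lapply(grid, function(v) {
    p <- params
    if (which == "K1") p@K[1] <- v else p@delta <- v
    validObject(p)
    eq <- coexistenceEquilibrium(p)
    rep <- classifyEquilibrium(p, "coexistence")
    dc <- destabilizationCriterion(p)
    data.frame(value = v, M1star = eq@M[1],
               sumConditionHolds = rep@sumConditionHolds,
               monotoneKHolds = rep@monotoneKHolds,
               gershgorinCertified = rep@gershgorinCertified,
               destabilized = dc$met, destabMargin = dc$margin,
               spectralRadius = rep@spectralRadius,
               classification = rep@classification)
  })
  new("ScanResult", which = which, grid = grid,
      table = do.call(rbind, rows), params = params)
}

#' Analytic K1 threshold of the destabilization criterion
#'
#' Solving \eqn{\sum_{i=2}^{n-1} K_i = (\delta + 2\gamma K_1)/\gamma} for
#' \eqn{K_1} gives the boundary
#' \deqn{K_1^{\mathrm{thr}} = \frac{\gamma \sum_{i=2}^{n-1} K_i - \delta}
#'   {2\gamma}.}
#' Below the threshold the criterion is met (certificate lost); above it,
#' not. A nonpositive threshold means reducing \eqn{K_1} alone can never
#' meet the criterion.
#'
#' @param params a [KineticParameters-class].
#' @return A list with `threshold` (the boundary K1, possibly <= 0) and
#'   `attainable` (logical; TRUE iff threshold > 0).
#' @export
stabilityBoundaryK1 <- function(params) {
  stopifnot(is(params, "KineticParameters"))
  validObject(params)
  k <- params@n - 1L
  thr <- (params@gamma * sum(params@K[2:k]) - params@delta) /
    (2 * params@gamma)
  list(threshold = thr, attainable = thr > 0)
}

#' Inferred aggregation number along a K1 or gamma sweep
#'
#' Evaluates the corrected size inversion [inferOligomerSize()] along a
#' grid: sweeping \eqn{K_1} at fixed \eqn{\gamma} (the size is proportional
#' to \eqn{1/K_1}, hence strictly decreasing), or sweeping \eqn{\gamma} at
#' fixed \eqn{K_1} (strictly increasing). Raising the inferred size — by
#' lowering \eqn{K_1} or raising \eqn{\gamma} — means more monomers are
#' needed per oligomer, i.e. fewer oligomers form.
#'
#' @param delta numeric(1) > 0.
#' @param M1_star numeric(1) > 0, equilibrium monomer level; must be below
#'   every `gamma` in a gamma-sweep.
#' @param sweep `"K1"` or `"gamma"`: which quantity the grid runs over.
#' @param grid strictly increasing positive values of the swept quantity.
#' @param gamma fixed carrying capacity (K1-sweep).
#' @param K1 fixed monomer-monomer constant (gamma-sweep).
#' @return A data.frame with the grid values and the inferred `size`.
#' @export
nCurve <- function(delta, M1_star, sweep = c("K1", "gamma"), grid,
                   gamma = NULL, K1 = NULL) {
  sweep <- match.arg(sweep)
  grid <- as.numeric(grid)
  if (any(grid <= 0)) stop("grid values must be positive")
  if (sweep == "K1") {
    if (is.null(gamma)) stop("a fixed 'gamma' is required for a K1-sweep")
    if (M1_star >= gamma) stop("M1_star must be below gamma")
    size <- vapply(grid, function(k1)
      inferOligomerSize(delta, gamma, k1, M1_star)$size, numeric(1))
    data.frame(K1 = grid, size = size)
  } else {
    if (is.null(K1)) stop("a fixed 'K1' is required for a gamma-sweep")
    if (any(M1_star >= grid)) stop("M1_star must be below every gamma")
    size <- vapply(grid, function(g)
      inferOligomerSize(delta, g, K1, M1_star)$size, numeric(1))
    data.frame(gamma = grid, size = size)
  }
}

#' Seeding experiment: time to oligomer accumulation vs initial monomers
#'
#' Simulates the model from increasing initial monomer levels ("seeds") and
#' records, per level, the first time index at which the cumulative
#' oligomer accumulator crosses a threshold. More seeds make aggregate
#' formation faster, so crossing times are non-increasing in the seed
#' level.
#'
#' @param params a [KineticParameters-class].
#' @param seedLevels strictly increasing vector of positive initial monomer
#'   abundances.
#' @param threshold numeric(1) > 0, oligomer amount defining "aggregated".
#' @param Tmax integer(1), simulation horizon per level.
#' @return A data.frame with columns `seed`, `crossingTime` (NA when the
#'   threshold is not reached by `Tmax`) and `finalO`.
#' @examples
#' p <- kineticParameters(1, 100, c(0.01, 0.02, 0.03, 0.04, 0.05))
#' seedingExperiment(p, c(5, 50), threshold = 1, Tmax = 200)
#' @export
seedingExperiment <- function(params, seedLevels, threshold, Tmax = 500L) {
  stopifnot(is(params, "KineticParameters"))
  validObject(params)
  if (!length(seedLevels)) stop("'seedLevels' must be non-empty")
  if (any(seedLevels <= 0)) stop("seed levels must be positive")
  if (length(seedLevels) > 1L && any(diff(seedLevels) <= 0))
    stop("seed levels must be strictly increasing")
  if (threshold <= 0) stop("'threshold' must be > 0")
  k <- params@n - 1L
  rows <- lapply(seedLevels, function(s) {
    tr <- simulateTrajectory(params,
                             aggregateState(c(s, numeric(k - 1L))), Tmax)
    hit <- which(tr@O >= threshold)
    data.frame(seed = s,
               crossingTime = if (length(hit)) tr@t[hit[1]] else NA_integer_,
               finalO = tr@O[length(tr@O)])
  })
  do.call(rbind, rows)
}
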