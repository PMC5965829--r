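#' Extinction equilibrium
#'
#' The all-zero fixed point \eqn{E^* = (0, \ldots, 0)}: no monomers, no
#' aggregates. It is a fixed point of the update map exactly.
#'
#' @param params a [KineticParameters-class].
#' @return An [EquilibriumPoint-class] of kind `"extinction"`.
#' @export
extinctionEquilibrium <- function(params) {
  stopifnot(is(params, "KineticParameters"))
  validObject(params)
  new("EquilibriumPoint", M = numeric(params@n - 1L), kind = "extinction")
}

#' Coexistence equilibrium
#'
#' The positive fixed point of the aggregation map:
#' \deqn{M_1^* = \frac{\delta\gamma}{\delta + n\gamma K_1}, \qquad
#'       M_i^* = \frac{K_1}{K_i} M_1^*, \quad 2 \le i \le n-1.}
#' \eqn{M_1^*} always lies strictly between 0 and \eqn{\gamma}.
#'
#' @param params a [KineticParameters-class].
#' @return An [EquilibriumPoint-class] of kind `"coexistence"`.
#' @examples
#' p <- kineticParameters(1, 100, c(0.01, 0.02, 0.03, 0.04, 0.05))
#' speciesAbundances(coexistenceEquilibrium(p))[1]  # 100/7
#' @export
coexistenceEquilibrium <- function(params) {
  stopifnot(is(params, "KineticParameters"))
  validObject(params)
  delta <- params@delta; gamma <- params@gamma
  K <- params@K; n <- params@n
  M1 <- delta * gamma / (delta + n * gamma * K[1])
  M <- c(M1, (K[1] / K[-1]) * M1)
  new("EquilibriumPoint", M = M, kind = "coexistence")
}

#' Fixed-point residual of a candidate equilibrium
#'
#' Applies [stepState()] once to the candidate point and returns the maximum
#' over species of \eqn{|M_i' - M_i| / \max(1, |M_i|)}. A genuine
#' equilibrium gives a residual at rounding level; a perturbed point does
#' not.
#'
#' @param point an [EquilibriumPoint-class] (or numeric species vector).
#' @param params a [KineticParameters-class].
#' @return numeric(1), the maximum relative residual.
#' @export
fixedPointResidual <- function(point, params) {
  M <- if (is(point, "EquilibriumPoint")) point@M else as.numeric(point)
  s <- aggregateState(M)
  Mn <- stepState(s, params)@M
  max(abs(Mn - M) / pmax(1, abs(M)))
}

#' Infer the oligomer aggregation number from the equilibrium monomer level
#'
#' Inverts the coexistence relation \eqn{M_1^* = \delta\gamma/(\delta +
#' n\gamma K_1)} to recover the aggregation number n from
#' \eqn{(\delta, \gamma, K_1, M_1^*)}. The exact algebraic inversion is
#' \deqn{n = \frac{\delta(\gamma - M_1^*)}{\gamma K_1 M_1^*}}
#' (mode `"corrected"`, the default). Mode `"as_printed"` evaluates the
#' widely quoted form without the \eqn{\gamma} in the denominator,
#' \eqn{\delta(\gamma - M_1^*)/(K_1 M_1^*)}; substituting the equilibrium
#' formula into it returns \eqn{n\gamma} rather than n, so this mode is
#' retained for reference and a message flags the discrepancy when it is
#' used. At \eqn{M_1^* = \gamma} both modes return 0.
#'
#' @param delta numeric(1) > 0, net monomer reproduction rate.
#' @param gamma numeric(1) > 0, carrying capacity.
#' @param K1 numeric(1) > 0, monomer-monomer reaction constant.
#' @param M1_star numeric(1), equilibrium monomer level; 0 < M1_star <= gamma.
#' @param mode `"corrected"` (default) or `"as_printed"`.
#' @return A list with `size` (real-valued aggregation number) and
#'   `sizeRounded` (nearest integer, half-to-even, a convenience).
#' @examples
#' p <- kineticParameters(1, 100, c(0.01, 0.02, 0.03, 0.04, 0.05))
#' M1s <- speciesAbundances(coexistenceEquilibrium(p))[1]
#' inferOligomerSize(1, 100, 0.01, M1s)$size  # 6
#' @export
inferOligomerSize <- function(delta, gamma, K1, M1_star,
                              mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  if (delta <= 0 || gamma <= 0 || K1 <= 0)
    stop("delta, gamma and K1 must all be > 0")
  if (M1_star <= 0 || M1_star > gamma)
    stop("M1_star must satisfy 0 < M1_star <= gamma")
  size <- delta * (gamma - M1_star) / (gamma * K1 * M1_star)
  if (mode == "as_printed") {
    size <- size * gamma
    message("as_printed mode: this form evaluates to gamma times the ",
            "aggregation number; use 'corrected' for the exact inversion")
  }
  list(size = size, sizeRounded = round(size))
}

#' Census of equilibria off the M1 = 0 surface
#'
#' Every point with \eqn{M_1 = 0} is a fixed point of the map (no reactions
#' occur without monomers), so only equilibria with \eqn{M_1 > 0} are of
#' interest. This census runs a multi-start root search on
#' `stepState(M) - M` over the region \eqn{M_1 > 0} (random nonnegative
#' starts plus the closed-form candidates), de-duplicates the converged
#' roots, and returns the distinct equilibria found with \eqn{M_1} above a
#' cutoff.
#'
#' @param params a [KineticParameters-class].
#' @param nStarts integer(1), number of random starts (default 60).
#' @param seed integer(1), RNG seed for the starts.
#' @param m1Cutoff numeric(1), minimum M1 for a root to count as off the
#'   M1 = 0 surface (default 1e-6).
#' @param tol numeric(1), fixed-point residual tolerance for accepting a
#'   converged root (default 1e-8).
#' @return A list with `count` (number of distinct equilibria with
#'   M1 > `m1Cutoff`) and `points` (matrix of the distinct roots, one row
#'   each).
#' @export
findEquilibria <- function(params, nStarts = 60L, seed = 1L,
                           m1Cutoff = 1e-6, tol = 1e-8) {
  stopifnot(is(params, "KineticParameters"))
  validObject(params)
  k <- params@n - 1L
  g <- function(M) stepState(aggregateState(pmax(M, 0)), params)@M - pmax(M, 0)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)

  starts <- rbind(
    speciesAbundances(coexistenceEquilibrium(params)),
    matrix(stats::runif(nStarts * k, min = 0,
                        max = 2 * params@gamma), ncol = k))
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(g, starts[i, ], tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(sol)) next
    r <- pmax(sol$x, 0)
    if (any(!is.finite(r))) next
    if (fixedPointResidual(r, params) < tol) roots[[length(roots) + 1L]] <- r
  }
  if (!length(roots))
    return(list(count = 0L, points = matrix(numeric(), ncol = k)))
  R <- do.call(rbind, roots)
  R <- R[R[, 1] > m1Cutoff, , drop = FALSE]
  # de-duplicate: cluster roots closer than a relative tolerance
  distinct <- matrix(numeric(), ncol = k, nrow = 0)
  for (i in seq_len(nrow(R))) {
    dup <- FALSE
    if (nrow(distinct)) {
      d <- apply(distinct, 1L,
                 function(q) max(abs(q - R[i, ]) / pmax(1, abs(q))))
      dup <- any(d < 1e-5)
    }
    if (!dup) distinct <- rbind(distinct, R[i, ])
  }
  list(count = nrow(distinct), points = distinct)
}
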