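#' Analytic Jacobian at the extinction equilibrium
#'
#' At \eqn{E^* = 0} the linearization is diagonal:
#' \eqn{\mathrm{diag}(\delta + 1, 1, \ldots, 1)}. Its leading eigenvalue
#' \eqn{\delta + 1 > 1} makes the extinction point unstable for every
#' \eqn{\delta > 0}; the remaining unit eigenvalues reflect that higher
#' species are frozen when no monomers are present.
#'
#' @param params a [KineticParameters-class].
#' @return A numeric `(n-1) x (n-1)` matrix.
#' @export
jacobianExtinction <- function(params) {
  stopifnot(is(params, "KineticParameters"))
  validObject(params)
  diag(c(params@delta + 1, rep(1, params@n - 2L)))
}

#' Analytic Jacobian at the coexistence equilibrium
#'
#' The linearization of the update map at \eqn{M^*}. Row 1 is dense:
#' \deqn{a_{11} = 1 - \frac{M_1^*(\delta + 2\gamma K_1)}{\gamma(\delta+1)},
#'  \qquad a_{1j} = -\frac{M_1^* K_j}{\delta + 1}, \quad j \ge 2.}
#' Rows \eqn{2 \le i \le n-1} carry only a sub-diagonal and a diagonal
#' entry,
#' \deqn{a_{i,i-1} = \frac{K_{i-1} M_1^*}{1 + K_i M_1^*}, \qquad
#'       a_{ii} = \frac{1}{1 + K_i M_1^*},}
#' all other entries being exactly zero (the cross-couplings through
#' \eqn{M_1} cancel at the equilibrium).
#'
#' @param params a [KineticParameters-class].
#' @return A numeric `(n-1) x (n-1)` matrix.
#' @export
jacobianCoexistence <- function(params) {
  stopifnot(is(params, "KineticParameters"))
  validObject(params)
  delta <- params@delta; gamma <- params@gamma; K <- params@K
  k <- params@n - 1L
  M1s <- speciesAbundances(coexistenceEquilibrium(params))[1]
  J <- matrix(0, k, k)
  J[1, 1] <- 1 - M1s * (delta + 2 * gamma * K[1]) / (gamma * (delta + 1))
  J[1, 2:k] <- -M1s * K[2:k] / (delta + 1)
  for (i in 2:k) {
    J[i, i] <- 1 / (1 + K[i] * M1s)
    J[i, i - 1L] <- K[i - 1L] * M1s / (1 + K[i] * M1s)
  }
  J
}

#' Central-finite-difference Jacobian of the step map
#'
#' Numerical oracle for the analytic Jacobians: differentiates the M-part
#' of [stepState()] at an arbitrary nonnegative point by central
#' differences.
#'
#' @param point numeric species vector (or [EquilibriumPoint-class]).
#' @param params a [KineticParameters-class].
#' @param h numeric(1) > 0, difference step (default 1e-6, scaled by
#'   `max(1, |point|)` per coordinate).
#' @return A numeric `(n-1) x (n-1)` matrix.
#' @export
numericalJacobian <- function(point, params, h = 1e-6) {
  M <- if (is(point, "EquilibriumPoint")) point@M else as.numeric(point)
  if (h <= 0) stop("'h' must be > 0")
  k <- length(M)
  stepM <- function(x) .stepM(x, params)  # raw map: admits the small
  J <- matrix(0, k, k)                    # negative excursions of central
                                          # differencing at a boundary point
  for (j in seq_len(k)) {
    hj <- h * max(1, abs(M[j]))
    e <- numeric(k); e[j] <- hj
    J[, j] <- (stepM(M + e) - stepM(M - e)) / (2 * hj)
  }
  J
}

#' Gershgorin disks of a square matrix
#'
#' One disk per row: center at the diagonal entry \eqn{a_{ii}}, radius the
#' off-diagonal absolute row sum \eqn{r_i = \sum_{j \ne i} |a_{ij}|}. Every
#' eigenvalue of the matrix lies in the union of the disks.
#'
#' @param m a square numeric (or complex) matrix.
#' @return A data.frame with one row per disk, columns `center` (complex)
#'   and `radius`.
#' @export
gershgorinDisks <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("'m' must be a square matrix")
  centers <- as.complex(diag(m))
  radii <- rowSums(abs(m)) - abs(diag(m))
  data.frame(center = centers, radius = radii)
}

# eigenvalue classification with a marginality band around |lambda| = 1
.classifySpectrum <- function(eigenvalues, tol = 1e-9) {
  mags <- Mod(eigenvalues)
  rho <- max(mags)
  if (rho > 1 + tol) "unstable"
  else if (rho < 1 - tol) "stable"
  else "marginal"
}

#' Stability analysis of an equilibrium
#'
#' Builds the analytic Jacobian at the requested equilibrium, computes its
#' eigenvalues, spectral radius and Gershgorin disks, and evaluates the two
#' conditions of the stability theorem for the coexistence point:
#' \deqn{\sum_{i=2}^{n-1} K_i < \frac{\delta + 2\gamma K_1}{\gamma}
#'   \quad\text{and}\quad K_{i-1} \le K_i, \;\; 2 \le i \le n-1.}
#' The Gershgorin certificate is computed from the actual disks: row 1 must
#' satisfy \eqn{a_{11} - r_1 > -1} and \eqn{a_{11} + r_1 < 1} (the latter
#' is algebraically the sum condition), and rows \eqn{i \ge 2} must satisfy
#' \eqn{a_{ii} + r_i < 1}, i.e. \eqn{K_{i-1} < K_i}. Equality
#' \eqn{K_{i-1} = K_i} places a disk tangent to the unit circle; the
#' certificate is then withheld (`monotoneKBoundary`) and classification
#' defers to the eigenvalues.
#'
#' For the extinction point the spectrum is \eqn{\{\delta+1, 1, \ldots\}};
#' since \eqn{\delta > 0} the classification is always `"unstable"`, with
#' the unit eigenvalues recorded (the point is non-hyperbolic).
#'
#' Eigenvalue magnitudes within `1e-9` of 1 are classified `"marginal"`.
#'
#' @param params a [KineticParameters-class].
#' @param which `"extinction"` or `"coexistence"`.
#' @return A [StabilityReport-class].
#' @examples
#' p <- kineticParameters(10, 1, rep(0.1, 5))
#' classifyEquilibrium(p, "coexistence")
#' @export
classifyEquilibrium <- function(params,
                                which = c("coexistence", "extinction")) {
  which <- match.arg(which)
  stopifnot(is(params, "KineticParameters"))
  validObject(params)
  delta <- params@delta; gamma <- params@gamma; K <- params@K
  k <- params@n - 1L
  J <- if (which == "extinction") jacobianExtinction(params)
       else jacobianCoexistence(params)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)
  rho <- max(Mod(ev))
  disks <- gershgorinDisks(J)

  Ktail <- sum(K[2:k])
  bound <- (delta + 2 * gamma * K[1]) / gamma
  sumHolds <- Ktail < bound
  sumMargin <- bound - Ktail
  monotone <- all(diff(K) >= 0)
  boundaryK <- monotone && any(diff(K) == 0)

  if (which == "extinction") {
    certified <- FALSE  # unit eigenvalues sit on the circle; no certificate
    cls <- if (delta > 0) "unstable" else .classifySpectrum(ev)
  } else {
    a11 <- Re(disks$center[1]); r1 <- disks$radius[1]
    row1ok <- (a11 - r1 > -1) && (a11 + r1 < 1)
    rowsok <- all(Re(disks$center[-1]) + disks$radius[-1] < 1) &&
      all(Re(disks$center[-1]) - disks$radius[-1] > -1)
    certified <- row1ok && rowsok
    cls <- .classifySpectrum(ev)
  }
  new("StabilityReport", which = which, jacobian = J,
      eigenvalues = ev, spectralRadius = rho, disks = disks,
      sumConditionHolds = sumHolds, sumConditionMargin = sumMargin,
      monotoneKHolds = monotone, monotoneKBoundary = boundaryK,
      gershgorinCertified = certified, classification = cls)
}

#' Destabilization (intervention) criterion
#'
#' The intervention condition: the coexistence equilibrium loses its
#' Gershgorin stability certificate when
#' \deqn{\sum_{i=2}^{n-1} K_i > \frac{\delta + 2\gamma K_1}{\gamma},}
#' which a catalyst can arrange by reducing \eqn{K_1} (or a suppressant by
#' reducing \eqn{\delta}). Violating the certificate does not by itself
#' prove instability — Gershgorin has no converse — so the report also
#' carries the eigenvalue-based classification of the coexistence point for
#' comparison.
#'
#' @param params a [KineticParameters-class].
#' @return A list with `met` (logical; TRUE iff the strict inequality
#'   holds), `margin` (\eqn{\sum_{i \ge 2} K_i - (\delta + 2\gamma
#'   K_1)/\gamma}), `spectralRadius` and `classification` of the
#'   coexistence Jacobian.
#' @export
destabilizationCriterion <- function(params) {
  stopifnot(is(params, "KineticParameters"))
  validObject(params)
  delta <- params@delta; gamma <- params@gamma; K <- params@K
  k <- params@n - 1L
  Ktail <- sum(K[2:k])
  bound <- (delta + 2 * gamma * K[1]) / gamma
  rep <- classifyEquilibrium(params, "coexistence")
  list(met = Ktail > bound, margin = Ktail - bound,
       spectralRadius = rep@spectralRadius,
       classification = rep@classification)
}
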