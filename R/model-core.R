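#' Beverton-Holt source term
#'
#' The monomer source \eqn{f(M_1(t)) = \delta M_1(t) (1 - M_1(t+1)/\gamma)}:
#' net production of monomers over one step, saturating at the carrying
#' capacity \eqn{\gamma}. The bracket uses the *next* monomer level, the
#' implicit (Beverton-Holt) convention that makes the one-species update
#' solvable in closed form.
#'
#' @param M1_now numeric(1) >= 0, monomer abundance at time t.
#' @param M1_next numeric(1) >= 0, monomer abundance at time t + 1.
#' @param params a [KineticParameters-class].
#' @return numeric(1), the per-step monomer production.
#' @examples
#' p <- kineticParameters(1, 100, c(0.01, 0.02, 0.03, 0.04, 0.05))
#' sourceTerm(10, 20, p)  # 10 * (1 - 20/100) = 8
#' @export
sourceTerm <- function(M1_now, M1_next, params) {
  stopifnot(is(params, "KineticParameters"))
  validObject(params)
  if (M1_now < 0 || M1_next < 0)
    stop("monomer abundances must be >= 0")
  params@delta * M1_now * (1 - M1_next / params@gamma)
}

#' One Beverton-Holt step of the monomer population
#'
#' The no-interaction monomer update
#' \deqn{M_1(t+1) = \frac{(\delta+1)\gamma M_1(t)}{\gamma + \delta M_1(t)},}
#' the classical Beverton-Holt map: iterates from any positive start
#' increase monotonically toward the carrying capacity \eqn{\gamma}.
#'
#' @param M1 numeric >= 0 (vectorized), monomer abundance.
#' @param params a [KineticParameters-class].
#' @return numeric, the monomer abundance one step later.
#' @examples
#' p <- kineticParameters(1, 100, c(0.01, 0.02, 0.03, 0.04, 0.05))
#' bevertonHoltStep(10, p)  # 2000/110
#' @export
bevertonHoltStep <- function(M1, params) {
  stopifnot(is(params, "KineticParameters"))
  validObject(params)
  if (any(M1 < 0)) stop("monomer abundance must be >= 0")
  (params@delta + 1) * params@gamma * M1 / (params@gamma + params@delta * M1)
}

#' Advance the aggregation chain by one time step
#'
#' The closed-form update of the full model. Monomers:
#' \deqn{M_1(t+1) = \frac{(\delta+1)\gamma M_1}{\gamma + \delta M_1
#'   + 2\gamma K_1 M_1 + \gamma \sum_{i=2}^{n-1} K_i M_i},}
#' and for each higher species \eqn{2 \le j \le n-1}
#' \deqn{M_j(t+1) = \frac{M_j + K_{j-1} M_1 M_{j-1}}{1 + K_j M_1}}
#' (with \eqn{M_{j-1} = M_1} for \eqn{j = 2}, so the dimer gain is
#' \eqn{K_1 M_1^2}). All right-hand sides use time-t values only. The
#' cumulative oligomer accumulator advances by the mass the last reaction
#' removes: \eqn{O(t+1) = O(t) + K_{n-1} M_1(t) M_{n-1}(t+1)}.
#'
#' In `"no_interaction"` mode all aggregation terms are disabled: monomers
#' follow [bevertonHoltStep()] and every other species (and `O`) is frozen.
#'
#' @param state an [AggregateState-class].
#' @param params a [KineticParameters-class]; its dimension must match.
#' @param mode `"interacting"` (default) or `"no_interaction"`.
#' @return The [AggregateState-class] at `t + 1`.
#' @examples
#' p <- kineticParameters(1, 100, c(0.01, 0.02, 0.03, 0.04, 0.05))
#' stepState(aggregateState(c(10, 0, 0, 0, 0)), p)
#' @export
stepState <- function(state, params,
                      mode = c("interacting", "no_interaction")) {
  mode <- match.arg(mode)
  stopifnot(is(state, "AggregateState"), is(params, "KineticParameters"))
  validObject(state); validObject(params)
  M <- state@M
  k <- params@n - 1L
  if (length(M) != k)
    stop(sprintf("state has %d species but parameters imply n - 1 = %d",
                 length(M), k))
  delta <- params@delta; gamma <- params@gamma; K <- params@K

  if (mode == "no_interaction") {
    Mnext <- M
    Mnext[1] <- bevertonHoltStep(M[1], params)
    return(aggregateState(Mnext, O = state@O, t = state@t + 1L))
  }

  Mnext <- .stepM(M, params)
  Onext <- state@O + K[k] * M[1] * Mnext[k]
  aggregateState(Mnext, O = Onext, t = state@t + 1L)
}

# raw closed-form update of the species vector; no state validation, so it
# can be evaluated at slightly negative points when differentiating
.stepM <- function(M, params) {
  delta <- params@delta; gamma <- params@gamma; K <- params@K
  k <- params@n - 1L
  denom1 <- gamma + delta * M[1] + 2 * gamma * K[1] * M[1] +
    gamma * sum(K[2:k] * M[2:k])
  Mnext <- numeric(k)
  Mnext[1] <- (delta + 1) * gamma * M[1] / denom1
  prev <- c(M[1], M[seq_len(k - 2L) + 1L])  # M1, M2, ..., M_{k-1}
  for (j in 2:k)
    Mnext[j] <- (M[j] + K[j - 1L] * M[1] * prev[j - 1L]) / (1 + K[j] * M[1])
  Mnext
}

#' Simulate the model over a horizon
#'
#' Iterates [stepState()] `T` times from an initial state and collects the
#' path into a [Trajectory-class] of length `T + 1`.
#'
#' @param params a [KineticParameters-class].
#' @param initial an [AggregateState-class].
#' @param T integer(1) >= 0, number of steps.
#' @param mode `"interacting"` (default) or `"no_interaction"`.
#' @return A [Trajectory-class].
#' @examples
#' p <- kineticParameters(1, 100, c(0.01, 0.02, 0.03, 0.04, 0.05))
#' tr <- simulateTrajectory(p, aggregateState(c(10, 0, 0, 0, 0)), T = 50)
#' finalState(tr)
#' @export
simulateTrajectory <- function(params, initial, T,
                               mode = c("interacting", "no_interaction")) {
  mode <- match.arg(mode)
  stopifnot(is(params, "KineticParameters"), is(initial, "AggregateState"))
  T <- as.integer(T)
  if (is.na(T) || T < 0L) stop("'T' must be a nonnegative integer")
  k <- params@n - 1L
  if (length(initial@M) != k)
    stop(sprintf("initial state has %d species but parameters imply %d",
                 length(initial@M), k))
  M <- matrix(NA_real_, nrow = T + 1L, ncol = k)
  O <- numeric(T + 1L)
  M[1L, ] <- initial@M; O[1L] <- initial@O
  s <- initial
  if (T > 0L) for (i in seq_len(T)) {
    s <- stepState(s, params, mode = mode)
    M[i + 1L, ] <- s@M; O[i + 1L] <- s@O
  }
  new("Trajectory", M = M, O = O,
      t = initial@t + 0:T, params = params, mode = mode)
}

#' Residuals of the increment-form balance equations
#'
#' Independent check of one step against the increment (mass-balance) form
#' of the model, which uses mixed time indexing: gains are evaluated at time
#' t, losses at time t + 1. Per species,
#' \deqn{\Delta M_1 = f(M_1) - 2 K_1 M_1(t) M_1(t+1)
#'   - M_1(t+1)\sum_{i=2}^{n-1} K_i M_i(t),}
#' \deqn{\Delta M_j = K_{j-1} M_{j-1}(t) M_1(t) - K_j M_1(t) M_j(t+1),
#'   \quad j \ge 2,}
#' and the function returns, per species, the difference between the
#' observed increment `next - current` and these right-hand sides. For a
#' pair produced by [stepState()] every residual vanishes to rounding.
#'
#' @param state an [AggregateState-class] at time t.
#' @param next_state an [AggregateState-class] at time t + 1.
#' @param params a [KineticParameters-class].
#' @param mode `"interacting"` (default) or `"no_interaction"`.
#' @return numeric vector of length `n - 1` of residuals.
#' @export
incrementResiduals <- function(state, next_state, params,
                               mode = c("interacting", "no_interaction")) {
  mode <- match.arg(mode)
  stopifnot(is(state, "AggregateState"), is(next_state, "AggregateState"),
            is(params, "KineticParameters"))
  if (next_state@t != state@t + 1L)
    stop("states must be at consecutive time indices")
  M <- state@M; Mn <- next_state@M
  k <- params@n - 1L
  if (length(M) != k || length(Mn) != k)
    stop("state dimension does not match parameters")
  K <- params@K
  f <- sourceTerm(M[1], Mn[1], params)
  if (mode == "no_interaction") {
    rhs <- c(f, rep(0, k - 1L))
    return((Mn - M) - rhs)
  }
  rhs <- numeric(k)
  rhs[1] <- f - 2 * K[1] * M[1] * Mn[1] - Mn[1] * sum(K[2:k] * M[2:k])
  prev <- c(M[1], M[seq_len(k - 2L) + 1L])
  for (j in 2:k)
    rhs[j] <- K[j - 1L] * prev[j - 1L] * M[1] - K[j] * M[1] * Mn[j]
  (Mn - M) - rhs
}

#' Monomer-equivalent mass audit of a trajectory
#'
#' The printed scheme does not conserve monomer-equivalent mass even with
#' the source removed, because losses are booked at time t + 1 while gains
#' are booked at time t. This diagnostic makes the drift visible rather than
#' hiding it: it returns, per time index, the total monomer equivalents
#' \eqn{\sum_i i\, M_i + n\, O} together with the cumulative source input,
#' and their difference (the scheme's intrinsic booking drift).
#'
#' @param traj a [Trajectory-class].
#' @return A data.frame with columns `t`, `massEquivalents`,
#'   `cumulativeSource`, `drift`.
#' @export
massAudit <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  p <- traj@params
  k <- p@n - 1L
  w <- seq_len(k)
  mass <- as.numeric(traj@M %*% w) + p@n * traj@O
  nr <- nrow(traj@M)
  src <- numeric(nr)
  if (nr > 1L) for (i in 2:nr) {
    if (traj@mode == "interacting") {
      s <- sourceTerm(traj@M[i - 1L, 1L], traj@M[i, 1L], p)
    } else {
      s <- traj@M[i, 1L] - traj@M[i - 1L, 1L]
    }
    src[i] <- src[i - 1L] + s
  }
  data.frame(t = traj@t, massEquivalents = mass, cumulativeSource = src,
             drift = mass - mass[1] - src)
}
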