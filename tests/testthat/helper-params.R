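# Shared fixtures: the baseline six-monomer parameter set used throughout,
# plus an implicit-form oracle that advances the model one step by solving
# the increment (mass-balance) equations with a root finder, independently
# of the closed-form update in stepState().

baseParams <- function() {
  kineticParameters(delta = 1, gamma = 100,
                    K = c(0.01, 0.02, 0.03, 0.04, 0.05), n = 6L)
}

# Solve the mixed-index increment equations for the t+1 state:
#   x1 - M1 = delta*M1*(1 - x1/gamma) - 2*K1*M1*x1 - x1*sum(K[i]*M[i])
#   xj - Mj = K[j-1]*M1*prev[j-1] - K[j]*M1*xj        (prev[1] = M1)
# Root-finding oracle; never calls the closed form.
implicitStepOracle <- function(M, params) {
  delta <- netGrowthRate(params); gamma <- carryingCapacity(params)
  K <- rateConstants(params); k <- aggregationNumber(params) - 1L
  g <- function(x) {
    r <- numeric(k)
    r[1] <- x[1] - M[1] -
      (delta * M[1] * (1 - x[1] / gamma) - 2 * K[1] * M[1] * x[1] -
         x[1] * sum(K[2:k] * M[2:k]))
    prev <- c(M[1], M[seq_len(k - 2L) + 1L])
    for (j in 2:k)
      r[j] <- x[j] - M[j] -
        (K[j - 1L] * M[1] * prev[j - 1L] - K[j] * M[1] * x[j])
    r
  }
  sol <- pracma::fsolve(g, as.numeric(M), tol = 1e-14)
  sol$x
}

randomState <- function(params, scale = NULL) {
  k <- aggregationNumber(params) - 1L
  if (is.null(scale)) scale <- carryingCapacity(params)
  aggregateState(stats::runif(k, 0, scale))
}
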