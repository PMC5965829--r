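#' Reproducible random parameter sets
#'
#' Draws a valid [KineticParameters-class] with \eqn{\delta} log-uniform on
#' `deltaRange`, \eqn{\gamma} log-uniform on `gammaRange` and every
#' \eqn{K_i} log-uniform on `kRange`. The default ranges
#' (\eqn{\delta \in [0.1, 10]}, \eqn{\gamma \in [10, 1000]},
#' \eqn{K_i \in [10^{-4}, 10^{-1}]}) are wide enough that both the
#' certified-stable and the destabilized regime are reachable.
#'
#' Under `condition = "certified_stable"` draws are rejection-sampled until
#' the stability theorem holds strictly (the row-sum condition
#' \eqn{\sum_{i \ge 2} K_i < (\delta + 2\gamma K_1)/\gamma} and strict K
#' monotonicity; the K draw is sorted ascending first). Under
#' `"destabilized"`, until the intervention criterion
#' \eqn{\sum_{i \ge 2} K_i > (\delta + 2\gamma K_1)/\gamma} holds. The
#' generator is deterministic in `seed` and restores the caller's RNG
#' state.
#'
#' @param seed integer(1) RNG seed.
#' @param n integer(1) aggregation number (default 6).
#' @param condition `"none"`, `"certified_stable"` or `"destabilized"`.
#' @param deltaRange,gammaRange,kRange length-2 positive ranges.
#' @param maxAttempts integer(1), rejection-sampling cap (default 100000).
#' @return A [KineticParameters-class].
#' @examples
#' randomParameters(1)
#' randomParameters(1, condition = "certified_stable")
#' @export
randomParameters <- function(seed, n = 6L,
                             condition = c("none", "certified_stable",
                                           "destabilized"),
                             deltaRange = c(0.1, 10),
                             gammaRange = c(10, 1000),
                             kRange = c(1e-4, 1e-1),
                             maxAttempts = 100000L) {
  condition <- match.arg(condition)
  n <- as.integer(n)
  if (n < 3L) stop("'n' must be >= 3")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  rlog <- function(m, r) 10^stats::runif(m, log10(r[1]), log10(r[2]))
  for (attempt in seq_len(maxAttempts)) {
    delta <- rlog(1, deltaRange)
    gamma <- rlog(1, gammaRange)
    K <- rlog(n - 1L, kRange)
    if (condition == "certified_stable") K <- sort(K)
    Ktail <- sum(K[-1])
    bound <- (delta + 2 * gamma * K[1]) / gamma
    ok <- switch(condition,
      none = TRUE,
      certified_stable = Ktail < bound && all(diff(K) > 0),
      destabilized = Ktail > bound)
    if (ok)
      return(kineticParameters(delta, gamma, K, n))
  }
  stop("rejection sampling failed to satisfy condition '", condition,
       "' within ", maxAttempts, " attempts; widen the ranges")
}
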