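#' Read and validate a run configuration
#'
#' Reads a YAML config with keys `delta`, `gamma`, `K` (list), `n`, `M0`
#' (list), `T`, `seed`, `mode` (`interacting` | `no_interaction`) and
#' returns a validated [RunConfig-class]. Every invariant violation
#' produces a named, human-readable error: missing keys, a `K` length that
#' does not match `n`, and nonpositive rates are each reported distinctly.
#'
#' @param path path to the YAML file.
#' @return A [RunConfig-class].
#' @examples
#' cfg <- readRunConfig(system.file("extdata", "example_config.yaml",
#'                                  package = "AbetaKinetics"))
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n` key as boolean FALSE; map it back
  names(raw)[names(raw) == "FALSE"] <- "n"
  required <- c("delta", "gamma", "K", "n", "M0", "T")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("config is missing required key(s): ",
         paste(missing, collapse = ", "))
  if (length(raw$delta) != 1L || !is.numeric(raw$delta) || raw$delta <= 0)
    stop("config key 'delta': must be a single number > 0")
  if (length(raw$gamma) != 1L || !is.numeric(raw$gamma) || raw$gamma <= 0)
    stop("config key 'gamma': must be a single number > 0")
  n <- as.integer(raw$n)
  if (length(n) != 1L || is.na(n) || n < 3L)
    stop("config key 'n': must be an integer >= 3")
  K <- as.numeric(unlist(raw$K))
  if (length(K) != n - 1L)
    stop(sprintf("config key 'K': length %d does not match n - 1 = %d",
                 length(K), n - 1L))
  if (any(K <= 0)) stop("config key 'K': all reaction constants must be > 0")
  params <- kineticParameters(raw$delta, raw$gamma, K, n)
  M0 <- as.numeric(unlist(raw$M0))
  mode <- if (is.null(raw$mode)) "interacting" else as.character(raw$mode)
  seed <- if (is.null(raw$seed)) 0L else as.integer(raw$seed)
  new("RunConfig", params = params, M0 = M0, T = as.integer(raw$T),
      seed = seed, mode = mode)
}

.fmt <- function(x) formatC(x, digits = 17, format = "g")

#' Write and read a trajectory table
#'
#' `writeTrajectory()` writes a [Trajectory-class] as a delimited table
#' with header `t, M1..M{n-1}, O`, one row per time index, at full double
#' precision so the table round-trips through `readTrajectoryTable()`
#' essentially exactly.
#'
#' @param traj a [Trajectory-class].
#' @param path output (input) file path.
#' @param format `"csv"` or `"tsv"`.
#' @return `writeTrajectory()` returns `path` invisibly;
#'   `readTrajectoryTable()` returns a data.frame.
#' @export
writeTrajectory <- function(traj, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(is(traj, "Trajectory"))
  df <- as.data.frame(traj)
  out <- df
  for (j in seq_along(out)[-1]) out[[j]] <- .fmt(df[[j]])
  ok <- tryCatch({
    utils::write.table(out, path, sep = if (format == "csv") "," else "\t",
                       row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write trajectory to '", path, "': ",
         conditionMessage(ok))
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectoryTable <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  utils::read.table(path, header = TRUE,
                    sep = if (format == "csv") "," else "\t")
}

#' Serialize a stability report as structured text
#'
#' Writes the flags, margins, spectral radius and eigenvalues (as
#' real/imaginary pairs) of a [StabilityReport-class] to a YAML document.
#'
#' @param report a [StabilityReport-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStabilityReport <- function(report, path) {
  stopifnot(is(report, "StabilityReport"))
  doc <- list(
    which = report@which,
    classification = report@classification,
    spectral_radius = report@spectralRadius,
    sum_condition_holds = report@sumConditionHolds,
    sum_condition_margin = report@sumConditionMargin,
    monotone_K_holds = report@monotoneKHolds,
    monotone_K_boundary = report@monotoneKBoundary,
    gershgorin_certified_stable = report@gershgorinCertified,
    eigenvalues = lapply(seq_along(report@eigenvalues), function(i)
      list(re = Re(report@eigenvalues[i]), im = Im(report@eigenvalues[i]))),
    gershgorin_disks = lapply(seq_len(nrow(report@disks)), function(i)
      list(center_re = Re(report@disks$center[i]),
           center_im = Im(report@disks$center[i]),
           radius = report@disks$radius[i])))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}
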