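#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-stream seed from a master seed, a stage name and a
# wave index. Keeps results independent across pipeline stages while everything
# flows from one master seed. Result is always a valid 32-bit R seed.
#' Derive a stage-specific random seed from a master seed
#'
#' All randomness in the package flows from one master seed; each pipeline
#' stage (population draw, risk surface, case draw, MCMC chain, ...) uses a
#' sub-seed derived deterministically from the master seed, the stage name and
#' the wave index, so stages can be re-run independently and still reproduce.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label, e.g. `"cases"`.
#' @param wave Integer wave index (0 when not wave-specific).
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "cases", 1)
substream_seed <- function(seed, stage, wave = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.double(seed)) * 48271 + h * 100003 + wave * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
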