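# Shared helpers: seed streams, logging, validation.

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All randomness in the package flows from one integer master seed.  Each
#' consumer (chain 1, chain 2, truth surface, populations, counts, ...) draws
#' from its own named stream so that adding a consumer never perturbs the
#' draws of another.  The stream name is folded into a 31-bit integer with a
#' fixed polynomial hash and XOR-combined with the master seed.
#'
#' @param seed integer master seed.
#' @param stream character scalar naming the consumer, e.g. `"chain1"`.
#' @return an integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
#' @examples
#' split_seed(42, "truth") != split_seed(42, "counts")
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647                       # 2^31 - 1, Mersenne prime
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% m
  # golden-ratio scramble keeps nearby master seeds apart
  s <- (as.numeric(seed) %% m) * 2654435761 %% m
  as.integer((s + h * 40503 + 17) %% m)
}

#' @keywords internal
ar_log <- function(..., level = "INFO", quiet = getOption("arearisk.quiet", FALSE)) {
  if (isTRUE(quiet)) return(invisible(NULL))
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' @keywords internal
ar_warn <- function(...) warning(..., call. = FALSE)

#' @keywords internal
ar_stop <- function(...) stop(..., call. = FALSE)

# near-equality used for sum-to-zero pre-condition checks
#' @keywords internal
ar_near <- function(x, y, tol = 1e-8) abs(x - y) < tol
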