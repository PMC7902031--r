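#' @keywords internal
"_PACKAGE"

# Classed error helper so callers can distinguish argument misuse from
# degenerate physical states.
ls_stop <- function(msg, class, call. = FALSE, ...) {
  stop(structure(
    class = c(paste0("lungstretch_", class), "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL, ...)
  ))
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ls_stop(sprintf("`%s` must be a finite numeric scalar", name),
            "invalid_argument")
  }
  if (positive && x <= 0) {
    ls_stop(sprintf("`%s` must be > 0 (got %g)", name, x), "invalid_argument")
  }
  if (nonneg && x < 0) {
    ls_stop(sprintf("`%s` must be >= 0 (got %g)", name, x), "invalid_argument")
  }
  invisible(x)
}

#' Derive a reproducible substream seed from a global seed
#'
#' Each synthetic-data generator draws from its own substream so that adding
#' one generator call to a script does not perturb the random numbers any
#' other generator sees. The substream seed is a deterministic hash of the
#' global seed and a stream label, kept below 2^31.
#'
#' @param seed Integer global seed.
#' @param stream Character label of the stream (e.g. `"pressure"`).
#' @return An integer seed.
#' @export
#' @examples
#' substream_seed(1, "pressure")
substream_seed <- function(seed, stream) {
  stopifnot_scalar(seed, "seed")
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 9973) %% 2147483629L)
}
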