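#' Construct a Signal object
#'
#' A `sm_signal` is a mono sampled waveform together with its sample rate and
#' two opaque labels: an `id` identifying the recording and a `group`
#' identifying the subject (patient / speaker) it came from. The group label
#' drives grouped train/test splitting, where all recordings of one subject
#' must fall on the same side of the split.
#'
#' @param samples numeric vector of finite sample values (arbitrary amplitude
#'   units).
#' @param rate sample rate in samples/second, a single positive number.
#' @param id opaque recording identifier.
#' @param group opaque subject identifier (defaults to `id`).
#' @return An object of class `sm_signal` with fields `samples`, `rate`,
#'   `id`, `group`.
#' @examples
#' s <- sm_signal(sin(2 * pi * 50 * seq(0, 1, by = 1 / 4000)), rate = 4000)
#' length(s$samples)
#' @export
sm_signal <- function(samples, rate, id = "signal", group = id) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) {
    stop("signal samples must all be finite")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number")
  }
  structure(
    list(samples = samples, rate = rate,
         id = as.character(id), group = as.character(group)),
    class = "sm_signal"
  )
}

#' @export
print.sm_signal <- function(x, ...) {
  cat(sprintf("<sm_signal '%s' (group '%s'): %d samples @ %g Hz, %.3f s>\n",
              x$id, x$group, length(x$samples), x$rate,
              length(x$samples) / x$rate))
  invisible(x)
}

as_sm_signal <- function(x, rate = NULL) {
  if (inherits(x, "sm_signal")) return(x)
  if (is.null(rate)) stop("rate required when coercing a numeric vector")
  sm_signal(x, rate)
}
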