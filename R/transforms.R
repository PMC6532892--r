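#' Sign-preserving log normalisation of tonal onglides
#'
#' Speakers differ substantially in pitch range, which right-skews raw
#' onglide magnitudes in semitones. The normalisation
#' \deqn{z = \mathrm{sign}(y)\,\log(|y| + 1)}
#' compresses magnitudes while keeping the sign (falling vs. rising) and the
#' rank order, so fall/rise counts and rank-based medians are unchanged by
#' it. The constant 1 keeps the map continuous through zero; natural
#' logarithm.
#'
#' Exact zeros are rejected: a zero onglide is neither falling nor rising
#' and does not occur in validated data.
#'
#' @param y numeric vector of raw onglides in semitones (no zeros).
#' @return Normalised values, same length and signs as `y`.
#' @examples
#' signed_log(c(-3, 5.5))
#' signed_log_inverse(signed_log(5.5))
#' @export
signed_log <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("'y' must be finite numeric")
  if (any(y == 0))
    stop("onglide of exactly 0 is not allowed: ",
         "a zero onglide is neither falling nor rising ",
         "(values of 0 did not exist in the validated data)")
  sign(y) * log(abs(y) + 1)
}

#' @rdname signed_log
#' @param z numeric vector of normalised values.
#' @return `signed_log_inverse(z)` returns semitones:
#'   \eqn{\mathrm{sign}(z)(e^{|z|} - 1)}.
#' @export
signed_log_inverse <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("'z' must be finite numeric")
  sign(z) * (exp(abs(z)) - 1)
}
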