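#' Convert frequency in Hz to mels
#'
#' Uses the common formula `mel = 2595 * log10(1 + f/700)`, a logarithmic
#' perceptual frequency scale under which formant distances better reflect
#' perceptual sensitivity. The map is strictly increasing and fixes
#' `hz_to_mel(0) == 0`.
#'
#' @param f Numeric vector of frequencies in Hz; must be finite and >= 0.
#' @return Numeric vector of the same length, in mels.
#' @seealso [mel_to_hz()]
#' @examples
#' hz_to_mel(c(0, 700, 1000))
#' @export
hz_to_mel <- function(f) {
  if (!is.numeric(f)) stop("`f` must be numeric")
  if (any(!is.finite(f))) stop("`f` must be finite")
  if (any(f < 0)) stop("`f` must be >= 0 (got negative frequency)")
  2595 * log10(1 + f / 700)
}

#' Convert mels back to Hz
#'
#' Inverse of [hz_to_mel()].
#'
#' @param m Numeric vector in mels; finite and >= 0.
#' @return Numeric vector of frequencies in Hz.
#' @export
mel_to_hz <- function(m) {
  if (!is.numeric(m)) stop("`m` must be numeric")
  if (any(!is.finite(m))) stop("`m` must be finite")
  if (any(m < 0)) stop("`m` must be >= 0")
  700 * (10^(m / 2595) - 1)
}
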