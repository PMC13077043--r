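## pulse_field: excitation waveforms.

#' Instantaneous field magnitude of an excitation protocol
#'
#' For `rect_heaviside` protocols the ideal step is smoothed with a tanh
#' ramp of width `riseTime` (centered at onset and at `duration`), so the
#' waveform is C1-continuous for stiff integrators and carries the value
#' `E/2` at the nominal switching instants. For `sine` protocols the value
#' is `E * sin(2 pi f t)` inside the pulse window and 0 outside.
#'
#' @param t time (s), scalar or vector, `t >= 0`; the pulse starts at 0.
#' @param protocol a [PulseProtocol-class].
#' @return field magnitude(s), V/m.
#' @examples
#' p <- PulseProtocol(4e5, 2e-6)
#' pulseValue(1e-6, p)   # mid-pulse: ~4e5
#' pulseValue(3e-6, p)   # after the pulse: ~0
#' @export
pulseValue <- function(t, protocol) {
  E <- protocol@fieldStrength
  dur <- protocol@duration
  w <- protocol@riseTime / 2          # tanh half-width: ~ full rise over riseTime
  ramp <- 0.5 * (tanh(t / w) - tanh((t - dur) / w))
  env <- E * ramp
  env[t < -5 * protocol@riseTime] <- 0
  if (protocol@waveform == "sine") {
    env <- env * sin(2 * pi * protocol@frequency * t)
  }
  env
}
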