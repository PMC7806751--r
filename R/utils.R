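# Half-up rounding (reporting convention; base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Round to the nearest multiple of `quantum`, half away from zero.
round_to_quantum <- function(x, quantum) {
  if (!is.numeric(quantum) || quantum <= 0)
    stop("rounding quantum must be positive", call. = FALSE)
  sign(x) * floor(abs(x) / quantum + 0.5) * quantum
}
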