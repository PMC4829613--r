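# round-half-up (R's round() rounds half to even); latent ratings use this
roundHalfUp <- function(x) floor(x + 0.5)

.clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# samples per segment implied by a config
.segmentLength <- function(config) {
  as.integer(round(config@sampling_rate * config@epoch_halfwidth))
}
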