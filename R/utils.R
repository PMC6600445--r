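# Deterministic seed substreams -------------------------------------------
#
# One master seed spawns an independent, reproducible substream per element
# (or per any label), so adding an element to a simulation never perturbs the
# draws of another. The derivation is a plain polynomial string hash folded
# into the master seed modulo the largest 32-bit prime, all in exact double
# arithmetic (< 2^53), so it is identical on every platform.

MERSENNE31 <- 2147483647

hash_label <- function(label) {
  h <- 0
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% MERSENNE31
  }
  h
}

substream_seed <- function(seed, label) {
  seed <- as.double(seed) %% MERSENNE31
  (seed * 48271 + hash_label(label) + 1) %% MERSENNE31
}

with_substream <- function(seed, label, code) {
  withr::with_seed(as.integer(substream_seed(seed, label)), code)
}

# misc ---------------------------------------------------------------------

fraction_labels <- function() paste0("F", 1:5)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}
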