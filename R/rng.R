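# Internal deterministic random streams for the sequence generator.
#
# The generator must be reproducible independently of the caller's global RNG
# state and safe to evaluate per-sequence in any order, so it uses a MINSTD
# linear congruential generator (Park-Miller, modulus 2^31 - 1) with one
# stream per (seed, label) pair. All arithmetic stays below 2^53 and is exact
# in doubles.

LCG_M <- 2147483647

lcg_state <- function(seed) {
  s <- as.numeric(seed) %% LCG_M
  if (s <= 0) s <- s + LCG_M - 1
  if (s == 0) s <- 1
  s
}

lcg_next <- function(state) (16807 * state) %% LCG_M

# n uniforms in (0,1) from a fresh stream
lcg_runif <- function(n, seed) {
  s <- lcg_state(seed)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- lcg_next(s)
    out[i] <- s / LCG_M
  }
  out
}

# integers in 1..k
lcg_sample <- function(n, k, seed) {
  pmin(floor(lcg_runif(n, seed) * k) + 1L, k)
}

# Deterministic numeric salt for a text label, for deriving sub-stream seeds.
salt_hash <- function(label) {
  codes <- utf8ToInt(label)
  h <- 17
  for (c in codes) h <- (h * 131 + c) %% (LCG_M - 1)
  h + 1
}

# Per-sequence sub-seed: mix a top-level seed with a counter/label.
mix_seed <- function(seed, label) {
  if (is.character(label)) label <- salt_hash(label)
  (lcg_state(seed) * 48271 + as.numeric(label) * 69621 + 1) %% LCG_M
}

# Random DNA of length n (used for gene-specific flanking sequence).
lcg_dna <- function(n, seed) {
  paste(c("A", "C", "G", "T")[lcg_sample(n, 4L, seed)], collapse = "")
}
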