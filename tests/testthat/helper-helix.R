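# Shared fixtures.  The low KDF iteration count is an evaluation-harness
# setting: key-stretching hardness has no bearing on any measured quantity.
fast_cfg <- function(...) helix_config(kdf_iterations = 1000L, ...)

rand_raw <- function(n) as.raw(sample.int(256L, n, replace = TRUE) - 1L)

with_seed_local <- helixcrypt:::with_seed

rand_seq <- function(n, alphabet = "DNA") {
  helixcrypt:::ints_to_seq(sample(0:3, n, replace = TRUE), alphabet)
}

raw_hex <- function(r) paste(format(r), collapse = "")

# reverse complement over the canonical integer coding
rev_comp <- function(seq) {
  ints <- rev(3L - helixcrypt:::seq_ints(seq))
  helixcrypt:::ints_to_seq(ints, attr(seq, "alphabet"))
}

# raw codeword-level RS encode (parity only), for the frozen oracle fixtures
rs_parity <- function(data, nsym) {
  .Call(getNativeSymbolInfo("C_rs_encode", "helixcrypt"), data, as.integer(nsym))
}
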