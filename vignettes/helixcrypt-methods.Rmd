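---
title: "helixcrypt: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{helixcrypt: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixcrypt)
```

## The problem

DNA data storage and bio-inspired cryptography meet in one pipeline: encrypt
arbitrary binary data into a nucleotide sequence that (a) decrypts exactly
with the key, (b) looks statistically random to anyone without it, (c) obeys
the biochemical constraints a synthesis provider would impose, and (d)
survives the substitution noise of synthesis and sequencing.  helixcrypt
implements that pipeline over the 4-letter alphabet, treating each base as a
2-bit symbol, together with the simulation and evaluation harness needed to
measure it.

## The cipher

Let $m$ be the plaintext bit string.  Encryption is a composition of six
invertible layers:

1. **Dynamic encoding.** Bit pairs map to bases through one of the $4! = 24$
   bijections $\{00,01,10,11\} \to \{A,T,C,G\}$.  The table in force is
   $\mathrm{SHA\text{-}256}(K) \bmod 24$, where $K$ is the 512-bit master
   key, so even the very first symbol mapping is secret.  Table 0 is the
   classical $00{\to}A,\ 01{\to}T,\ 10{\to}C,\ 11{\to}G$ assignment.
2. **Complementation.** The Watson–Crick involution $A \leftrightarrow T$,
   $C \leftrightarrow G$.
3. **DNA one-time pad.** Each base's 2-bit value is XORed with a keystream
   symbol.  The keystream is HMAC-SHA256 in counter mode,
   $\mathrm{block}_i = \mathrm{HMAC}_K(\mathrm{nonce} \,\|\, i)$, a
   deterministic PRF so that every encryption is replayable and distinct
   nonces give independent pads.
4. **Chaotic permutation.** The logistic map $x_{n+1} = r x_n (1 - x_n)$,
   $r = 3.99$, is iterated from a key-derived $x_0$ (first 8 bytes of
   $\mathrm{SHA\text{-}256}(K \,\|\, \texttt{"perm"})$ scaled to $(0,1)$ and
   clamped to $[2^{-20}, 1 - 2^{-20}]$), with a burn-in of 1000 iterates to
   escape transients.  The payload is gathered by the ranking permutation of
   the next $n$ iterates (stable ties).  Only the *ranking* of the chaotic
   values matters, which is robust to last-ulp floating-point differences at
   the payload sizes used here; the ciphertext header carries a format
   version so a cross-platform mismatch would be detectable rather than
   silent.
5. **Transcription.** $T \to U$, then two chained keyed substitution passes
   (below).
6. **Optional outer code and constrained modulation** (next sections).

Decryption inverts the layers in reverse order using the same passphrase and
the public header (salt, nonce, KDF iterations, bit length, code
parameters).  There is deliberately no authentication tag: a wrong
passphrase produces uniform noise, or an explicit Reed–Solomon failure when
the outer code is enabled.

### Key schedule

The passphrase is stretched by PBKDF2-HMAC-SHA256 with a 16-byte public salt
to a 64-byte master key (default 600,000 iterations).  512 key bits are 256
nucleotide-equivalents at 2 bits/base, which is what the key-space
accounting reports; the 24 encoding tables ($\log_2 24 \approx 4.58$ bits)
and the stream nonce are *derived* from the master key and are therefore
reported as structure, never multiplied into the key space.  Domain
separation between the chaotic seed, the keystream, and the substitution
boxes uses distinct HMAC/SHA-256 labels (`"perm"`, `"sbox-*"`); these labels
are part of the format.

### The chained substitution layer and the avalanche requirement

A strict avalanche criterion — half the ciphertext bits flip when one
plaintext bit changes — cannot be met by any memoryless per-symbol
substitution: layers 1–4 move and mask a single changed base but leave it a
single changed base.  Diffusion must come from chaining.

The design constraint is sharp.  If the substitution at position $i$ is
selected only by the *previous symbol* (a 4-state chain), a difference
between two encryptions survives each step with probability about $3/4$, so
changes die out geometrically after ~4 bases and the measured avalanche is
under 1%.  helixcrypt instead selects the box by a keyed hash of the
preceding **12-nucleotide window** of the pass's own output: three keyed
256-entry byte tables are XOR-combined over the 24-bit window register and
reduced to a 2-bit context class $c$, and the symbol is substituted by the
coset box $B_c(x) = S(x) \oplus c$ with $S$ a keyed bijection of the
alphabet.  Two consequences:

* a difference now dies only if twelve consecutive output symbols coincide,
  probability $(1/4)^{12} \approx 6 \times 10^{-8}$ per position —
  negligible at any realistic payload length; and
* because the four boxes are cosets of one bijection, two different
  contexts *always* disagree about the output unless the context class
  itself coincides (probability $1/4$), so each downstream symbol differs
  with probability exactly $3/4$, the uniform-re-randomization value.

One pass diffuses only downstream, so a second pass runs in the opposite
direction; a single flipped plaintext bit then re-randomizes the whole
payload.  The analytic expectations are $3/4$ changed nucleotides and $1/2$
changed bits (a changed 2-bit symbol is uniform over the three other values:
expected bit distance $\frac{1}{3}(1+1+2) = 4/3$ per changed symbol,
$\frac{3}{4} \cdot \frac{4}{3} \cdot \frac{1}{2} = \frac{1}{2}$ per bit).
`avalanche()` measures both; 1000 trials on 1 KB messages land within a few
tenths of a percent of these values.  Because each pass reads its context
from its own output, inversion is local: a corrupted ciphertext base
perturbs at most 12 neighbours per pass on decryption, which matters for the
error-correction layer below.

The identity family (`identity_sboxes()`) zeroes all context material, under
which the layer is exactly the textbook $T \to U$ transcription rule — this
anchors the printed worked examples.

## Reed–Solomon outer code

`rs_encode()`/`rs_decode()` implement a systematic RS code over
$GF(2^8)$ (primitive polynomial 0x11d, $\alpha = 2$), Berlekamp–Massey +
Chien + Forney decoding, standard shortening for the final block, and
column-major interleaving in groups of `interleave_depth` codewords.

**Placement.** The code wraps the *ciphertext* (it is applied to the packed
payload bytes after all cipher layers, and stripped first on decryption).
The alternative — coding the plaintext before encryption — is incompatible
with a diffusing cipher: by design, decryption amplifies any residual
channel error across the whole message, so an inner code would face a
near-100% symbol error rate.  Coding outermost, each base carries 2 bits and
each byte 4 bases, so a per-base substitution rate $e$ induces a per-byte
symbol error rate $1 - (1-e)^4$ — about 28.4% at $e = 8\%$.  The default
heavy-parity profile RS(255, 51) corrects $t = 102$ of 255 bytes (40%) per
codeword, leaving a comfortable margin at 8% and explaining the measured
all-trials-recover behaviour through 8–9% substitution rates.  RS(255, 223)
is available for archival-grade channels (0.5–2%).

Insertions and deletions break the fixed-length framing and are out of the
code's scope (no synchronization/watermark layer); the channel simulator
still produces them so the failure mode is observable.

## Biochemical constraints

`constraint_limits()` encodes the synthesis screen: GC in $[45\%, 55\%]$
globally **and** over every sliding 100-base window, homopolymer runs
$\le 3$, and zero hairpin stems — reverse-complement matches of at least
`stem_min` bases separated by at least 3 bases within a window.

**Why enforcement cannot be rejection alone.**  For a uniform random
sequence of length $n$, $P(\text{max run} \le 3) \approx e^{-3n/256}$ —
about $10^{-21}$ at $n = 4096$.  No nonce-rerandomization loop can buy that
back, so compliance at kilobase scale has to be structural.
`enforce_constraints()` therefore re-encodes the payload through a
**constrained modulation**: each byte maps to one of 256 six-base codewords
(the first 256 six-mers in lexicographic order with GC exactly 3/6, no run
longer than 3, and distinct first and last base pairs — 832 qualify).  Any
concatenation of codewords then has max run 3, global GC of exactly 50%, and
every window within about 2 bases of 50% GC, all by construction, at a 33%
base overhead (1.33 vs 2 bits/base).  One channel substitution still
corrupts only one codeword, i.e. one byte of the outer code.

Only the hairpin screen remains statistical, and the stem threshold decides
whether it is satisfiable at all.  At `stem_min = 6` a random kilobase
sequence carries ~100 expected stem hits, so "zero hairpins" would exclude
essentially every sequence; screening that short a stem is also not
synthesis practice.  The default is `stem_min = 11` (typical
inverted-repeat QC length), giving ~0.1 expected hits per kilobase payload;
`enforce_constraints()` clears residual hits by re-encrypting under
successive stream nonces (mean ≈ 1.1 attempts), records the successful
nonce in the header, and reports the best attempt's violations if the
budget (`max_attempts = 1000`) is ever exhausted.  The hairpin count is a
reverse-complement proxy; a nearest-neighbour $\Delta G$ model would slot
behind the same `hairpin_screen()` interface but is out of scope.

## Channel model

`corrupt()` applies independent per-base events — deletion, substitution
(uniform over the three other bases), then insertion after each position —
under an explicit seed, so every resilience experiment is replayable.  No
burst model is fitted: published error characterizations at this level quote
aggregate rates, and the interleaver already covers bursts on the
correction side.  Platform-specific profiles (e.g. nanopore homopolymer
bias) are out of scope.

## Evaluation suite

* **Entropy**: plug-in Shannon entropy of the empirical base frequencies
  (no small-sample bias correction — the evaluation protocol it mirrors
  uses none).  Uniformly random 1 KB plaintexts encrypt to ≈ 1.9995
  bits/base on average (maximum 2).
* **Avalanche**: both bit-level and nucleotide-level change fractions are
  reported, since the two are often conflated; the analytic full-diffusion
  values are 1/2 and 3/4.
* **SP 800-22 subset**: monobit frequency, runs, and DFT tests, with the
  standard 95% spectral threshold $T = \sqrt{n \ln(1/0.05)}$.  For
  multi-stream judgements the two-level convention applies: with $m$
  streams at $\alpha = 0.01$ the acceptable pass proportion is
  $0.99 \pm 3\sqrt{0.0099/m}$ (at $m = 10$: at least 9 of 10 per test).
  Demanding all 30 p-values above 0.01 simultaneously would reject a
  quarter of truly random keystreams.
* **Key space**: reported from the KDF output size, with derived structure
  (table choice, nonce) listed separately.

## Harness settings

The shipped tests and `scripts/acceptance.R` run the protocol at these
sizes: 1000 random messages of 128–192 bits plus 50 messages of 1 KB for
round-trip accuracy; 50 ciphertexts of 1 KB for entropy; 50 messages of 512
bytes swept over 1–10% substitution rates for resilience; 100 enforced
ciphertexts (50 at ~50 bytes, 50 at 1 KB) for the constraint profile; 1000
trials of 1 KB for avalanche.  The harness derives keys with
`kdf_iterations = 1000`: the iteration count is a brute-force work factor
with no influence on any measured statistic, and the 600,000-iteration
default remains the production setting.

## What the synthetic corpus does and does not show

All plaintexts are uniformly random bit strings (plus the literal benchmark
string `"CRYPTO"`).  That is the right null for measuring ciphertext
randomness — any structure in the output must then come from the cipher —
and round-trip exactness is input-distribution-free because every layer is
a bijection.  It does *not* exercise compressible or adversarially chosen
plaintexts (irrelevant to correctness, relevant to traffic analysis of
lengths, which the scheme does not hide), real synthesis chemistry, or
platform-specific error profiles; the channel is a simulation and the
biochemical screen is a proxy, so passing tests show coding-theoretic
robustness, not wet-lab validation.

## Known limitations

* No authentication or integrity tag (an attacker can malleate
  ciphertexts); no key exchange; no constant-time guarantees beyond
  avoiding data-dependent branching in table lookups.
* Indels are simulated but not corrected.
* The hairpin screen is combinatorial, not thermodynamic.
* Payload length (hence plaintext length) is visible in the header.
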