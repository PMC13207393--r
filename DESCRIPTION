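Package: helixcrypt
Title: Multi-Layer DNA/RNA-Alphabet Encryption with Storage-Channel Error Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reversible multi-layer encryption of arbitrary binary data into
    nucleotide sequences over the DNA/RNA alphabets, in the style of
    bio-inspired cryptographic schemes for DNA data storage. A passphrase is
    stretched to a 512-bit master key (PBKDF2-HMAC-SHA256) that drives a
    key-selected binary-to-base encoding table, Watson-Crick complementation,
    a one-time-pad XOR with an HMAC counter-mode keystream, a chaotic
    logistic-map permutation, and a transcription-inspired keyed substitution
    layer producing RNA ciphertext. A Reed-Solomon outer code over GF(2^8)
    protects payloads against simulated synthesis/sequencing substitution,
    insertion and deletion errors; a constrained-modulation layer enforces
    biochemical sequence constraints (GC balance, homopolymer cap, hairpin
    screen). Includes a security-evaluation suite (Shannon entropy, avalanche
    statistics, an SP 800-22 subset, key-space accounting), FASTA/JSON
    serialization and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
SystemRequirements: OpenSSL (libcrypto)
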