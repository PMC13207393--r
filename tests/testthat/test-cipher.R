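test_that("complement matches the printed rows and is an involution", {
  expect_identical(as.character(complement(nuc_seq("TAAG"))), "ATTC")
  expect_identical(as.character(complement(nuc_seq("TTAA"))), "AATT")
  expect_identical(as.character(complement(nuc_seq("TAGG"))), "ATCC")
  set.seed(2)
  for (i in 1:20) {
    s <- rand_seq(sample(0:50, 1L))
    expect_identical(as.character(complement(complement(s))), as.character(s))
  }
  expect_error(complement(nuc_seq("ACGU", "RNA")), "DNA")
})

test_that("dna_xor is a keyed involution with the hand-worked fixture", {
  t0 <- encoding_table(0)
  s <- nuc_seq("TAAG")
  expect_identical(as.character(dna_xor(s, rep(0L, 4L), t0)), "TAAG")
  # TAAG = 01 00 00 11; xor (11,11,11,11) = 10 11 11 00 -> CGGA
  expect_identical(as.character(dna_xor(s, rep(3L, 4L), t0)), "CGGA")
  set.seed(3)
  for (i in 1:20) {
    n <- sample(1:100, 1L)
    s <- rand_seq(n)
    k <- sample(0:3, n, replace = TRUE)
    tab <- encoding_table(sample(0:23, 1L))
    expect_identical(as.character(dna_xor(dna_xor(s, k, tab), k, tab)),
                     as.character(s))
  }
  expect_error(dna_xor(nuc_seq("ACGT"), c(1L, 2L), t0), "length")
})

test_that("gather permutation matches the self-consistent printed rows", {
  expect_identical(as.character(apply_permutation(nuc_seq("AATT"), c(4, 1, 3, 2))),
                   "TATA")
  expect_identical(as.character(apply_permutation(nuc_seq("ATCC"), c(2, 3, 4, 1))),
                   "TCCA")
  s <- rand_seq(9)
  expect_identical(as.character(apply_permutation(s, 1:9)), as.character(s))
  expect_error(apply_permutation(s, c(1:8, 8)), "permutation")
  expect_error(apply_permutation(s, 1:5), "length")
})

test_that("transcription is T->U under identity boxes and invertible under keyed boxes", {
  expect_identical(as.character(transcribe(nuc_seq("TTAA"), identity_sboxes())),
                   "UUAA")
  expect_identical(as.character(untranscribe(nuc_seq("UUAA", "RNA"),
                                             identity_sboxes())), "TTAA")
  key <- derive_master_key("boxes", raw(16), 1000L)
  f <- sbox_family(key)
  set.seed(4)
  for (i in 1:25) {
    s <- rand_seq(sample(0:200, 1L))
    expect_identical(as.character(untranscribe(transcribe(s, f), f)),
                     as.character(s))
    r <- rand_seq(sample(1:100, 1L), "RNA")
    expect_identical(as.character(transcribe(untranscribe(r, f), f)),
                     as.character(r))
  }
  expect_error(transcribe(nuc_seq("ACGU", "RNA"), f), "DNA")
  expect_error(untranscribe(nuc_seq("ACGT"), f), "RNA")
})

test_that("each coset box family member is a bijection derived from the key", {
  key <- derive_master_key("boxes2", raw(16), 1000L)
  f <- sbox_family(key)
  for (dir in f) {
    expect_setequal(dir$sbox, 0:3)
    for (ctx in 0:3)
      expect_setequal(bitwXor(dir$sbox, ctx), 0:3)
  }
  expect_identical(sbox_family(key), f)
})

test_that("encrypt/decrypt round-trips bytes, bit strings, and the empty message", {
  cfg <- fast_cfg()
  set.seed(5)
  for (i in 1:20) {
    msg <- rand_raw(sample(1:200, 1L))
    ct <- encrypt(msg, "pw", cfg)
    expect_identical(attr(ct$payload, "alphabet"), "RNA")
    expect_lte(ct$plaintext_bit_length, 2L * seq_length(ct$payload))
    expect_identical(as.raw(decrypt(ct, "pw")), msg)
  }
  # non-byte bit lengths (odd base count exercises the pad rule)
  for (nb in c(1L, 7L, 129L, 191L)) {
    nbytes <- ceiling(nb / 8)
    msg <- raw(nbytes)
    ct <- encrypt(msg, "pw", cfg, nbits = nb)
    out <- decrypt(ct, "pw")
    expect_identical(as.raw(out), msg)
    expect_identical(attr(out, "nbits"), nb)
  }
  ct0 <- encrypt(raw(0), "pw", cfg)
  expect_identical(seq_length(ct0$payload), 0L)
  expect_identical(as.raw(decrypt(ct0, "pw")), raw(0))
})

test_that("the CRYPTO benchmark encodes to 24 bases before any outer code", {
  ct <- encrypt("CRYPTO", "pw", fast_cfg())
  expect_identical(seq_length(ct$payload), 24L)
  expect_identical(rawToChar(decrypt(ct, "pw")), "CRYPTO")
})

test_that("tampered framing fails loudly, wrong passphrase yields noise", {
  cfg <- fast_cfg()
  msg <- rand_raw(64)
  ct <- encrypt(msg, "pw", cfg)
  ct_trunc <- ct
  ct_trunc$payload <- nuc_seq(substr(as.character(ct$payload), 1, 100), "RNA")
  expect_error(decrypt(ct_trunc, "pw"), class = "helixcrypt_format_error")
  expect_false(identical(as.raw(decrypt(ct, "wrong")), msg))
  bad <- ct; bad$version <- "helixcrypt-999"
  expect_error(decrypt(bad, "pw"), "version")
})

test_that("round-trip holds at large message sizes", {
  msg <- rand_raw(65536)
  ct <- encrypt(msg, "pw", fast_cfg())
  expect_identical(seq_length(ct$payload), 4L * 65536L)
  expect_identical(as.raw(decrypt(ct, "pw")), msg)
})

test_that("round-trip holds with the Reed-Solomon outer code enabled", {
  cfg <- fast_cfg(use_ecc = TRUE, ecc = code_config(255, 51, 8))
  set.seed(6)
  for (nbytes in c(1L, 50L, 512L)) {
    msg <- rand_raw(nbytes)
    ct <- encrypt(msg, "pw", cfg)
    expect_identical(ct$ecc, list(n = 255L, k = 51L, interleave = 8L))
    expect_identical(as.raw(decrypt(ct, "pw")), msg)
  }
})
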