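test_that("GC content and homopolymer measurements match direct counts", {
  expect_identical(gc_content(nuc_seq("ACGT")), 0.5)
  expect_identical(gc_content(nuc_seq("TAAG")), 0.25)
  expect_identical(gc_content(nuc_seq("GGCC")), 1.0)
  expect_error(gc_content(nuc_seq("")), class = "helixcrypt_input_error")

  expect_identical(max_homopolymer(nuc_seq("AAAT")), 3L)
  expect_identical(max_homopolymer(nuc_seq("ACGU", "RNA")), 1L)
  expect_identical(max_homopolymer(nuc_seq("AAAGA")), 3L)
  expect_identical(max_homopolymer(nuc_seq("")), 0L)
})

test_that("hairpin screen finds planted stems and respects reverse-complement symmetry", {
  lim6 <- constraint_limits(stem_min = 6L, loop_min = 3L)
  expect_identical(hairpin_screen(nuc_seq(strrep("A", 12)), lim6), 0)
  # GCGCGC is its own reverse complement: planted stem with a 3-base loop
  planted <- nuc_seq("GCGCGCAAAGCGCGC")
  expect_gte(hairpin_screen(planted, lim6), 1)
  # brute-force oracle on the planted 15-mer
  brute <- 0L
  x <- helixcrypt:::seq_ints(planted)
  for (i in 1:(15 - 6 + 1)) for (j in 1:(15 - 6 + 1)) {
    if (j >= i + 6 + 3 && all(x[i:(i + 5)] == 3 - rev(x[j:(j + 5)])))
      brute <- brute + 1L
  }
  expect_identical(as.integer(hairpin_screen(planted, lim6)), brute)

  set.seed(41)
  for (rep in 1:10) {
    s <- rand_seq(300, "DNA")
    expect_identical(hairpin_screen(s, lim6), hairpin_screen(rev_comp(s), lim6))
  }
})

test_that("the modulation codebook is structurally constraint-safe and lossless", {
  cb <- helixcrypt:::modulation_codebook()
  expect_length(unique(cb$code), 256L)
  d <- sapply(5:0, function(s) (cb$code %/% 4L^s) %% 4L)
  expect_true(all(rowSums(d == 1L | d == 2L) == 3L))          # GC exactly 3/6
  expect_true(all(apply(d, 1, function(v) max(rle(v)$lengths)) <= 3L))
  expect_true(all(d[, 1] != d[, 2] & d[, 5] != d[, 6]))       # safe ends
  set.seed(42)
  for (rep in 1:10) {
    b <- rand_raw(sample(1:300, 1))
    expect_identical(helixcrypt:::demodulate_payload(
      helixcrypt:::modulate_payload(b)), b)
  }
  expect_error(helixcrypt:::demodulate_payload(nuc_seq("ACGU", "RNA")),
               class = "helixcrypt_format_error")
})

test_that("enforced ciphertexts satisfy every constraint and stay decryptable", {
  cfg <- fast_cfg()
  lim <- constraint_limits()
  set.seed(43)
  for (nbytes in c(25L, 50L, 300L)) {
    msg <- rand_raw(nbytes)
    ct <- enforce_constraints(encrypt(msg, "pw", cfg), "pw", lim, cfg)
    res <- check_constraints(ct$payload, lim)
    expect_true(res$ok)
    expect_gte(res$gc, lim$gc_min)
    expect_lte(res$gc, lim$gc_max)
    expect_lte(res$max_run, lim$max_homopolymer)
    expect_identical(res$hairpin_hits, 0)
    expect_identical(as.raw(decrypt(ct, "pw")), msg)
  }
})

test_that("an already compliant ciphertext keeps its nonce; impossible limits fail loudly", {
  cfg <- fast_cfg()
  msg <- rand_raw(40)
  ct <- encrypt(msg, "pw", cfg)
  enforced <- enforce_constraints(ct, "pw", constraint_limits(), cfg)
  # the constrained re-encoding of nonce 0 is almost always already compliant
  expect_lte(enforced$stream_nonce, 3L)
  expect_error(
    enforce_constraints(ct, "pw",
                        constraint_limits(gc_min = 0.98, gc_max = 0.99,
                                          max_attempts = 5L), cfg),
    class = "helixcrypt_constraint_error")
})

test_that("constraint limits validate their invariants", {
  expect_error(constraint_limits(gc_min = 0.6, gc_max = 0.5),
               class = "helixcrypt_config_error")
  expect_error(constraint_limits(max_homopolymer = 0),
               class = "helixcrypt_config_error")
})
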