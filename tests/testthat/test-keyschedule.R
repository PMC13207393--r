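test_that("PBKDF2 key derivation is deterministic, salt-separated, and matches the reference value", {
  salt <- raw(16)
  k1 <- derive_master_key("CRYPTO-test", salt, 1000L)
  k2 <- derive_master_key("CRYPTO-test", salt, 1000L)
  expect_identical(k1$master_key, k2$master_key)
  expect_length(k1$master_key, 64L)
  expect_identical(k1$stream_nonce, 0L)

  salt2 <- as.raw(c(1L, rep(0L, 15L)))
  expect_false(identical(k1$master_key,
                         derive_master_key("CRYPTO-test", salt2, 1000L)$master_key))

  # frozen values from an independent PBKDF2/SHA-256 reference implementation
  expect_identical(
    raw_hex(k1$master_key),
    paste0("3fd85030b4e47fdab65233d0402f7f2ea0ea4b9ac36bfd5cfd9b9797f2b2247b",
           "ad3c726d6ab08bdb21597a53ac7a6625073e9d212d39d55afffe078fd8f587e4"))
  expect_identical(k1$table_index, 18L)
  # table index is recomputable from the master key alone
  expect_identical(helixcrypt:::table_index_from_key(k1$master_key), 18L)

  expect_error(derive_master_key("", salt, 1000L), "non-empty")
  expect_error(derive_master_key("x", salt, 0L), "positive")
  expect_error(derive_master_key("x", raw(8), 10L), "16 raw bytes")
})

test_that("HMAC-SHA256 primitive matches RFC 4231 test case 2", {
  out <- helixcrypt:::hmac_sha256(charToRaw("Jefe"),
                                  charToRaw("what do ya want for nothing?"))
  expect_identical(
    raw_hex(out),
    "5bdcc146bf60754e6a042426089575c75a003f089d2739839dec58b964ec3843")
})

test_that("keystream is a counter-mode PRF: prefix-consistent, nonce-separated, near-uniform", {
  key <- derive_master_key("stream", raw(16), 1000L)
  s10 <- keystream(key, 0L, 10L)
  s20 <- keystream(key, 0L, 20L)
  expect_identical(s10, s20[1:10])

  expect_false(identical(keystream(key, 0L, 128L), keystream(key, 1L, 128L)))
  expect_error(keystream(key, 0L, 0L), "positive")

  s <- keystream(key, 2L, 1e5L)
  freqs <- tabulate(s + 1L, 4L) / 1e5
  expect_true(all(abs(freqs - 0.25) < 0.01))
  expect_gt(stats::chisq.test(tabulate(s + 1L, 4L))$p.value, 0.001)
})

test_that("logistic map matches high-precision iterates and stays in (0,1)", {
  p <- logistic_params(x0 = 0.5, burn_in = 0L)
  x <- logistic_sequence(p, 3L)
  # frozen 60-digit-arithmetic reference values, >= 10 significant digits
  expect_equal(x[1], 0.9975, tolerance = 1e-12)
  expect_equal(x[2], 0.0099500625, tolerance = 1e-12)
  expect_equal(x[3], 0.039305724437421914, tolerance = 1e-12)

  for (x0 in c(0.123, 0.5, 0.987)) {
    v <- logistic_sequence(logistic_params(x0 = x0, burn_in = 100L), 500L)
    expect_true(all(v > 0 & v < 1))
  }
  expect_error(logistic_params(x0 = 0), "strictly")
  expect_error(logistic_params(x0 = 1.2), "strictly")
  expect_error(logistic_params(r = 2), "3.57")
})

test_that("chaotic permutation is a stable ranking, bijective, key-sensitive, invertible", {
  # ranking fixture: values (0.3, 0.1, 0.9, 0.5) -> gather permutation (2,1,4,3)
  expect_identical(order(c(0.3, 0.1, 0.9, 0.5)), c(2L, 1L, 4L, 3L))

  key <- derive_master_key("perm-key", raw(16), 1000L)
  for (n in c(1L, 8L, 97L, 1000L)) {
    p <- permutation_from_chaos(key, n)
    expect_identical(sort(p), seq_len(n))          # bijection on 1..n
    expect_identical(p, permutation_from_chaos(key, n))  # deterministic
    # composition with brute-force inverse is the identity
    pinv <- match(seq_len(n), p)
    expect_identical(p[pinv], seq_len(n))
    s <- rand_seq(n)
    expect_identical(as.character(invert_permutation(apply_permutation(s, p), p)),
                     as.character(s))
  }
  key2 <- key
  key2$master_key[1] <- as.raw(bitwXor(as.integer(key2$master_key[1]), 1L))
  expect_false(identical(permutation_from_chaos(key, 64L),
                         permutation_from_chaos(key2, 64L)))
})

test_that("x0 is key-derived and clamped inside (0,1)", {
  key <- derive_master_key("any", raw(16), 1000L)
  x0 <- helixcrypt:::chaos_x0(key)
  expect_true(x0 >= 2^-20 && x0 <= 1 - 2^-20)
  expect_identical(x0, helixcrypt:::chaos_x0(key))
})
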