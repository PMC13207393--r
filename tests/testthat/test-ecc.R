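test_that("encoder parity matches the independent reference fixtures", {
  # frozen from a textbook GF(2^8) encoder (prim 0x11d, alpha = 2, fcr = 0)
  expect_identical(raw_hex(rs_parity(as.raw(0:10), 4L)), "c08f286c")
  expect_identical(
    raw_hex(rs_parity(as.raw(0:222), 32L)),
    "41841183b11fdb537421939696cda70e1db5c86684af222564b89cc6069f172e")
})

test_that("codewords have zero syndromes under independent GF arithmetic", {
  # independent R implementation of GF(2^8) evaluation (russian-peasant
  # multiply, no shared tables with the C codec)
  gmul <- function(a, b) {
    p <- 0L
    while (b > 0L) {
      if (bitwAnd(b, 1L)) p <- bitwXor(p, a)
      a <- bitwShiftL(a, 1L)
      if (bitwAnd(a, 256L)) a <- bitwXor(a, 285L)  # 0x11d
      b <- bitwShiftR(b, 1L)
    }
    p
  }
  gpow <- function(e) { x <- 1L; for (i in seq_len(e)) x <- gmul(x, 2L); x }
  peval <- function(cw, xv) { y <- 0L; for (c in cw) y <- bitwXor(gmul(y, xv), c); y }
  set.seed(21)
  msg <- sample(0:255, 11)
  cw <- c(msg, as.integer(rs_parity(as.raw(msg), 4L)))
  for (i in 0:3) expect_identical(peval(cw, gpow(i)), 0L)
})

test_that("decoder corrects up to t random errors and flags overload", {
  set.seed(22)
  cfg <- code_config(255, 223, 1)
  expect_identical(cfg$t, 16L)
  d <- rand_raw(223)
  cw <- rs_encode(d, cfg)
  expect_identical(rs_decode(cw, cfg), d)      # clean identity
  for (ne in c(1L, 8L, 16L)) {
    cwe <- cw
    pos <- sample(255, ne)
    cwe[pos] <- as.raw(bitwXor(as.integer(cwe[pos]),
                               sample(1:255, ne, replace = TRUE)))
    expect_identical(rs_decode(cwe, cfg), d)
  }
  # beyond capacity: either flagged or (rarely) miscorrected, never silently right
  cwe <- cw
  pos <- sample(255, 60)
  cwe[pos] <- as.raw(bitwXor(as.integer(cwe[pos]), sample(1:255, 60, TRUE)))
  res <- tryCatch(rs_decode(cwe, cfg), helixcrypt_decode_error = function(e) e)
  expect_true(inherits(res, "helixcrypt_decode_error") || !identical(res, d))
})

test_that("shortening and interleaving frame arbitrary lengths losslessly", {
  set.seed(23)
  cfg <- code_config(255, 51, 8)
  for (len in c(1L, 50L, 51L, 512L, 1024L)) {
    d <- rand_raw(len)
    coded <- rs_encode(d, cfg)
    expect_identical(length(coded), helixcrypt:::rs_coded_length(len, cfg))
    expect_identical(rs_decode(coded, cfg), d)
  }
  expect_identical(rs_encode(raw(0), cfg), raw(0))
  expect_identical(rs_decode(raw(0), cfg), raw(0))
})

test_that("interleaving spreads bursts of depth*t bytes across codewords", {
  set.seed(24)
  cfg <- code_config(255, 223, 8)   # t = 16, burst capacity 128
  d <- rand_raw(8L * 223L)
  coded <- rs_encode(d, cfg)
  start <- 301L
  idx <- start:(start + 8L * 16L - 1L)
  coded[idx] <- as.raw(bitwXor(as.integer(coded[idx]),
                               sample(1:255, length(idx), TRUE)))
  expect_identical(rs_decode(coded, cfg), d)
})

test_that("heavy-parity profile survives the byte-error rate of an 8% base channel", {
  # per-byte symbol error rate 1 - (1 - 0.08)^4 = 0.2836
  set.seed(25)
  cfg <- code_config(255, 51, 1)
  for (rep in 1:20) {
    d <- rand_raw(512)
    coded <- rs_encode(d, cfg)
    hit <- stats::runif(length(coded)) < 1 - (1 - 0.08)^4
    coded[hit] <- as.raw(bitwXor(as.integer(coded[hit]),
                                 sample(1:255, sum(hit), TRUE)))
    expect_identical(rs_decode(coded, cfg), d)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(code_config(255, 255), class = "helixcrypt_config_error")
  expect_error(code_config(255, 0), class = "helixcrypt_config_error")
  expect_error(code_config(256, 100), class = "helixcrypt_config_error")
  expect_error(code_config(255, 254), class = "helixcrypt_config_error")
  expect_identical(code_config(255, 223)$t, 16L)
  # inconsistent framing is a format error, not a crash
  expect_error(rs_decode(rand_raw(10), code_config(255, 223, 1)),
               class = "helixcrypt_format_error")
})
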