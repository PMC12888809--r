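# SHA-256 (FIPS 180-4) over raw bytes, implemented on doubles because R has
# no unsigned 32-bit integer type. Words are doubles in [0, 2^32); bitwise ops
# split each word into 16-bit halves that fit in R integers.

.hex2dbl <- function(h) {
  d <- strtoi(strsplit(h, "")[[1]], 16L)
  Reduce(function(a, b) a * 16 + b, d)
}

.K256 <- vapply(c(
  "428a2f98", "71374491", "b5c0fbcf", "e9b5dba5", "3956c25b", "59f111f1",
  "923f82a4", "ab1c5ed5", "d807aa98", "12835b01", "243185be", "550c7dc3",
  "72be5d74", "80deb1fe", "9bdc06a7", "c19bf174", "e49b69c1", "efbe4786",
  "0fc19dc6", "240ca1cc", "2de92c6f", "4a7484aa", "5cb0a9dc", "76f988da",
  "983e5152", "a831c66d", "b00327c8", "bf597fc7", "c6e00bf3", "d5a79147",
  "06ca6351", "14292967", "27b70a85", "2e1b2138", "4d2c6dfc", "53380d13",
  "650a7354", "766a0abb", "81c2c92e", "92722c85", "a2bfe8a1", "a81a664b",
  "c24b8b70", "c76c51a3", "d192e819", "d6990624", "f40e3585", "106aa070",
  "19a4c116", "1e376c08", "2748774c", "34b0bcb5", "391c0cb3", "4ed8aa4a",
  "5b9cca4f", "682e6ff3", "748f82ee", "78a5636f", "84c87814", "8cc70208",
  "90befffa", "a4506ceb", "bef9a3f7", "c67178f2"), .hex2dbl, numeric(1))

.H256 <- vapply(c(
  "6a09e667", "bb67ae85", "3c6ef372", "a54ff53a",
  "510e527f", "9b05688c", "1f83d9ab", "5be0cd19"), .hex2dbl, numeric(1))

.bop32 <- function(op, x, y) {
  xl <- as.integer(x %% 65536); xh <- as.integer(x %/% 65536)
  yl <- as.integer(y %% 65536); yh <- as.integer(y %/% 65536)
  op(xh, yh) * 65536 + op(xl, yl)
}
.bxor32 <- function(x, y) .bop32(bitwXor, x, y)
.band32 <- function(x, y) .bop32(bitwAnd, x, y)
.bnot32 <- function(x) 4294967295 - x
.shr32 <- function(x, n) x %/% (2^n)
.rotr32 <- function(x, n) (x %/% (2^n)) + (x %% (2^n)) * (2^(32 - n))
.add32 <- function(...) Reduce(`+`, list(...)) %% 4294967296

.word_hex <- function(w) {
  sprintf("%04x%04x", as.integer(w %/% 65536), as.integer(w %% 65536))
}

#' SHA-256 digest of a string or raw vector
#'
#' @param x A single character string (hashed as UTF-8 bytes) or a raw vector.
#' @return Lower-case hex digest (64 characters).
#' @export
sha256_hex <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- charToRaw(enc2utf8(x))
  }
  stopifnot(is.raw(x))
  len <- length(x)
  bitlen <- len * 8
  # pad: 0x80, zeros to 56 mod 64, then 8-byte big-endian bit length
  padlen <- (55 - len) %% 64
  msg <- c(x, as.raw(0x80), as.raw(rep(0L, padlen)),
           as.raw(c(floor(bitlen / 2^56) %% 256, floor(bitlen / 2^48) %% 256,
                    floor(bitlen / 2^40) %% 256, floor(bitlen / 2^32) %% 256,
                    floor(bitlen / 2^24) %% 256, floor(bitlen / 2^16) %% 256,
                    floor(bitlen / 2^8) %% 256, bitlen %% 256)))
  H <- .H256
  bytes <- as.integer(msg)
  nblocks <- length(bytes) %/% 64
  for (blk in seq_len(nblocks)) {
    off <- (blk - 1L) * 64L
    w <- numeric(64)
    for (i in 1:16) {
      j <- off + (i - 1L) * 4L
      w[i] <- bytes[j + 1L] * 16777216 + bytes[j + 2L] * 65536 +
        bytes[j + 3L] * 256 + bytes[j + 4L]
    }
    for (i in 17:64) {
      s0 <- .bxor32(.bxor32(.rotr32(w[i - 15], 7), .rotr32(w[i - 15], 18)),
                    .shr32(w[i - 15], 3))
      s1 <- .bxor32(.bxor32(.rotr32(w[i - 2], 17), .rotr32(w[i - 2], 19)),
                    .shr32(w[i - 2], 10))
      w[i] <- .add32(w[i - 16], s0, w[i - 7], s1)
    }
    a <- H[1]; b <- H[2]; cc <- H[3]; d <- H[4]
    e <- H[5]; f <- H[6]; g <- H[7]; h <- H[8]
    for (i in 1:64) {
      S1 <- .bxor32(.bxor32(.rotr32(e, 6), .rotr32(e, 11)), .rotr32(e, 25))
      ch <- .bxor32(.band32(e, f), .band32(.bnot32(e), g))
      t1 <- .add32(h, S1, ch, .K256[i], w[i])
      S0 <- .bxor32(.bxor32(.rotr32(a, 2), .rotr32(a, 13)), .rotr32(a, 22))
      maj <- .bxor32(.bxor32(.band32(a, b), .band32(a, cc)), .band32(b, cc))
      t2 <- .add32(S0, maj)
      h <- g; g <- f; f <- e; e <- .add32(d, t1)
      d <- cc; cc <- b; b <- a; a <- .add32(t1, t2)
    }
    H <- .add32(H, c(a, b, cc, d, e, f, g, h))
  }
  paste(vapply(H, .word_hex, character(1)), collapse = "")
}
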