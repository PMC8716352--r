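# CRC-64 (ECMA-182 polynomial 0x42F0E1EBA9EA3693, MSB-first, zero
# init, no final xor) — the checksum the image-guided-therapy message
# protocol puts in its header. R has no native 64-bit integers, so a
# 64-bit word is carried as two doubles (hi, lo), each an unsigned
# 32-bit value; xor goes through the signed-integer bitwXor with an
# explicit unsigned<->signed conversion.

# xor of two unsigned 32-bit values carried as doubles; split into
# 16-bit halves because as.integer cannot represent all of [0, 2^32)
xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

crc64_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    poly_hi <- 0x42F0E1EB; poly_lo <- 0xA9EA3693  # hex literals parse as doubles
    hi <- numeric(256); lo <- numeric(256)
    for (b in 0:255) {
      chi <- b * 2^24; clo <- 0           # byte << 56, upper half
      for (k in 1:8) {
        top <- chi >= 2^31
        chi <- (chi * 2 + (clo >= 2^31)) %% 2^32
        clo <- (clo * 2) %% 2^32
        if (top) {
          chi <- xor32(chi, poly_hi)
          clo <- xor32(clo, poly_lo)
        }
      }
      hi[b + 1] <- chi; lo[b + 1] <- clo
    }
    tab <<- list(hi = hi, lo = lo)
    tab
  }
})

#' CRC-64 checksum (ECMA-182)
#'
#' @param bytes a raw vector.
#' @return Length-8 raw vector, big-endian (most significant byte
#'   first) — the byte layout used on the wire.
#' @export
crc64 <- function(bytes) {
  cbct_check(is.raw(bytes), "cbctnav_validation", "bytes must be a raw vector")
  tb <- crc64_table()
  chi <- 0; clo <- 0
  for (byte in as.integer(bytes)) {
    idx <- bitwXor(as.integer(chi %/% 2^24), byte) + 1L
    # crc <- table[idx] xor (crc << 8)
    shi <- (chi %% 2^24) * 256 + clo %/% 2^24
    slo <- (clo %% 2^24) * 256
    chi <- xor32(tb$hi[idx], shi)
    clo <- xor32(tb$lo[idx], slo)
  }
  as.raw(c(chi %/% 2^24, (chi %/% 2^16) %% 256, (chi %/% 2^8) %% 256, chi %% 256,
           clo %/% 2^24, (clo %/% 2^16) %% 256, (clo %/% 2^8) %% 256, clo %% 256))
}
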