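# Low-level byte helpers: big-endian integer packing, IEEE 754 half precision,
# hex rendering of keys and binary search over sorted hex strings.
#
# All multi-byte values in the on-disk format are big-endian, so files are
# byte-identical across architectures. Integers are carried as R doubles;
# exactness is guaranteed for |v| <= 2^53 - 1, which bounds what 7- and 8-byte
# columns can hold through this binding (the byte format itself is full-width).

MAX_EXACT_INT <- 2^53 - 1

# Pack a non-negative double-valued integer into `size` big-endian bytes.
uint_to_be <- function(x, size) {
  out <- raw(size)
  for (i in seq(size, 1L)) {
    b <- x %% 256
    out[i] <- as.raw(b)
    x <- (x - b) / 256
  }
  if (x != 0) stop("value does not fit in ", size, " bytes", call. = FALSE)
  out
}

# Inverse of uint_to_be. Exact while the result is < 2^53.
be_to_uint <- function(bytes) {
  x <- 0
  for (b in as.integer(bytes)) x <- x * 256 + b
  x
}

# Signed integers are stored biased: stored = value + 2^(8s-1), computed
# byte-wise so 8-byte columns stay exact in double arithmetic.
int_to_be_biased <- function(x, size) {
  if (x >= 0) {
    out <- uint_to_be(x, size)
    out[1L] <- as.raw(as.integer(out[1L]) + 0x80L)
  } else {
    u <- uint_to_be(-x - 1, size)
    out <- as.raw(0xFFL - as.integer(u))
    out[1L] <- as.raw(0x7FL - as.integer(u[1L]))
  }
  out
}

be_biased_to_int <- function(bytes) {
  b1 <- as.integer(bytes[1L])
  if (b1 >= 0x80L) {
    bytes[1L] <- as.raw(b1 - 0x80L)
    be_to_uint(bytes)
  } else {
    u <- as.raw(0xFFL - as.integer(bytes))
    u[1L] <- as.raw(0x7FL - as.integer(bytes[1L]))
    -(be_to_uint(u) + 1)
  }
}

# ---- IEEE 754 half precision ------------------------------------------------

HALF_QNAN <- as.raw(c(0x7E, 0x00))
SINGLE_QNAN <- as.raw(c(0x7F, 0xC0, 0x00, 0x00))
DOUBLE_QNAN <- as.raw(c(0x7F, 0xF8, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00))

# Convert a finite double to the 16-bit half-precision pattern (as integer
# 0..65535), rounding to nearest even. Overflow (|v| > 65504 after rounding)
# is an error: the format has no use for infinities here.
double_to_half_bits <- function(v) {
  neg <- (v < 0) || (v == 0 && 1 / v < 0)
  s <- if (neg) 32768L else 0L
  a <- abs(v)
  if (a == 0) return(s)
  # exact binary normalisation: a = m * 2^e with m in [1, 2)
  m <- a
  e <- 0L
  while (m >= 2) { m <- m / 2; e <- e + 1L }
  while (m < 1) { m <- m * 2; e <- e - 1L }
  if (e >= -14L) {
    mant <- round((m - 1) * 1024)   # round() is round-half-even
    if (mant == 1024) { mant <- 0; e <- e + 1L }
    if (e > 15L) stop("value out of half-precision range: ", v, call. = FALSE)
    s + (e + 15L) * 1024L + as.integer(mant)
  } else {
    mant <- round(a * 2^24)         # subnormal: units of 2^-24
    if (mant > 1024) {
      # can only reach 1024 exactly (-> smallest normal); larger is impossible
      stop("half-precision rounding invariant violated", call. = FALSE)
    }
    s + as.integer(mant)
  }
}

half_bits_to_double <- function(bits) {
  s <- if (bits >= 32768L) -1 else 1
  bits <- bits %% 32768L
  e <- bits %/% 1024L
  mant <- bits %% 1024L
  if (e == 31L) {
    if (mant == 0L) return(s * Inf)
    return(NaN)
  }
  if (e == 0L) s * mant * 2^-24 else s * (1 + mant / 1024) * 2^(e - 15L)
}

half_encode <- function(v) {
  bits <- double_to_half_bits(v)
  as.raw(c(bits %/% 256L, bits %% 256L))
}

half_decode <- function(bytes) {
  half_bits_to_double(as.integer(bytes[1L]) * 256L + as.integer(bytes[2L]))
}

float_encode <- function(v, size) {
  switch(as.character(size),
    "2" = half_encode(v),
    "4" = writeBin(as.double(v), raw(), size = 4L, endian = "big"),
    "8" = writeBin(as.double(v), raw(), size = 8L, endian = "big"),
    stop("bad float size ", size, call. = FALSE)
  )
}

float_decode <- function(bytes, size) {
  switch(as.character(size),
    "2" = half_decode(bytes),
    "4" = readBin(bytes, "double", n = 1L, size = 4L, endian = "big"),
    "8" = readBin(bytes, "double", n = 1L, size = 8L, endian = "big"),
    stop("bad float size ", size, call. = FALSE)
  )
}

float_missing_pattern <- function(size) {
  switch(as.character(size), "2" = HALF_QNAN, "4" = SINGLE_QNAN, "8" = DOUBLE_QNAN)
}

# Quantize a double to the value it will hold after a store/load cycle at the
# given float width. Used by generators so round-trip comparisons are exact.
float_quantize <- function(v, size) {
  if (is.na(v)) return(NA_real_)
  if (size == 8) v else float_decode(float_encode(v, size), size)
}

# ---- hex keys and binary search --------------------------------------------

# as.character() on a raw vector yields two lowercase hex digits per byte, so
# the concatenation compares identically to the underlying byte string.
raw_to_hex <- function(bytes) paste(as.character(bytes), collapse = "")

hex_to_raw <- function(hex) {
  if (nchar(hex) == 0L) return(raw(0))
  as.raw(strtoi(substring(hex, seq(1L, nchar(hex), 2L), seq(2L, nchar(hex), 2L)),
                base = 16L))
}

# First index i in sorted `keys` with keys[i] >= k (length(keys)+1 if none).
# Hex alphabet [0-9a-f] collates identically to byte order in any locale.
hex_lower_bound <- function(keys, k) {
  lo <- 1L
  hi <- length(keys) + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (keys[mid] < k) lo <- mid + 1L else hi <- mid
  }
  lo
}
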