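hex <- function(r) paste(sprintf("%02x", as.integer(r)), collapse = "")

test_that("integer element encoding uses the biased big-endian form", {
  int1 <- wt_column("i", "int", 1L)
  expect_equal(hex(encode_element(int1, 0)), "80")
  expect_equal(hex(encode_element(int1, -127)), "01")
  expect_equal(hex(encode_element(int1, 127)), "ff")
  expect_equal(hex(encode_element(int1, NA)), "00")
  expect_equal(decode_element(int1, as.raw(0x80)), 0)
  expect_true(is.na(decode_element(int1, as.raw(0x00))))

  uint2 <- wt_column("u", "uint", 2L)
  expect_equal(hex(encode_element(uint2, 5)), "0006")
  expect_equal(hex(encode_element(uint2, NA)), "0000")
  expect_true(is.na(decode_element(uint2, as.raw(c(0, 0)))))
  expect_equal(decode_element(uint2, encode_element(uint2, 65534)), 65534)

  # out-of-range and non-integer values are refused, naming the column
  expect_error(encode_element(int1, -128), "valid int1 range")
  expect_error(encode_element(uint2, 65535), "valid uint2 range")
  expect_error(encode_element(uint2, 1.5), "non-integer")
  expect_error(encode_element(uint2, -1), "'u'")
})

test_that("8-byte integers round-trip exactly across the double-exact range", {
  for (ct in c("uint", "int")) {
    col <- wt_column("x", ct, 8L)
    vals <- c(0, 1, 2^31, 2^52 + 12345, 2^53 - 1,
              if (ct == "int") c(-1, -2^52 - 7, -(2^53 - 1)))
    for (v in vals)
      expect_identical(decode_element(col, encode_element(col, v)), v)
    expect_error(encode_element(col, 2^53), "range")
  }
})

test_that("half-precision floats encode to IEEE 754 bit patterns", {
  f2 <- wt_column("f", "float", 2L)
  expect_equal(hex(encode_element(f2, 1.0)), "3c00")
  expect_equal(hex(encode_element(f2, 0.1)), "2e66")
  expect_equal(decode_element(f2, as.raw(c(0x2e, 0x66))), 0.0999755859375)
  expect_equal(hex(encode_element(f2, NA)), "7e00")
  expect_true(is.na(decode_element(f2, as.raw(c(0x7e, 0x00)))))
  expect_error(encode_element(f2, 70000), "range")
  expect_error(encode_element(f2, Inf), "non-finite")

  f4 <- wt_column("f", "float", 4L)
  expect_equal(hex(encode_element(f4, 1.0)), "3f800000")
  expect_equal(hex(encode_element(f4, NA)), "7fc00000")
  f8 <- wt_column("f", "float", 8L)
  expect_equal(hex(encode_element(f8, NA)), "7ff8000000000000")
  expect_identical(decode_element(f8, encode_element(f8, pi)), pi)
})

golden_schema <- function() {
  wt_schema(list(
    wt_column("a", "uint", 2L),
    wt_column("b", "char", 1L, WT_VARIABLE),
    wt_column("c", "float", 4L, 2L)))
}

test_that("row encoding matches the committed golden bytes", {
  s <- golden_schema()
  lay <- compute_layout(s)
  row <- encode_row(s, lay, list(5, "AC", c(1.0, NA)))
  expect_identical(hex(row), "0006000e00023f8000007fc000004143")
  expect_equal(length(row), 16L)
  row2 <- encode_row(s, lay, list(NA, NA, c(NA, NA)))
  expect_identical(hex(row2), "0000000000007fc000007fc00000")
  expect_equal(length(row2), 14L)
})

test_that("row decoding projects and round-trips", {
  s <- golden_schema()
  lay <- compute_layout(s)
  row <- encode_row(s, lay, list(5, "AC", c(1.0, NA)))
  expect_equal(decode_row(s, lay, row, "b"), list(b = "AC"))
  full <- decode_row(s, lay, row)
  expect_equal(unname(full), list(5, "AC", c(1.0, NA)))
  # projection equals the corresponding slice of the full decode
  expect_equal(decode_row(s, lay, row, c("c", "a")), full[c("c", "a")])
  expect_error(decode_row(s, lay, row, "nope"), "unknown column: 'nope'")
  expect_error(encode_row(s, lay, list(5, "AC", c(1, 2), 9)), "4 values")
})

test_that("corrupt variable pointers are detected", {
  s <- golden_schema()
  lay <- compute_layout(s)
  row <- encode_row(s, lay, list(5, "AC", c(1.0, NA)))
  bad <- row
  bad[4] <- as.raw(0xFF)   # count now huge
  expect_error(decode_row(s, lay, bad, "b"), "corrupt row")
  bad2 <- row
  bad2[3] <- as.raw(0x00)
  bad2[4] <- as.raw(0x01)  # offset points into the fixed region
  expect_error(decode_row(s, lay, bad2, "b"), "corrupt row")
})

test_that("fixed-length char columns reject missing and wrong lengths", {
  c1 <- wt_column("s", "char", 1L, 3L)
  expect_error(encode_element(c1, NA_character_), "MISSING")
  expect_error(encode_element(c1, "ABCD"), "fixed char")
  expect_equal(decode_element(c1, encode_element(c1, "ABC")), "ABC")
})

test_that("rows larger than 65535 bytes are refused", {
  s <- wt_schema(list(wt_column("s", "char", 1L, WT_VARIABLE)))
  lay <- compute_layout(s)
  big <- paste(rep("x", 70000), collapse = "")
  expect_error(encode_row(s, lay, list(big)), "element limit|row limit")
})

test_that("random rows round-trip through the codec", {
  for (seed in 1:120) {
    rt <- random_table(seed, max_columns = 5, max_rows = 5)
    lay <- compute_layout(rt$schema)
    for (r in rt$rows) {
      enc <- encode_row(rt$schema, lay, r)
      expect_equal(unname(decode_row(rt$schema, lay, enc)), r)
      # determinism: same input, same bytes
      expect_identical(encode_row(rt$schema, lay, r), enc)
    }
  }
})
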