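# Row codec: packing cell values into the canonical big-endian binary row and
# back. A row is a fixed region (scalars and variable-column pointers, laid
# out by compute_layout()) followed by a variable region holding the payloads
# of variable-length columns in schema order, unpadded.
#
# Reserved missing patterns: integers store value+bias with the all-zero
# pattern meaning MISSING (costing one value of range); floats store the
# canonical quiet NaN. Fixed-length char columns have no reserved pattern and
# therefore cannot hold MISSING; variable-length columns store MISSING (and
# the indistinguishable empty value) as the (0, 0) pointer.

# valid value range of an integer column, net of the reserved pattern and of
# R's exact-double limit
int_valid_range <- function(col) {
  s <- col$element_size
  if (col$ctype == "uint") c(0, min(2^(8 * s) - 2, MAX_EXACT_INT))
  else c(max(-(2^(8 * s - 1) - 1), -MAX_EXACT_INT),
         min(2^(8 * s - 1) - 1, MAX_EXACT_INT))
}

encode_numeric_element <- function(col, v) {
  s <- col$element_size
  if (col$ctype == "float") {
    if (is.na(v)) return(float_missing_pattern(s))
    if (!is.finite(v))
      stop("column '", col$name, "': non-finite value ", v, call. = FALSE)
    if (s == 4L && abs(v) > 3.4028234663852886e38)
      stop("column '", col$name, "': value ", v,
           " out of single-precision range", call. = FALSE)
    return(float_encode(v, s))
  }
  if (is.na(v)) return(raw(s))
  if (v != trunc(v))
    stop("column '", col$name, "': non-integer value ", v, call. = FALSE)
  r <- int_valid_range(col)
  if (v < r[1L] || v > r[2L])
    stop("column '", col$name, "': value ", format(v, scientific = FALSE),
         " outside valid ", col$ctype, col$element_size, " range [",
         format(r[1L], scientific = FALSE), ", ",
         format(r[2L], scientific = FALSE), "]", call. = FALSE)
  if (col$ctype == "uint") uint_to_be(v + 1, s) else int_to_be_biased(v, s)
}

decode_numeric_element <- function(col, bytes) {
  s <- col$element_size
  if (col$ctype == "float") {
    if (identical(bytes, float_missing_pattern(s))) return(NA_real_)
    return(float_decode(bytes, s))
  }
  if (all(bytes == as.raw(0L))) return(NA_real_)
  if (col$ctype == "uint") be_to_uint(bytes) - 1 else be_biased_to_int(bytes)
}

#' Encode one cell value to its binary element bytes
#'
#' Encodes a single column's value: a numeric vector (one number per element),
#' a string for char columns (one byte per element), or `NA` for missing.
#' Integers are stored big-endian with a bias (`+1` for `uint`,
#' `+2^(8s-1)` for `int`) so that the all-zero pattern is reserved for
#' missing; floats are raw IEEE 754 half/single/double bit patterns with the
#' canonical quiet NaN reserved for missing.
#'
#' @param col A [wt_column()].
#' @param value The cell value.
#' @return A raw vector, `element_size` bytes per element.
#' @export
encode_element <- function(col, value) {
  if (col$ctype == "char") {
    if (length(value) != 1L)
      stop("column '", col$name, "': char value must be a single string",
           call. = FALSE)
    if (is.na(value)) {
      if (!is_variable(col))
        stop("column '", col$name, "': fixed-length char column cannot hold ",
             "MISSING", call. = FALSE)
      return(raw(0))
    }
    bytes <- charToRaw(as.character(value))
    if (!is_variable(col) && length(bytes) != col$num_elements)
      stop("column '", col$name, "': string of ", length(bytes),
           " bytes in fixed char(", col$num_elements, ") column",
           call. = FALSE)
    return(bytes)
  }
  # numeric column
  if (is_variable(col) && length(value) == 0L) return(raw(0))
  if (!is_variable(col)) {
    if (length(value) == 1L && is.na(value) && col$num_elements > 1L)
      value <- rep(NA_real_, col$num_elements)   # MISSING shorthand
    if (length(value) != col$num_elements)
      stop("column '", col$name, "': ", length(value), " elements for fixed ",
           "count ", col$num_elements, call. = FALSE)
  } else if (length(value) == 1L && is.na(value)) {
    return(raw(0))
  }
  out <- raw(0)
  for (v in as.numeric(value)) out <- c(out, encode_numeric_element(col, v))
  out
}

#' Decode element bytes back to a cell value
#'
#' Inverse of [encode_element()]. `decode_element(col, encode_element(col, v))`
#' returns `v` exactly for integers and strings, and bit-exactly at stored
#' precision for floats.
#'
#' @param col A [wt_column()].
#' @param buf Raw vector holding a whole number of elements.
#' @return The cell value; `NA` for the reserved missing patterns.
#' @export
decode_element <- function(col, buf) {
  if (col$ctype == "char") {
    if (length(buf) == 0L) return(NA_character_)
    return(rawToChar(buf))
  }
  s <- col$element_size
  if (length(buf) %% s != 0L)
    stop("column '", col$name, "': buffer of ", length(buf),
         " bytes is not a whole number of ", s, "-byte elements",
         call. = FALSE)
  n <- length(buf) %/% s
  if (n == 0L) return(NA_real_)
  out <- vapply(seq_len(n), function(i)
    decode_numeric_element(col, buf[((i - 1L) * s + 1L):(i * s)]), 0)
  if (n == 1L) out[[1L]] else out
}

element_count <- function(col, value) {
  if (col$ctype == "char") {
    if (is.na(value)) 0L else nchar(as.character(value), type = "bytes")
  } else {
    if (length(value) == 1L && is.na(value)) 0L else length(value)
  }
}

#' Encode a full row
#'
#' Lays out the fixed region per `layout`, then appends variable-region
#' payloads in schema order and points each variable column's 4-byte
#' (offset, count) pointer at its payload. A variable column holding MISSING
#' or an empty value stores the pointer `(0, 0)` and contributes no payload.
#'
#' @param schema A [wt_schema()].
#' @param layout The matching [compute_layout()].
#' @param values A list with one cell value per column, in schema order.
#' @return A raw vector: the encoded row (at most 65535 bytes).
#' @export
encode_row <- function(schema, layout, values) {
  ncol <- length(schema$columns)
  if (length(values) != ncol)
    stop("row has ", length(values), " values for ", ncol, " columns",
         call. = FALSE)
  fixed <- raw(layout$fixed_region_size)
  payloads <- list()
  var_at <- integer(0)    # fixed-region offsets of pointers to patch
  for (i in seq_len(ncol)) {
    col <- schema$columns[[i]]
    off <- layout$offsets[[i]]
    if (is_variable(col)) {
      payload <- encode_element(col, values[[i]])
      count <- element_count(col, values[[i]])
      if (count > MAX_VAR_ELEMENTS)
        stop("column '", col$name, "': ", count, " elements exceed the ",
             MAX_VAR_ELEMENTS, "-element limit", call. = FALSE)
      payloads[[length(payloads) + 1L]] <- payload
      var_at <- c(var_at, off)
    } else {
      bytes <- encode_element(col, values[[i]])
      if (length(bytes)) fixed[(off + 1L):(off + length(bytes))] <- bytes
    }
  }
  # assign payload offsets now that the fixed region size is known
  running <- layout$fixed_region_size
  vcols <- Filter(is_variable, schema$columns)
  for (j in seq_along(payloads)) {
    nbytes <- length(payloads[[j]])
    off <- var_at[j]
    es <- vcols[[j]]$element_size
    n_elem <- nbytes %/% es
    if (n_elem == 0L) {
      ptr <- raw(POINTER_SIZE)
    } else {
      ptr <- c(uint_to_be(running, 2L), uint_to_be(n_elem, 2L))
      running <- running + nbytes
    }
    fixed[(off + 1L):(off + POINTER_SIZE)] <- ptr
  }
  row <- c(fixed, unlist(payloads, use.names = FALSE) %||% raw(0))
  row <- as.raw(row)
  if (length(row) > MAX_ROW_BYTES)
    stop("encoded row of ", length(row), " bytes exceeds the ",
         MAX_ROW_BYTES, "-byte row limit", call. = FALSE)
  row
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_var_pointer <- function(row, layout, off, col) {
  ptr <- row[(off + 1L):(off + POINTER_SIZE)]
  p_off <- be_to_uint(ptr[1:2])
  count <- be_to_uint(ptr[3:4])
  if (count == 0L && p_off == 0L) return(c(0L, 0L))
  end <- p_off + count * col$element_size
  if (p_off < layout$fixed_region_size || end > length(row))
    stop("corrupt row: variable pointer for column '", col$name,
         "' (offset ", p_off, ", count ", count, ") outside row of ",
         length(row), " bytes", call. = FALSE)
  c(p_off, count)
}

#' Decode a row, optionally projecting a subset of columns
#'
#' Only the bytes of the requested columns are touched, which is what makes
#' column-projected cursors cheap.
#'
#' @param schema A [wt_schema()].
#' @param layout The matching [compute_layout()].
#' @param row Raw vector produced by [encode_row()] under the same schema.
#' @param columns Character vector of column names to decode, in the order
#'   wanted, or `NULL` for all columns in schema order.
#' @return A list of cell values, one per requested column.
#' @export
decode_row <- function(schema, layout, row, columns = NULL) {
  nm <- schema_names(schema)
  if (is.null(columns)) columns <- nm
  idx <- match(columns, nm)
  if (anyNA(idx))
    stop("unknown column: '", columns[which(is.na(idx))[1L]], "'",
         call. = FALSE)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    col <- schema$columns[[i]]
    off <- layout$offsets[[i]]
    if (is_variable(col)) {
      pc <- read_var_pointer(row, layout, off, col)
      buf <- if (pc[2L] == 0L) raw(0)
             else row[(pc[1L] + 1L):(pc[1L] + pc[2L] * col$element_size)]
      out[[k]] <- decode_element(col, buf)
    } else {
      w <- layout$widths[[i]]
      out[[k]] <- decode_element(col, row[(off + 1L):(off + w)])
    }
  }
  names(out) <- columns
  out
}
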