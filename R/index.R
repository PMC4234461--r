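#' Secondary indexes
#'
#' An index maps an order-preserving byte encoding of one or more columns'
#' values to row positions, stored in an ordered key-value database
#' (`index_<name>.db` in the table directory, `name` = key columns joined by
#' `"+"`). Because the key encoding preserves value order byte-lexically,
#' range queries, partial-key (prefix) queries, key counts and histograms are
#' all sorted scans. Optional per-column bin widths map a half-open value
#' interval `[b*w, (b+1)*w)` to the single key `b = floor(value / w)`.
#'
#' Key encodings per column type: integers reuse the biased row encoding
#' (all-zero MISSING first, then ascending); floats use the IEEE bit pattern
#' with the sign bit flipped (and all bits inverted for negatives) so byte
#' order equals numeric order, MISSING encoding as all zeroes; fixed-length
#' char is raw bytes; variable-length char is raw bytes plus a 0x00
#' terminator, which preserves prefix order (`"2" < "2L"`). Binned columns
#' encode `floor(value/width)` as a signed 8-byte integer so negative bins
#' order correctly. MISSING always sorts first.
#'
#' Key columns must be scalar, fixed-count numeric, or char: a
#' variable-count numeric column cannot be indexed (its element count would
#' not be recoverable from the concatenated key).
#'
#' @name wtab-indexes
NULL

#' Map a value to its bin
#'
#' Bin `b` covers the half-open interval `[b*width, (b+1)*width)`.
#'
#' @param value Finite number (or `NA`, which passes through).
#' @param width Positive bin width.
#' @return `floor(value / width)`.
#' @examples
#' bin_value(1.2, 0.5)    # 2
#' bin_value(-0.3, 0.5)   # -1
#' @export
bin_value <- function(value, width) {
  if (!is.numeric(width) || length(width) != 1L || is.na(width) || width <= 0)
    stop("bin width must be a positive number", call. = FALSE)
  if (is.na(value)) return(NA_real_)
  if (!is.finite(value)) stop("cannot bin non-finite value", call. = FALSE)
  b <- floor(value / width)
  # the quotient can land a hair on the wrong side of an integer; nudge so
  # that b*width <= value < (b+1)*width always holds
  if (b * width > value) b <- b - 1
  else if ((b + 1) * width <= value) b <- b + 1
  b
}

index_name_for <- function(columns) paste(columns, collapse = "+")

# validate key columns + bins against a schema; returns list of wt_column
check_index_spec <- function(schema, columns, bins) {
  if (length(columns) == 0L) stop("index needs at least one key column",
                                  call. = FALSE)
  if (anyDuplicated(columns))
    stop("repeated key column in index spec", call. = FALSE)
  cols <- lapply(columns, function(nm) schema_column(schema, nm))
  for (col in cols) {
    if (col$ctype != "char" && is_variable(col))
      stop("column '", col$name, "': variable-count numeric columns cannot ",
           "be indexed", call. = FALSE)
  }
  if (!is.null(bins)) {
    if (length(bins) != length(columns))
      stop("bins must align with key columns (use NA for unbinned)",
           call. = FALSE)
    for (i in seq_along(bins)) {
      w <- bins[i]
      if (is.na(w)) next
      col <- cols[[i]]
      if (col$ctype == "char")
        stop("column '", col$name, "': char columns cannot be binned",
             call. = FALSE)
      if (w <= 0) stop("bin width must be positive", call. = FALSE)
      if (col$ctype %in% c("uint", "int") && w != trunc(w))
        stop("column '", col$name, "': integer column needs an integer bin ",
             "width", call. = FALSE)
      if (!is.na(col$num_elements) && col$num_elements != 1L)
        stop("column '", col$name, "': only scalar columns can be binned",
             call. = FALSE)
    }
  }
  cols
}

float_key_transform <- function(bytes) {
  if (as.integer(bytes[1L]) >= 0x80L) as.raw(0xFFL - as.integer(bytes))
  else { bytes[1L] <- as.raw(as.integer(bytes[1L]) + 0x80L); bytes }
}

float_key_untransform <- function(bytes) {
  if (as.integer(bytes[1L]) >= 0x80L) {
    bytes[1L] <- as.raw(as.integer(bytes[1L]) - 0x80L); bytes
  } else as.raw(0xFFL - as.integer(bytes))
}

encode_key_column <- function(col, width, value) {
  if (!is.na(width)) {
    if (length(value) != 1L)
      stop("binned column '", col$name, "' expects a scalar", call. = FALSE)
    b <- bin_value(value, width)
    return(if (is.na(b)) raw(8L) else int_to_be_biased(b, 8L))
  }
  if (col$ctype == "char") {
    if (is_variable(col)) {
      if (is.na(value)) return(as.raw(0L))
      bytes <- charToRaw(as.character(value))
      if (any(bytes == as.raw(0L)))
        stop("column '", col$name, "': embedded NUL byte in indexed ",
             "variable-length value", call. = FALSE)
      return(c(bytes, as.raw(0L)))
    }
    return(encode_element(col, value))
  }
  if (col$ctype == "float") {
    n <- col$num_elements
    if (length(value) == 1L && is.na(value) && n > 1L)
      value <- rep(NA_real_, n)
    if (length(value) != n)
      stop("column '", col$name, "': ", length(value), " elements for fixed ",
           "count ", n, call. = FALSE)
    out <- raw(0)
    for (v in as.numeric(value)) {
      out <- c(out, if (is.na(v)) raw(col$element_size)
               else float_key_transform(float_encode(v, col$element_size)))
    }
    return(out)
  }
  encode_element(col, value)   # uint / int: row encoding is order-preserving
}

# Encode a (possibly partial) key tuple for an index.
encode_index_key <- function(cols, bins, values) {
  k <- length(values)
  if (k > length(cols))
    stop("key tuple longer than the index's ", length(cols), " key columns",
         call. = FALSE)
  out <- raw(0)
  for (i in seq_len(k)) {
    w <- if (is.null(bins)) NA_real_ else bins[i]
    out <- c(out, encode_key_column(cols[[i]], w, values[[i]]))
  }
  out
}

decode_key_column <- function(col, width, bytes, pos) {
  if (!is.na(width)) {
    b <- bytes[pos:(pos + 7L)]
    v <- if (all(b == as.raw(0L))) NA_real_ else be_biased_to_int(b)
    return(list(value = v, pos = pos + 8L))
  }
  if (col$ctype == "char") {
    if (is_variable(col)) {
      end <- pos
      while (bytes[end] != as.raw(0L)) end <- end + 1L
      v <- if (end == pos) NA_character_ else rawToChar(bytes[pos:(end - 1L)])
      return(list(value = v, pos = end + 1L))
    }
    n <- col$num_elements
    return(list(value = rawToChar(bytes[pos:(pos + n - 1L)]),
                pos = pos + n))
  }
  n <- col$num_elements
  es <- col$element_size
  vals <- numeric(n)
  for (j in seq_len(n)) {
    b <- bytes[pos:(pos + es - 1L)]
    vals[j] <- if (col$ctype == "float") {
      if (all(b == as.raw(0L))) NA_real_
      else float_decode(float_key_untransform(b), es)
    } else {
      decode_numeric_element(col, b)
    }
    pos <- pos + es
  }
  list(value = if (n == 1L) vals[[1L]] else vals, pos = pos)
}

decode_index_key <- function(cols, bins, bytes) {
  out <- vector("list", length(cols))
  pos <- 1L
  for (i in seq_along(cols)) {
    w <- if (is.null(bins)) NA_real_ else bins[i]
    d <- decode_key_column(cols[[i]], w, bytes, pos)
    out[[i]] <- d$value
    pos <- d$pos
  }
  names(out) <- vapply(cols, function(c) c$name, "")
  out
}

#' Build a secondary index
#'
#' Scans the table once, encodes each row's key-column values into an
#' order-preserving byte key and writes the sorted key database. Rows with
#' equal keys are stored in ascending row-position order. The index is
#' registered in the table's metadata; building under an existing name is
#' refused (remove it first). A failed build leaves the table directory
#' untouched.
#'
#' @param table A read-only `wt_table`.
#' @param columns Key column names, in order.
#' @param bins Optional numeric vector aligned with `columns`: a positive bin
#'   width per column, `NA` for unbinned. Only numeric scalar columns can be
#'   binned; integer columns need integer widths.
#' @return The opened `wt_index`, invisibly.
#' @export
wt_index_build <- function(table, columns, bins = NULL) {
  stopifnot(inherits(table, "wt_table"))
  cols <- check_index_spec(table$schema, columns, bins)
  name <- index_name_for(columns)
  meta <- read_metadata_xml(table_paths(table$dir)$metadata)
  if (name %in% names(meta$indexes))
    stop("index '", name, "' already exists; remove it first", call. = FALSE)
  rows <- wt_cursor(table, columns)
  keys <- character(length(rows))
  values <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    keys[i] <- raw_to_hex(encode_index_key(cols, bins, rows[[i]]))
    values[[i]] <- uint_to_be(i - 1, 8L)
  }
  # stable sort keeps equal keys in row-position order
  db <- index_db_path(table$dir, name)
  tmp <- paste0(db, ".tmp")
  kv_write(tmp, keys, values)
  file.rename(tmp, db)
  meta$indexes[[name]] <- list(name = name,
                               bins = if (is.null(bins)) NULL else bins)
  write_metadata_xml(table$dir, meta$num_rows, meta$indexes)
  invisible(wt_index_open(table, name))
}

#' Open an existing index
#'
#' @param table A `wt_table`.
#' @param name Index name (key columns joined by `"+"`).
#' @return A `wt_index` handle.
#' @export
wt_index_open <- function(table, name) {
  meta <- read_metadata_xml(table_paths(table$dir)$metadata)
  if (!(name %in% names(meta$indexes)))
    stop("no index '", name, "' on table '", table$dir, "'", call. = FALSE)
  columns <- strsplit(name, "+", fixed = TRUE)[[1L]]
  bins <- meta$indexes[[name]]$bins
  cols <- check_index_spec(table$schema, columns, bins)
  kv <- kv_read(index_db_path(table$dir, name))
  positions <- vapply(kv$values, be_to_uint, 0)
  structure(list(table = table, name = name, columns = columns, cols = cols,
                 bins = bins, keys = kv$keys, positions = positions),
            class = "wt_index")
}

#' Remove an index
#'
#' Deletes the index database and deregisters it from the table metadata.
#' Row data is never touched.
#'
#' @param table A `wt_table`.
#' @param name Index name.
#' @export
wt_index_remove <- function(table, name) {
  meta <- read_metadata_xml(table_paths(table$dir)$metadata)
  if (!(name %in% names(meta$indexes)))
    stop("no index '", name, "' on table '", table$dir, "'", call. = FALSE)
  file.remove(index_db_path(table$dir, name))
  meta$indexes[[name]] <- NULL
  write_metadata_xml(table$dir, meta$num_rows, meta$indexes)
  invisible(TRUE)
}

#' List the indexes on a table
#'
#' @param table A `wt_table`.
#' @return A data frame with one row per index: `name`, `bins` (comma-joined,
#'   `""` for none) and `entries`.
#' @export
wt_index_list <- function(table) {
  meta <- read_metadata_xml(table_paths(table$dir)$metadata)
  name <- names(meta$indexes)
  bins <- vapply(meta$indexes, function(ix) {
    if (is.null(ix$bins) || all(is.na(ix$bins))) "" else
      paste(ifelse(is.na(ix$bins), "", format(ix$bins, trim = TRUE)),
            collapse = ",")
  }, "")
  entries <- vapply(name, function(nm)
    kv_read(index_db_path(table$dir, nm))$n, 0)
  data.frame(name = name, bins = unname(bins), entries = unname(entries),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.wt_index <- function(x, ...) {
  cat("wt_index '", x$name, "' on ", x$table$dir, ": ",
      length(x$positions), " entries\n", sep = "")
  invisible(x)
}

index_bound_hex <- function(index, tuple) {
  if (is.null(tuple)) return(NULL)
  if (!is.list(tuple)) tuple <- as.list(tuple)
  raw_to_hex(encode_index_key(index$cols, index$bins, tuple))
}

#' Cursor over an index key range
#'
#' Yields rows in index-key order (ties in ascending row position), projected
#' to the requested columns, for all rows whose key satisfies
#' `enc(start) <= key < enc(stop)` byte-lexicographically. `start` and `stop`
#' are tuples of values for a *prefix* of the key columns (partial keys), so
#' e.g. `start = list("2L"), stop = list("2R")` on a CHROM+POS index selects
#' every row on chromosome 2L in ascending position. Values for binned
#' columns are binned before encoding. `NULL` means unbounded.
#'
#' @param index A `wt_index`.
#' @param columns Columns to project (`NULL` = all).
#' @param start,stop Partial key tuples (lists, or vectors for single-column
#'   prefixes), or `NULL`.
#' @return A list of projected rows in index order.
#' @export
wt_index_cursor <- function(index, columns = NULL, start = NULL, stop = NULL) {
  sel <- kv_range(list(keys = index$keys),
                  index_bound_hex(index, start),
                  index_bound_hex(index, stop))
  fetch_rows(index$table, index$positions[sel], columns)
}

#' Iterate the distinct keys of an index
#'
#' @param index A `wt_index`.
#' @return A list of decoded key tuples (named lists) in ascending key order;
#'   binned columns yield bin ids.
#' @export
wt_index_keys <- function(index) {
  uk <- unique(index$keys)
  lapply(uk, function(k) decode_index_key(index$cols, index$bins,
                                          hex_to_raw(k)))
}

#' Count the rows with a given key
#'
#' @param index A `wt_index`.
#' @param key Full key tuple (list, or vector for a single-column index).
#' @return The exact number of rows whose encoded key equals `enc(key)`;
#'   0 when absent.
#' @export
wt_key_count <- function(index, key) {
  if (!is.list(key)) key <- as.list(key)
  if (length(key) != length(index$cols))
    stop("key_count needs a full key tuple (", length(index$cols),
         " columns)", call. = FALSE)
  k <- index_bound_hex(index, key)
  lo <- hex_lower_bound(index$keys, k)
  n <- 0
  while (lo + n <= length(index$keys) && index$keys[lo + n] == k) n <- n + 1
  n
}

#' Histogram of an index
#'
#' One entry per distinct key in ascending key order; counts sum to the
#' table's row count (rows whose key columns are all MISSING fall under the
#' all-zero key, which sorts first).
#'
#' @param index A `wt_index`.
#' @return A list with `keys` (list of decoded key tuples) and `counts`
#'   (numeric vector), parallel and in ascending key order.
#' @export
wt_histogram <- function(index) {
  if (length(index$keys) == 0L) return(list(keys = list(), counts = numeric(0)))
  r <- rle(index$keys)
  list(keys = lapply(r$values, function(k)
         decode_index_key(index$cols, index$bins, hex_to_raw(k))),
       counts = as.numeric(r$lengths))
}

#' Smallest and largest key of an index
#'
#' @param index A nonempty `wt_index`.
#' @return A list with `min` and `max`: the decoded extreme key tuples.
#' @export
wt_key_range <- function(index) {
  if (length(index$keys) == 0L) stop("index is empty", call. = FALSE)
  list(min = decode_index_key(index$cols, index$bins,
                              hex_to_raw(index$keys[1L])),
       max = decode_index_key(index$cols, index$bins,
                              hex_to_raw(index$keys[length(index$keys)])))
}
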