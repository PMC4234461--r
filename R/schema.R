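#' Column and schema definitions
#'
#' A table schema is an ordered list of column specifications. Each column
#' holds one or more elements of a single storage type:
#' \describe{
#'   \item{uint}{unsigned integer, 1--8 bytes per element}
#'   \item{int}{signed integer, 1--8 bytes per element}
#'   \item{float}{IEEE 754 floating point: 2 (half), 4 (single) or 8 (double)
#'     bytes}
#'   \item{char}{byte characters, always 1 byte per element; a value is a
#'     string whose length is the element count}
#' }
#' `num_elements` is a positive count for fixed-size columns, or
#' [WT_VARIABLE] for variable-length columns, whose payload lives in the
#' variable region of each row.
#'
#' @param name Column name. Must match `[A-Za-z_][A-Za-z0-9_.]*`; dots allow
#'   namespaced names such as `INFO.DP` or `NA0001.GT`.
#' @param ctype One of `"uint"`, `"int"`, `"float"`, `"char"`.
#' @param element_size Bytes per element (see above).
#' @param num_elements Elements per value, or [WT_VARIABLE].
#' @param description Optional free-text description.
#' @return An object of class `wt_column`.
#' @examples
#' wt_column("POS", "uint", 4)
#' wt_column("ALT", "char", 1, WT_VARIABLE)
#' @export
wt_column <- function(name, ctype, element_size, num_elements = 1L,
                      description = "") {
  col <- structure(
    list(name = as.character(name), ctype = as.character(ctype),
         element_size = as.integer(element_size),
         num_elements = if (is.na(num_elements)) NA_integer_
                        else as.integer(num_elements),
         description = as.character(description)),
    class = "wt_column")
  validate_column(col)
  col
}

#' Marker for variable-length columns
#'
#' @format An `NA` integer used as the `num_elements` of a variable-length
#'   column.
#' @export
WT_VARIABLE <- NA_integer_

is_variable <- function(col) is.na(col$num_elements)

validate_column <- function(col) {
  if (!nzchar(col$name) || !grepl("^[A-Za-z_][A-Za-z0-9_.]*$", col$name))
    stop("invalid column name: '", col$name, "'", call. = FALSE)
  sizes <- switch(col$ctype,
    uint = 1:8, int = 1:8, float = c(2L, 4L, 8L), char = 1L,
    stop("column '", col$name, "': unknown ctype '", col$ctype, "'",
         call. = FALSE))
  if (!(col$element_size %in% sizes))
    stop("column '", col$name, "': element_size ", col$element_size,
         " invalid for ctype ", col$ctype, call. = FALSE)
  if (!is.na(col$num_elements) && col$num_elements < 1L)
    stop("column '", col$name, "': num_elements must be positive or ",
         "WT_VARIABLE", call. = FALSE)
  invisible(col)
}

#' Construct and validate a table schema
#'
#' @param columns A list of [wt_column()] objects; order is significant and is
#'   preserved through the XML serialization.
#' @param version Format version string.
#' @return An object of class `wt_schema`.
#' @export
wt_schema <- function(columns, version = "1.0") {
  if (length(columns) == 0L) stop("schema needs at least one column",
                                  call. = FALSE)
  for (col in columns) {
    if (!inherits(col, "wt_column")) stop("not a wt_column", call. = FALSE)
    validate_column(col)
  }
  nm <- vapply(columns, function(c) c$name, "")
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicate column name: '", dup[1L], "'", call. = FALSE)
  structure(list(columns = columns, version = as.character(version)),
            class = "wt_schema")
}

schema_names <- function(schema) vapply(schema$columns, function(c) c$name, "")

schema_column <- function(schema, name) {
  i <- match(name, schema_names(schema))
  if (is.na(i)) stop("unknown column: '", name, "'", call. = FALSE)
  schema$columns[[i]]
}

#' @export
print.wt_schema <- function(x, ...) {
  cat("wt_schema (version ", x$version, ") with ", length(x$columns),
      " columns:\n", sep = "")
  for (col in x$columns) {
    n <- if (is_variable(col)) "var" else col$num_elements
    cat(sprintf("  %-20s %-5s size %d x %s\n", col$name, col$ctype,
                col$element_size, n))
  }
  invisible(x)
}

#' @export
format.wt_column <- function(x, ...) {
  n <- if (is_variable(x)) "var" else x$num_elements
  sprintf("%s:%s%d[%s]", x$name, x$ctype, x$element_size, n)
}

# ---- XML serialization ------------------------------------------------------

#' Serialize a schema to XML
#'
#' The XML dialect is canonical for this package: a `<schema version=...>`
#' root holding `<columns>` with one `<column>` element per column in schema
#' order. Output is byte-deterministic (fixed attribute order, two-space
#' indentation, LF line endings), so equal schemas always serialize
#' identically.
#'
#' @param schema A [wt_schema()].
#' @return A single XML string.
#' @seealso [parse_schema_xml()]
#' @export
write_schema_xml <- function(schema) {
  if (!inherits(schema, "wt_schema")) schema <- wt_schema(schema)
  xml_attr_escape <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub("\"", "&quot;", s, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<schema version=\"%s\">", xml_attr_escape(schema$version)),
    "  <columns>")
  for (col in schema$columns) {
    n <- if (is_variable(col)) "var" else as.character(col$num_elements)
    lines <- c(lines, sprintf(
      "    <column name=\"%s\" ctype=\"%s\" element_size=\"%d\" num_elements=\"%s\" description=\"%s\"/>",
      xml_attr_escape(col$name), col$ctype, col$element_size, n,
      xml_attr_escape(col$description)))
  }
  paste0(paste(c(lines, "  </columns>", "</schema>"), collapse = "\n"), "\n")
}

#' Parse a schema from XML
#'
#' @param xml_text XML string in the dialect written by [write_schema_xml()].
#' @return A [wt_schema()]; columns appear in document order.
#' @export
parse_schema_xml <- function(xml_text) {
  doc <- tryCatch(xml2::read_xml(xml_text),
                  error = function(e) stop("malformed schema XML: ",
                                           conditionMessage(e), call. = FALSE))
  root <- xml2::xml_name(doc)
  if (root != "schema") stop("schema XML root must be <schema>, got <",
                             root, ">", call. = FALSE)
  version <- xml2::xml_attr(doc, "version")
  if (is.na(version)) version <- "1.0"
  nodes <- xml2::xml_find_all(doc, "./columns/column")
  if (length(nodes) == 0L) stop("schema XML has no columns", call. = FALSE)
  columns <- lapply(nodes, function(node) {
    name <- xml2::xml_attr(node, "name")
    ctype <- xml2::xml_attr(node, "ctype")
    es <- xml2::xml_attr(node, "element_size")
    ne <- xml2::xml_attr(node, "num_elements")
    desc <- xml2::xml_attr(node, "description")
    if (anyNA(c(name, ctype, es, ne)))
      stop("schema XML column missing a required attribute", call. = FALSE)
    wt_column(name, ctype, as.integer(es),
              if (identical(ne, "var")) WT_VARIABLE else as.integer(ne),
              if (is.na(desc)) "" else desc)
  })
  wt_schema(columns, version = version)
}

# ---- row layout -------------------------------------------------------------

# Bytes a (offset, count) pointer for a variable-length column occupies in the
# fixed region: 2-byte offset from row start + 2-byte element count. A row is
# therefore capped at 65535 bytes and a value at 65535 elements.
POINTER_SIZE <- 4L
MAX_ROW_BYTES <- 65535
MAX_VAR_ELEMENTS <- 65535

#' Compute the fixed-region layout of a schema
#'
#' Each column is assigned consecutive byte offsets within the fixed region of
#' a row, in schema order. A fixed-count column occupies
#' `element_size * num_elements` bytes; a variable-length column occupies a
#' 4-byte pointer (2-byte offset from the row start plus 2-byte element
#' count) referencing its payload in the variable region.
#'
#' @param schema A [wt_schema()].
#' @return An object of class `wt_layout` with per-column `offsets`, per-column
#'   fixed footprints `widths`, and `fixed_region_size`.
#' @export
compute_layout <- function(schema) {
  widths <- vapply(schema$columns, function(col) {
    if (is_variable(col)) POINTER_SIZE
    else col$element_size * col$num_elements
  }, 0L)
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  names(offsets) <- names(widths) <- schema_names(schema)
  structure(list(offsets = offsets, widths = widths,
                 fixed_region_size = sum(widths)),
            class = "wt_layout")
}

# ---- smallest-type inference ------------------------------------------------

#' Running statistics for column type inference
#'
#' Accumulates the observations needed to choose the smallest column type that
#' represents a data stream: integer extrema, whether any value demanded
#' floating point, string-length extrema, the maximum element count, and
#' whether a missing value was seen.
#'
#' @return An environment of class `wt_column_stats`.
#' @seealso [stats_observe()], [infer_column_spec()]
#' @export
new_column_stats <- function() {
  e <- new.env(parent = emptyenv())
  e$min_int <- NA_real_; e$max_int <- NA_real_
  e$needs_float <- FALSE
  e$min_len <- NA_integer_; e$max_len <- NA_integer_
  e$max_count <- NA_integer_; e$counts_vary <- FALSE
  e$saw_missing <- FALSE
  e$n_values <- 0
  class(e) <- "wt_column_stats"
  e
}

#' Feed one value into a column-statistics accumulator
#'
#' @param stats A [new_column_stats()] accumulator.
#' @param value A numeric vector, a string, or `NA` for missing.
#' @export
stats_observe <- function(stats, value) {
  if (length(value) == 0L || (length(value) == 1L && is.na(value))) {
    stats$saw_missing <- TRUE
    return(invisible(stats))
  }
  n <- if (is.character(value)) nchar(value, type = "bytes") else length(value)
  if (is.na(stats$max_count)) stats$max_count <- n
  else {
    if (n != stats$max_count) stats$counts_vary <- TRUE
    stats$max_count <- max(stats$max_count, n)
  }
  if (is.character(value)) {
    len <- nchar(value, type = "bytes")
    stats$min_len <- min(stats$min_len, len, na.rm = TRUE)
    stats$max_len <- max(stats$max_len, len, na.rm = TRUE)
  } else {
    v <- value[!is.na(value)]
    if (any(is.na(value))) stats$saw_missing <- TRUE
    if (length(v)) {
      if (any(v != trunc(v))) stats$needs_float <- TRUE
      stats$min_int <- min(stats$min_int, v, na.rm = TRUE)
      stats$max_int <- max(stats$max_int, v, na.rm = TRUE)
    }
  }
  stats$n_values <- stats$n_values + 1
  invisible(stats)
}

# smallest byte size whose *valid* range (which reserves one pattern for
# MISSING) covers [lo, hi]
smallest_uint_size <- function(hi) {
  for (s in 1:8) if (hi <= min(2^(8 * s) - 2, MAX_EXACT_INT)) return(s)
  stop("integer too large for 8-byte column: ", hi, call. = FALSE)
}

smallest_int_size <- function(lo, hi) {
  for (s in 1:8) {
    m <- min(2^(8 * s - 1) - 1, MAX_EXACT_INT)
    if (lo >= -m && hi <= m) return(s)
  }
  stop("integer range too large for 8-byte column", call. = FALSE)
}

#' Infer the smallest column specification covering observed data
#'
#' Chooses the smallest legal type whose valid value range (net of the
#' reserved missing pattern) covers everything the statistics recorded:
#' non-negative integers become `uint`, signed integers `int`, anything with a
#' fractional part `float` (single precision by default). Character columns
#' are fixed-length only when every observed string had the same length, a
#' single element, and no missing value was seen; otherwise they are
#' variable-length.
#'
#' @param name Column name for the resulting spec.
#' @param kind_hint `"int"`, `"float"` or `"char"`: the lexical class of the
#'   source field.
#' @param stats A [new_column_stats()] accumulator after a full pass over the
#'   data.
#' @param float_size Element size used when the column is floating point.
#' @return A [wt_column()].
#' @export
infer_column_spec <- function(name, kind_hint = c("int", "float", "char"),
                              stats, float_size = 4L) {
  kind_hint <- match.arg(kind_hint)
  if (stats$n_values == 0) {
    warning("column '", name, "': no values observed; defaulting to ",
            "variable char", call. = FALSE)
    return(wt_column(name, "char", 1L, WT_VARIABLE))
  }
  num_elements <- if (stats$counts_vary) WT_VARIABLE else stats$max_count
  if (kind_hint == "char") {
    fixed <- !stats$counts_vary && identical(stats$min_len, stats$max_len) &&
      !stats$saw_missing
    if (fixed) wt_column(name, "char", 1L, stats$max_len)
    else wt_column(name, "char", 1L, WT_VARIABLE)
  } else if (kind_hint == "float" || stats$needs_float) {
    wt_column(name, "float", as.integer(float_size), num_elements)
  } else if (is.na(stats$min_int)) {
    # only missing numeric values seen
    wt_column(name, "int", 1L, num_elements)
  } else if (stats$min_int >= 0) {
    wt_column(name, "uint", smallest_uint_size(stats$max_int), num_elements)
  } else {
    wt_column(name, "int", smallest_int_size(stats$min_int, stats$max_int),
              num_elements)
  }
}
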