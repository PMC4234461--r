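#' Write-once read-many tables
#'
#' A table is a directory holding a sequential binary data file (`rows.dat`),
#' a row-pointer database (`rowindex.db`) mapping the 8-byte big-endian row
#' position to the row's (offset, length), the schema (`schema.xml`),
#' table metadata (`metadata.xml`) and one `index_<name>.db` per secondary
#' index. Tables are built once with [wt_create()] / [wt_append()] /
#' [wt_finalise()] and thereafter only read; every file is big-endian
#' canonical, so a table directory can be copied byte-for-byte between
#' machines of any architecture.
#'
#' @name wtab-tables
NULL

FORMAT_VERSION <- "1.0"

table_paths <- function(dir) {
  list(schema = file.path(dir, "schema.xml"),
       data = file.path(dir, "rows.dat"),
       rowindex = file.path(dir, "rowindex.db"),
       metadata = file.path(dir, "metadata.xml"))
}

index_db_path <- function(dir, name) file.path(dir, paste0("index_", name, ".db"))

#' Create a new table for building
#'
#' Refuses to touch a non-empty directory: tables are write-once, and an
#' existing table can never be overwritten in place.
#'
#' @param dir Directory to create the table in; must not exist or be empty.
#' @param schema A [wt_schema()].
#' @return A builder object of class `wt_builder`; pass it to [wt_append()]
#'   then [wt_finalise()].
#' @export
wt_create <- function(dir, schema) {
  if (!inherits(schema, "wt_schema")) stop("schema must be a wt_schema",
                                           call. = FALSE)
  if (dir.exists(dir)) {
    if (length(list.files(dir, all.files = TRUE, no.. = TRUE)))
      stop("directory '", dir, "' is not empty; tables are write-once",
           call. = FALSE)
  } else if (!dir.create(dir, recursive = TRUE)) {
    stop("cannot create table directory '", dir, "'", call. = FALSE)
  }
  paths <- table_paths(dir)
  writeChar(write_schema_xml(schema), paths$schema, eos = NULL)
  b <- new.env(parent = emptyenv())
  b$dir <- dir
  b$schema <- schema
  b$layout <- compute_layout(schema)
  b$con <- file(paths$data, "wb")
  b$num_rows <- 0
  b$offset <- 0
  b$offsets <- numeric(0)
  b$lengths <- numeric(0)
  b$finalised <- FALSE
  class(b) <- "wt_builder"
  b
}

check_building <- function(builder) {
  if (!inherits(builder, "wt_builder") || builder$finalised)
    stop("builder is not in BUILDING mode (already finalised?)",
         call. = FALSE)
}

#' Append a row to a table under construction
#'
#' @param builder A [wt_create()] builder.
#' @param values List of cell values, one per schema column.
#' @return The 0-based row position, invisibly. Positions are dense and
#'   sequential.
#' @export
wt_append <- function(builder, values) {
  check_building(builder)
  row <- encode_row(builder$schema, builder$layout, values)
  writeBin(row, builder$con)
  pos <- builder$num_rows
  builder$offsets <- c(builder$offsets, builder$offset)
  builder$lengths <- c(builder$lengths, length(row))
  builder$offset <- builder$offset + length(row)
  builder$num_rows <- pos + 1
  invisible(pos)
}

write_metadata_xml <- function(dir, num_rows, indexes) {
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             sprintf("<metadata version=\"%s\" num_rows=\"%s\">",
                     FORMAT_VERSION, format(num_rows, scientific = FALSE)),
             "  <indexes>")
  for (ix in indexes) {
    bins <- if (is.null(ix$bins)) "" else
      paste(vapply(ix$bins, function(b) if (is.na(b)) "NA" else
        format(b, scientific = FALSE), ""), collapse = ",")
    lines <- c(lines, sprintf("    <index name=\"%s\" bins=\"%s\"/>",
                              ix$name, bins))
  }
  txt <- paste0(paste(c(lines, "  </indexes>", "</metadata>"),
                      collapse = "\n"), "\n")
  writeChar(txt, file.path(dir, "metadata.xml"), eos = NULL)
}

read_metadata_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("cannot read table metadata '", path, "': ", conditionMessage(e),
         call. = FALSE))
  num_rows <- as.numeric(xml2::xml_attr(doc, "num_rows"))
  if (is.na(num_rows)) stop("metadata missing num_rows", call. = FALSE)
  nodes <- xml2::xml_find_all(doc, "./indexes/index")
  indexes <- lapply(nodes, function(nd) {
    name <- xml2::xml_attr(nd, "name")
    bins_s <- xml2::xml_attr(nd, "bins")
    bins <- if (is.na(bins_s) || !nzchar(bins_s)) NULL else
      suppressWarnings(as.numeric(strsplit(bins_s, ",", fixed = TRUE)[[1L]]))
    list(name = name, bins = bins)
  })
  names(indexes) <- vapply(indexes, function(ix) ix$name, "")
  list(num_rows = num_rows, version = xml2::xml_attr(doc, "version"),
       indexes = indexes)
}

#' Finalise a table
#'
#' Persists the row-pointer database and metadata, closes the data file and
#' returns a read-only handle. The builder is unusable afterwards.
#'
#' @param builder A [wt_create()] builder.
#' @return A read-only `wt_table` handle.
#' @export
wt_finalise <- function(builder) {
  check_building(builder)
  close(builder$con)
  builder$finalised <- TRUE
  paths <- table_paths(builder$dir)
  n <- builder$num_rows
  keys <- character(n)
  values <- vector("list", n)
  for (i in seq_len(n)) {
    keys[i] <- raw_to_hex(uint_to_be(i - 1, 8L))
    values[[i]] <- c(uint_to_be(builder$offsets[i], 8L),
                     uint_to_be(builder$lengths[i], 4L))
  }
  kv_write(paths$rowindex, keys, values, sorted = TRUE)
  write_metadata_xml(builder$dir, n, list())
  wt_open(builder$dir)
}

#' Open a finalised table read-only
#'
#' @param dir A table directory written by [wt_finalise()] (possibly copied
#'   from another machine; the format is architecture-independent).
#' @return A `wt_table` handle.
#' @export
wt_open <- function(dir) {
  paths <- table_paths(dir)
  for (p in c(paths$schema, paths$data, paths$rowindex, paths$metadata))
    if (!file.exists(p))
      stop("'", dir, "' is not a finalised table (missing ", basename(p),
           ")", call. = FALSE)
  schema <- parse_schema_xml(paste(readLines(paths$schema, warn = FALSE),
                                   collapse = "\n"))
  meta <- read_metadata_xml(paths$metadata)
  kv <- kv_read(paths$rowindex)
  if (kv$n != meta$num_rows)
    stop("row index has ", kv$n, " entries but metadata claims ",
         meta$num_rows, " rows", call. = FALSE)
  offsets <- vapply(kv$values, function(v) be_to_uint(v[1:8]), 0)
  lengths <- vapply(kv$values, function(v) be_to_uint(v[9:12]), 0)
  structure(list(dir = dir, schema = schema, layout = compute_layout(schema),
                 num_rows = kv$n, offsets = offsets, lengths = lengths,
                 indexes = meta$indexes, mode = "READ_ONLY"),
            class = "wt_table")
}

#' @export
print.wt_table <- function(x, ...) {
  cat("wt_table at '", x$dir, "': ", format(x$num_rows, scientific = FALSE),
      " rows, ", length(x$schema$columns), " columns\n", sep = "")
  ix <- names(x$indexes)
  if (length(ix)) cat("indexes:", paste(ix, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.wt_table <- function(x) x$num_rows

resolve_position <- function(table, position) {
  n <- table$num_rows
  if (position < 0) position <- position + n
  if (is.na(position) || position < 0 || position >= n)
    stop("row position out of range [", -n, ", ", n, ")", call. = FALSE)
  position
}

read_row_bytes <- function(con, offset, length) {
  seek(con, where = offset, origin = "start")
  readBin(con, "raw", n = length)
}

#' Fetch one row by position
#'
#' Positions are 0-based; negative positions count from the end, mirroring
#' sequence indexing.
#'
#' @param table A `wt_table`.
#' @param position Row position in `[-num_rows, num_rows)`.
#' @return The full decoded row as a named list.
#' @export
wt_row <- function(table, position) {
  i <- resolve_position(table, position) + 1
  con <- file(table_paths(table$dir)$data, "rb")
  on.exit(close(con))
  row <- read_row_bytes(con, table$offsets[i], table$lengths[i])
  decode_row(table$schema, table$layout, row)
}

#' @export
`[[.wt_table` <- function(x, i) wt_row(x, i)

#' Sequential cursor over a row range
#'
#' Iterates rows `start, start+1, ..., stop-1` (half-open, 0-based) and
#' decodes only the requested columns — the fixed-region bytes of other
#' columns are never touched.
#'
#' @param table A `wt_table`.
#' @param columns Character vector of column names to project, in the order
#'   wanted; `NULL` means all columns.
#' @param start,stop Half-open 0-based row range; defaults cover the whole
#'   table. `start == stop` yields an empty result.
#' @return A list of projected rows (each a named list).
#' @export
wt_cursor <- function(table, columns = NULL, start = 0, stop = table$num_rows) {
  if (start < 0 || stop > table$num_rows)
    stop("cursor range [", start, ", ", stop, ") outside table of ",
         table$num_rows, " rows", call. = FALSE)
  if (!is.null(columns)) {
    if (length(columns) == 0L) stop("columns must be nonempty", call. = FALSE)
    bad <- setdiff(columns, schema_names(table$schema))
    if (length(bad)) stop("unknown column: '", bad[1L], "'", call. = FALSE)
  }
  if (start >= stop) return(list())
  idx <- seq.int(start + 1, stop)
  con <- file(table_paths(table$dir)$data, "rb")
  on.exit(close(con))
  lapply(idx, function(i) {
    row <- read_row_bytes(con, table$offsets[i], table$lengths[i])
    decode_row(table$schema, table$layout, row, columns)
  })
}

# fetch a set of rows by 0-based positions (index cursors use this)
fetch_rows <- function(table, positions, columns = NULL) {
  con <- file(table_paths(table$dir)$data, "rb")
  on.exit(close(con))
  lapply(positions + 1, function(i) {
    row <- read_row_bytes(con, table$offsets[i], table$lengths[i])
    decode_row(table$schema, table$layout, row, columns)
  })
}
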