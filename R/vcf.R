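# VCF 4.x conversion: header-driven schema generation, line parsing, and the
# two-pass build that picks the smallest type for each column.

# Parse ##INFO=<...> / ##FORMAT=<...> meta lines and the #CHROM column line.
parse_vcf_meta <- function(header_lines) {
  parse_def <- function(line, scope) {
    body <- sub("^##(INFO|FORMAT)=<", "", line)
    body <- sub(">\\s*$", "", body)
    # split on commas outside quotes
    chars <- strsplit(body, "")[[1L]]
    inq <- FALSE
    cut <- integer(0)
    for (i in seq_along(chars)) {
      if (chars[i] == "\"") inq <- !inq
      else if (chars[i] == "," && !inq) cut <- c(cut, i)
    }
    parts <- substring(body, c(1L, cut + 1L), c(cut - 1L, nchar(body)))
    kv <- regmatches(parts, regexec("^([A-Za-z]+)=(.*)$", parts))
    fields <- stats::setNames(
      vapply(kv, function(m) if (length(m)) m[3L] else "", ""),
      vapply(kv, function(m) if (length(m)) m[2L] else "", ""))
    if (!all(c("ID", "Type") %in% names(fields)))
      stop("malformed ", scope, " header line: ", line, call. = FALSE)
    list(id = fields[["ID"]],
         number = if ("Number" %in% names(fields)) fields[["Number"]] else ".",
         vtype = fields[["Type"]], scope = scope)
  }
  infos <- list(); formats <- list(); samples <- character(0)
  saw_chrom <- FALSE
  for (line in header_lines) {
    if (startsWith(line, "##INFO=<")) {
      d <- parse_def(line, "INFO")
      if (d$id %in% names(infos))
        stop("duplicate INFO id '", d$id, "' in VCF header", call. = FALSE)
      infos[[d$id]] <- d
    } else if (startsWith(line, "##FORMAT=<")) {
      d <- parse_def(line, "FORMAT")
      formats[[d$id]] <- d
    } else if (startsWith(line, "#CHROM")) {
      saw_chrom <- TRUE
      f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      if (length(f) > 9L) samples <- f[10:length(f)]
    }
  }
  if (!saw_chrom)
    stop("VCF header has no #CHROM column line", call. = FALSE)
  for (d in infos) {
    if (d$vtype == "Flag" && d$number != "0")
      stop("INFO Flag '", d$id, "' must have Number=0", call. = FALSE)
  }
  list(infos = infos, formats = formats, samples = samples)
}

vcf_num_elements <- function(number) {
  if (grepl("^[0-9]+$", number)) {
    n <- as.integer(number)
    if (n == 0L) 1L else n          # Flag: one uint1 element
  } else WT_VARIABLE                # A / G / R / .
}

# column spec for a typed VCF field, optionally sized from pass-1 stats
vcf_field_column <- function(name, vtype, number, stats = NULL,
                             float_size = 4L) {
  ne <- vcf_num_elements(number)
  switch(vtype,
    Integer = {
      col <- if (is.null(stats) || stats$n_values == 0)
        wt_column(name, "int", 4L)
      else infer_column_spec(name, "int", stats)
      wt_column(name, col$ctype, col$element_size, ne)
    },
    Float = wt_column(name, "float", as.integer(float_size), ne),
    Flag = wt_column(name, "uint", 1L, 1L),
    String = ,
    Character = wt_column(name, "char", 1L, WT_VARIABLE),
    stop("unknown VCF field Type '", vtype, "'", call. = FALSE))
}

#' Derive a table schema from a VCF header
#'
#' Produces, in order: the seven fixed VCF columns (CHROM, POS, ID, REF, ALT,
#' QUAL, FILTER), one `INFO.<ID>` column per INFO definition, then one
#' `<sample>.<ID>` column per sample and FORMAT definition. `Number=n` maps
#' to a fixed element count, `A`/`G`/`R`/`.` to variable; `Integer` maps to
#' the smallest integer type covering the supplied statistics (signed only if
#' negatives were seen), `Float` to IEEE single by default, `Flag` to a
#' one-byte indicator (1 = present, missing = absent), `String`/`Character`
#' to variable-length char. Multi-valued string fields (including ALT) are
#' stored comma-joined.
#'
#' @param header_lines Character vector: the `##` meta lines and the `#CHROM`
#'   line of a VCF 4.x file.
#' @param sample_names Sample names; defaults to those on the `#CHROM` line.
#' @param stats Optional named list of [new_column_stats()] accumulated over a
#'   first pass, keyed by column name; absent entries fall back to 4-byte
#'   defaults.
#' @param float_size Element size for Float columns and QUAL (2, 4 or 8).
#' @param extra_info IDs of INFO keys seen in data but absent from the header;
#'   appended as variable char columns.
#' @return A [wt_schema()].
#' @export
vcf_header_to_schema <- function(header_lines, sample_names = NULL,
                                 stats = NULL, float_size = 4L,
                                 extra_info = character(0)) {
  meta <- parse_vcf_meta(header_lines)
  if (is.null(sample_names)) sample_names <- meta$samples
  st <- function(nm) if (!is.null(stats)) stats[[nm]] else NULL
  pos_stats <- st("POS")
  pos <- if (is.null(pos_stats) || pos_stats$n_values == 0)
    wt_column("POS", "uint", 4L)
  else wt_column("POS", "uint", smallest_uint_size(pos_stats$max_int))
  columns <- list(
    wt_column("CHROM", "char", 1L, WT_VARIABLE),
    pos,
    wt_column("ID", "char", 1L, WT_VARIABLE),
    wt_column("REF", "char", 1L, WT_VARIABLE),
    wt_column("ALT", "char", 1L, WT_VARIABLE,
              description = "alternate alleles, comma-joined"),
    wt_column("QUAL", "float", as.integer(float_size)),
    wt_column("FILTER", "char", 1L, WT_VARIABLE))
  for (d in meta$infos) {
    nm <- paste0("INFO.", d$id)
    columns[[length(columns) + 1L]] <-
      vcf_field_column(nm, d$vtype, d$number, st(nm), float_size)
  }
  for (id in extra_info) {
    columns[[length(columns) + 1L]] <-
      wt_column(paste0("INFO.", id), "char", 1L, WT_VARIABLE,
                description = "INFO key not declared in header")
  }
  for (s in sample_names) {
    for (d in meta$formats) {
      nm <- paste0(s, ".", d$id)
      columns[[length(columns) + 1L]] <-
        vcf_field_column(nm, d$vtype, d$number, st(nm), float_size)
    }
  }
  wt_schema(columns)
}

# Parsing plan: how each schema column is filled from a VCF data line.
vcf_parse_plan <- function(meta, extra_info = character(0)) {
  plan <- list(
    list(kind = "chrom"), list(kind = "pos"), list(kind = "id"),
    list(kind = "ref"), list(kind = "alt"), list(kind = "qual"),
    list(kind = "filter"))
  for (d in meta$infos)
    plan[[length(plan) + 1L]] <- list(kind = "info", id = d$id,
                                      vtype = d$vtype)
  for (id in extra_info)
    plan[[length(plan) + 1L]] <- list(kind = "info", id = id,
                                      vtype = "String")
  for (si in seq_along(meta$samples)) {
    for (d in meta$formats)
      plan[[length(plan) + 1L]] <- list(kind = "format", id = d$id,
                                        vtype = d$vtype, sample = si)
  }
  plan
}

vcf_number <- function(s, what, line_no = NA) {
  v <- suppressWarnings(as.numeric(s))
  bad <- is.na(v) & s != "." & s != ""
  if (any(bad))
    stop("cannot parse ", what, " value '", s[bad][1L], "'",
         if (!is.na(line_no)) paste0(" at line ", line_no), call. = FALSE)
  v
}

vcf_typed_values <- function(s, vtype, what, line_no = NA) {
  if (s == "." || s == "") return(NA)
  parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
  if (vtype %in% c("Integer", "Float")) vcf_number(parts, what, line_no)
  else parts
}

#' Parse one VCF data line into cell values
#'
#' Applies the VCF missing-value rules: `.` maps to MISSING wherever the
#' format permits it, multi-valued fields split on `,`, INFO flags map to 1
#' when present and MISSING when absent, and INFO keys or FORMAT fields
#' absent from a record map to MISSING.
#'
#' @param line A tab-separated VCF data line.
#' @param meta Parsed header metadata (internal; produced by the converter).
#' @param plan Parsing plan matching the schema (internal).
#' @param line_no Line number for error messages.
#' @return A list of cell values, one per schema column; multi-valued string
#'   fields come back as character vectors.
#' @keywords internal
parse_vcf_record <- function(line, meta, plan = vcf_parse_plan(meta),
                             line_no = NA) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  n_samples <- length(meta$samples)
  expected <- if (n_samples > 0L) 9L + n_samples else 8L
  if (length(f) != expected)
    stop("VCF record has ", length(f), " fields, expected ", expected,
         if (!is.na(line_no)) paste0(" (line ", line_no, ")"), call. = FALSE)
  # INFO key/value pairs
  info <- list()
  if (f[8L] != ".") {
    for (ent in strsplit(f[8L], ";", fixed = TRUE)[[1L]]) {
      eq <- regexpr("=", ent, fixed = TRUE)
      if (eq > 0L) info[[substr(ent, 1L, eq - 1L)]] <-
          substr(ent, eq + 1L, nchar(ent))
      else info[[ent]] <- TRUE
    }
  }
  fmt_keys <- if (n_samples > 0L) strsplit(f[9L], ":", fixed = TRUE)[[1L]]
              else character(0)
  sample_fields <- if (n_samples > 0L)
    lapply(f[10:(9L + n_samples)], function(s)
      strsplit(s, ":", fixed = TRUE)[[1L]])
  else list()
  lapply(plan, function(p) {
    switch(p$kind,
      chrom = f[1L],
      pos = vcf_number(f[2L], "POS", line_no),
      id = if (f[3L] == ".") NA_character_ else f[3L],
      ref = f[4L],
      alt = if (f[5L] == ".") NA_character_
            else strsplit(f[5L], ",", fixed = TRUE)[[1L]],
      qual = vcf_number(f[6L], "QUAL", line_no),
      filter = if (f[7L] == ".") NA_character_ else f[7L],
      info = {
        v <- info[[p$id]]
        if (is.null(v)) NA
        else if (isTRUE(v)) 1          # Flag present
        else vcf_typed_values(v, p$vtype, paste0("INFO.", p$id), line_no)
      },
      format = {
        ki <- match(p$id, fmt_keys)
        sf <- sample_fields[[p$sample]]
        if (is.na(ki) || ki > length(sf)) NA
        else vcf_typed_values(sf[ki], p$vtype,
                              paste0(meta$samples[p$sample], ".", p$id),
                              line_no)
      })
  })
}

# join multi-valued strings for char columns; numerics pass through
prepare_cell <- function(col, value) {
  if (col$ctype == "char" && length(value) > 1L)
    paste(value, collapse = ",")
  else value
}

# stream a text or gzip file, calling fn(lines, first_line_no) per chunk
for_each_chunk <- function(path, fn, chunk = 4096L) {
  con <- gzfile(path, "rt")    # reads plain text transparently
  on.exit(close(con))
  line_no <- 0L
  repeat {
    lines <- readLines(con, n = chunk, warn = FALSE)
    if (length(lines) == 0L) break
    fn(lines, line_no + 1L)
    line_no <- line_no + length(lines)
  }
  invisible(line_no)
}

#' Convert a VCF file to a table
#'
#' By default the conversion is two-pass: the first pass accumulates
#' per-column statistics and discovers INFO keys missing from the header, the
#' second builds the table using the smallest type that represents each
#' column's observed values. With `single_pass = TRUE` integer columns get
#' fixed 4-byte defaults and undeclared INFO keys are an error. Row order
#' equals file order; gzip input yields a byte-identical table to the
#' equivalent plain-text input.
#'
#' @param vcf_path Path to a VCF 4.x file, plain or gzip-compressed.
#' @param out_dir Directory for the new table (must not already hold one).
#' @param single_pass Skip the statistics pass and use default sizes.
#' @param float_size Element size for Float columns and QUAL (2, 4 or 8).
#' @return The finalised `wt_table`.
#' @export
vcf_to_table <- function(vcf_path, out_dir, single_pass = FALSE,
                         float_size = 4L) {
  header_lines <- character(0)
  meta <- NULL
  extra_info <- character(0)
  stats <- NULL
  int_plan_cols <- character(0)

  # pass 1 (or header-only scan in single-pass mode)
  stats_env <- new.env(parent = emptyenv())
  scan_pass <- function(lines, first_no) {
    for (k in seq_along(lines)) {
      line <- lines[k]
      if (startsWith(line, "#")) {
        if (is.null(meta)) header_lines <<- c(header_lines, line)
        if (startsWith(line, "#CHROM")) meta <<- parse_vcf_meta(header_lines)
        next
      }
      if (is.null(meta))
        stop("VCF data line before #CHROM header (line ", first_no + k - 1L,
             ")", call. = FALSE)
      if (single_pass) next
      f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 8L)
        stop("short VCF record at line ", first_no + k - 1L, call. = FALSE)
      obs <- function(nm, value) {
        if (is.null(stats_env[[nm]])) stats_env[[nm]] <- new_column_stats()
        stats_observe(stats_env[[nm]], value)
      }
      obs("POS", vcf_number(f[2L], "POS", first_no + k - 1L))
      if (f[8L] != ".") {
        for (ent in strsplit(f[8L], ";", fixed = TRUE)[[1L]]) {
          eq <- regexpr("=", ent, fixed = TRUE)
          id <- if (eq > 0L) substr(ent, 1L, eq - 1L) else ent
          d <- meta$infos[[id]]
          if (is.null(d)) {
            if (!(id %in% extra_info)) extra_info <<- c(extra_info, id)
          } else if (d$vtype == "Integer" && eq > 0L) {
            obs(paste0("INFO.", id),
                vcf_typed_values(substr(ent, eq + 1L, nchar(ent)), "Integer",
                                 id, first_no + k - 1L))
          }
        }
      }
      if (length(meta$samples) && length(f) >= 10L) {
        fmt_keys <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
        int_keys <- fmt_keys[vapply(fmt_keys, function(id) {
          d <- meta$formats[[id]]
          !is.null(d) && d$vtype == "Integer"
        }, TRUE)]
        if (length(int_keys)) {
          for (si in seq_along(meta$samples)) {
            sf <- strsplit(f[9L + si], ":", fixed = TRUE)[[1L]]
            for (id in int_keys) {
              ki <- match(id, fmt_keys)
              if (ki <= length(sf))
                obs(paste0(meta$samples[si], ".", id),
                    vcf_typed_values(sf[ki], "Integer", id,
                                     first_no + k - 1L))
            }
          }
        }
      }
    }
  }
  for_each_chunk(vcf_path, scan_pass)
  if (is.null(meta))
    stop("'", vcf_path, "' has no #CHROM header line", call. = FALSE)
  stats <- as.list(stats_env)

  schema <- vcf_header_to_schema(header_lines, stats = stats,
                                 float_size = float_size,
                                 extra_info = extra_info)
  plan <- vcf_parse_plan(meta, extra_info)
  builder <- wt_create(out_dir, schema)
  ok <- FALSE
  on.exit(if (!ok && !builder$finalised) close(builder$con))
  build_pass <- function(lines, first_no) {
    for (k in seq_along(lines)) {
      line <- lines[k]
      if (startsWith(line, "#")) next
      values <- parse_vcf_record(line, meta, plan, first_no + k - 1L)
      cells <- Map(prepare_cell, schema$columns, values)
      wt_append(builder, cells)
    }
  }
  for_each_chunk(vcf_path, build_pass)
  tab <- wt_finalise(builder)
  ok <- TRUE
  tab
}
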