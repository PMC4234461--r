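# GTF conversion: 9 tab-separated fields per record, with gene_id and
# transcript_id extracted from the free-form attributes field.

gtf_extract_attr <- function(attributes, key) {
  m <- regexec(paste0(key, "\\s+\"([^\"]*)\""), attributes)[[1L]]
  if (m[1L] == -1L) NA_character_
  else substr(attributes, m[2L], m[2L] + attr(m, "match.length")[2L] - 1L)
}

parse_gtf_record <- function(line, line_no = NA) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) != 9L)
    stop("GTF record has ", length(f), " fields, expected 9",
         if (!is.na(line_no)) paste0(" (line ", line_no, ")"), call. = FALSE)
  start <- vcf_number(f[4L], "start", line_no)
  end <- vcf_number(f[5L], "end", line_no)
  if (is.na(start) || is.na(end) || start > end)
    stop("GTF record with invalid coordinates ", f[4L], "..", f[5L],
         if (!is.na(line_no)) paste0(" (line ", line_no, ")"), call. = FALSE)
  list(seqname = f[1L], source = f[2L], feature = f[3L],
       start = start, end = end,
       score = if (f[6L] == ".") NA_real_ else vcf_number(f[6L], "score",
                                                          line_no),
       strand = f[7L],
       frame = if (f[8L] == ".") NA_real_ else vcf_number(f[8L], "frame",
                                                          line_no),
       gene_id = gtf_extract_attr(f[9L], "gene_id"),
       transcript_id = gtf_extract_attr(f[9L], "transcript_id"),
       attributes = f[9L])
}

#' Convert a GTF file to a table
#'
#' Columns: `seqname`, `source`, `feature` (variable char), `start`, `end`
#' (unsigned integers, smallest size covering the data), `score` (single
#' float, missing for `.`), `strand` (one char), `frame` (1-byte unsigned,
#' missing for `.`), `gene_id` and `transcript_id` (extracted from the
#' attributes field) and the raw `attributes` string. Lines starting with
#' `#` are skipped; every other line must have exactly 9 tab-separated
#' fields.
#'
#' @param gtf_path Path to a GTF file, plain or gzip-compressed.
#' @param out_dir Directory for the new table.
#' @return The finalised `wt_table`.
#' @export
gtf_to_table <- function(gtf_path, out_dir) {
  max_coord <- 0
  for_each_chunk(gtf_path, function(lines, first_no) {
    for (k in seq_along(lines)) {
      if (startsWith(lines[k], "#")) next
      r <- parse_gtf_record(lines[k], first_no + k - 1L)
      max_coord <<- max(max_coord, r$end)
    }
  })
  coord_size <- smallest_uint_size(max(max_coord, 1))
  schema <- wt_schema(list(
    wt_column("seqname", "char", 1L, WT_VARIABLE),
    wt_column("source", "char", 1L, WT_VARIABLE),
    wt_column("feature", "char", 1L, WT_VARIABLE),
    wt_column("start", "uint", coord_size),
    wt_column("end", "uint", coord_size),
    wt_column("score", "float", 4L),
    wt_column("strand", "char", 1L, 1L),
    wt_column("frame", "uint", 1L),
    wt_column("gene_id", "char", 1L, WT_VARIABLE),
    wt_column("transcript_id", "char", 1L, WT_VARIABLE),
    wt_column("attributes", "char", 1L, WT_VARIABLE)))
  builder <- wt_create(out_dir, schema)
  ok <- FALSE
  on.exit(if (!ok && !builder$finalised) close(builder$con))
  for_each_chunk(gtf_path, function(lines, first_no) {
    for (k in seq_along(lines)) {
      if (startsWith(lines[k], "#")) next
      r <- parse_gtf_record(lines[k], first_no + k - 1L)
      wt_append(builder, unname(r))
    }
  })
  tab <- wt_finalise(builder)
  ok <- TRUE
  tab
}
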