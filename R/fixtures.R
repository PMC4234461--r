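# Deterministic fixture generators: toy VCF/GTF files and random
# schema/row sets for the property suites. All randomness goes through R's
# Mersenne-Twister with explicitly pinned sampling kinds, so a given seed
# produces identical bytes on any platform; the caller's RNG state is
# restored afterwards.

run_seeded <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  fn()
}

#' Generate a toy VCF file
#'
#' Emits a small, valid VCF 4.1 text with a configurable number of variant
#' rows and samples: five INFO fields (DP, MQ, AC, AF, DB) and two FORMAT
#' fields (GT, GQ), positions strictly increasing within each chromosome,
#' REF/ALT mostly single nucleotides with occasional indels and
#' multi-allelic sites, and sporadic missing values. Output is byte-identical
#' for equal arguments. The generator emulates the *format-level* shape of a
#' resequencing call set; it makes no attempt at realistic population
#' structure.
#'
#' @param num_rows Number of variant records.
#' @param num_samples Number of samples (0 for a site-only VCF).
#' @param seed RNG seed.
#' @param chromosomes Chromosome names to draw from.
#' @param max_pos Largest possible position.
#' @param indel_rate Fraction of rows whose REF or ALT is a multi-base
#'   allele.
#' @return Character vector of VCF lines.
#' @export
generate_toy_vcf <- function(num_rows = 100L, num_samples = 3L, seed = 1L,
                             chromosomes = c("2L", "2R", "3L", "3R", "X"),
                             max_pos = 1000000L, indel_rate = 0.1) {
  run_seeded(seed, function() {
    samples <- if (num_samples > 0L) sprintf("NA%04d", seq_len(num_samples))
               else character(0)
    header <- c(
      "##fileformat=VCFv4.1",
      "##source=toy-fixture-generator",
      "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
      "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
      "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele counts\">",
      "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequencies\">",
      "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"In a database\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              if (num_samples > 0L) c("FORMAT", samples)), collapse = "\t"))
    if (num_rows == 0L) return(header)
    bases <- c("A", "C", "G", "T")
    chrom <- sort(factor(sample(chromosomes, num_rows, replace = TRUE),
                         levels = chromosomes))
    pos <- unlist(lapply(split(seq_len(num_rows), chrom), function(idx) {
      sort(sample.int(max_pos, length(idx)))
    }), use.names = FALSE)
    rows <- character(num_rows)
    for (i in seq_len(num_rows)) {
      ref <- sample(bases, 1L)
      n_alt <- sample(c(1L, 1L, 1L, 2L), 1L)
      alt <- sample(setdiff(bases, ref), n_alt)
      if (runif(1) < indel_rate) {
        # turn the site into an indel: extend REF or the first ALT
        ext <- paste(sample(bases, sample(1:3, 1L), replace = TRUE),
                     collapse = "")
        if (runif(1) < 0.5) ref <- paste0(ref, ext)
        else alt[1L] <- paste0(alt[1L], ext)
      }
      qual <- if (runif(1) < 0.05) "." else
        format(round(runif(1, 1, 1000), 1), nsmall = 1)
      filter <- sample(c("PASS", "PASS", "PASS", "q10"), 1L)
      info <- c(
        if (runif(1) < 0.9) paste0("DP=", sample.int(250, 1L)),
        if (runif(1) < 0.8) paste0("MQ=", format(round(runif(1, 10, 60), 2),
                                                 nsmall = 2)),
        paste0("AC=", paste(sample.int(20, n_alt, replace = TRUE),
                            collapse = ",")),
        paste0("AF=", paste(format(round(runif(n_alt), 3), nsmall = 3),
                            collapse = ",")),
        if (runif(1) < 0.3) "DB")
      fields <- c(as.character(chrom[i]), format(pos[i], scientific = FALSE),
                  if (runif(1) < 0.2) sprintf("rs%06d", sample.int(999999, 1L))
                  else ".",
                  ref, paste(alt, collapse = ","), qual, filter,
                  paste(info, collapse = ";"))
      if (num_samples > 0L) {
        gts <- vapply(seq_len(num_samples), function(s) {
          if (runif(1) < 0.05) "./.:."
          else paste0(sample(c("0/0", "0/1", "1/1"), 1L), ":",
                      sample.int(99, 1L))
        }, "")
        fields <- c(fields, "GT:GQ", gts)
      }
      rows[i] <- paste(fields, collapse = "\t")
    }
    c(header, rows)
  })
}

#' Generate a toy GTF file
#'
#' Nested gene models: each gene has 1--2 transcripts of 1--4 exons (plus CDS
#' lines carrying a reading frame), with start <= end throughout and 9
#' tab-separated fields per line. Deterministic per seed.
#'
#' @param num_genes Number of genes.
#' @param seed RNG seed.
#' @param chromosomes Chromosome names to draw from.
#' @return Character vector of GTF lines.
#' @export
generate_toy_gtf <- function(num_genes = 10L, seed = 1L,
                             chromosomes = c("2L", "2R", "3L")) {
  run_seeded(seed, function() {
    lines <- c("#!genome-build toy-1", "#!genome-version toy")
    at <- 1000L
    for (g in seq_len(num_genes)) {
      chr <- sample(chromosomes, 1L)
      gid <- sprintf("TG%07d", g)
      for (t in seq_len(sample(1:2, 1L))) {
        tid <- sprintf("%s.t%d", gid, t)
        strand <- sample(c("+", "-"), 1L)
        n_exon <- sample(1:4, 1L)
        ex_start <- at + cumsum(sample.int(500L, n_exon))
        ex_len <- sample.int(300L, n_exon)
        attrs <- sprintf("gene_id \"%s\"; transcript_id \"%s\";", gid, tid)
        lines <- c(lines, paste(
          c(chr, "toy", "transcript", min(ex_start),
            max(ex_start + ex_len), ".", strand, ".", attrs),
          collapse = "\t"))
        for (e in seq_len(n_exon)) {
          score <- if (runif(1) < 0.5) "." else
            format(round(runif(1, 0, 100), 2), nsmall = 2)
          lines <- c(lines, paste(
            c(chr, "toy", "exon", ex_start[e], ex_start[e] + ex_len[e],
              score, strand, ".", attrs), collapse = "\t"))
          if (runif(1) < 0.6) {
            lines <- c(lines, paste(
              c(chr, "toy", "CDS", ex_start[e], ex_start[e] + ex_len[e],
                ".", strand, sample(0:2, 1L), attrs), collapse = "\t"))
          }
        }
        at <- max(ex_start + ex_len) + sample.int(2000L, 1L)
      }
    }
    lines
  })
}

random_column <- function(i) {
  ctype <- sample(c("uint", "int", "float", "char"), 1L)
  name <- sprintf("c%d_%s", i, ctype)
  if (ctype == "char") {
    if (runif(1) < 0.4) wt_column(name, "char", 1L, sample.int(6L, 1L))
    else wt_column(name, "char", 1L, WT_VARIABLE)
  } else {
    es <- if (ctype == "float") sample(c(2L, 4L, 8L), 1L)
          else sample.int(8L, 1L)
    ne <- {
      u <- runif(1)
      if (u < 0.6) 1L else if (u < 0.8) sample(2:3, 1L) else WT_VARIABLE
    }
    wt_column(name, ctype, es, ne)
  }
}

random_numeric_element <- function(col) {
  # edge-biased: missing, range extremes and small values are oversampled so
  # the reserved patterns and widths actually get exercised
  u <- runif(1)
  if (col$ctype == "float") {
    v <- if (u < 0.15) NA_real_
    else if (u < 0.25) 0
    else if (u < 0.35) round(stats::rnorm(1) * 10^sample(-2:3, 1L), 4)
    else stats::rnorm(1)
    float_quantize(v, col$element_size)
  } else {
    r <- int_valid_range(col)
    if (u < 0.15) NA_real_
    else if (u < 0.25) r[1L]
    else if (u < 0.35) r[2L]
    else if (u < 0.45) 0
    else trunc(runif(1, max(r[1L], -1e6), min(r[2L], 1e6)))
  }
}

random_cell <- function(col) {
  if (col$ctype == "char") {
    n <- if (is_variable(col)) {
      if (runif(1) < 0.15) return(NA_character_)
      sample.int(8L, 1L)
    } else col$num_elements
    return(paste(sample(LETTERS, n, replace = TRUE), collapse = ""))
  }
  n <- if (is_variable(col)) {
    if (runif(1) < 0.15) return(NA_real_)
    sample.int(4L, 1L)
  } else col$num_elements
  v <- vapply(seq_len(n), function(j) random_numeric_element(col), 0)
  if (is_variable(col) && all(is.na(v))) return(NA_real_)  # canonical MISSING
  if (n == 1L) v[[1L]] else v
}

#' Generate a random schema and matching rows
#'
#' Drives the property suites: a random schema over all supported types and
#' sizes (including variable-length columns), with values biased towards the
#' edges of each column's valid range, missing values, and empty
#' variable-length payloads. Floats are pre-quantized to their stored
#' precision so round-trips compare exactly.
#'
#' @param seed RNG seed.
#' @param max_columns,max_rows Upper bounds (at least 1); actual counts are
#'   drawn uniformly.
#' @return A list with `schema` (a [wt_schema()]) and `rows` (list of value
#'   lists).
#' @export
random_table <- function(seed, max_columns = 5L, max_rows = 8L) {
  run_seeded(seed, function() {
    ncol <- sample.int(max_columns, 1L)
    schema <- wt_schema(lapply(seq_len(ncol), random_column))
    nrow <- sample.int(max_rows, 1L)
    rows <- lapply(seq_len(nrow), function(i)
      lapply(schema$columns, random_cell))
    list(schema = schema, rows = rows)
  })
}

#' Write the toy fixture files into a directory
#'
#' Convenience wrapper used by the `make-fixtures` command-line script:
#' writes `toy.vcf`, a byte-identical `toy.vcf.gz`, and `toy.gtf`.
#'
#' @param dir Target directory (created if needed).
#' @param seed RNG seed.
#' @param num_rows,num_samples Passed to [generate_toy_vcf()].
#' @return Invisibly, the paths written.
#' @export
write_toy_fixtures <- function(dir, seed = 1L, num_rows = 100L,
                               num_samples = 3L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vcf <- generate_toy_vcf(num_rows = num_rows, num_samples = num_samples,
                          seed = seed)
  gtf <- generate_toy_gtf(seed = seed)
  paths <- file.path(dir, c("toy.vcf", "toy.vcf.gz", "toy.gtf"))
  writeLines(vcf, paths[1L])
  con <- gzfile(paths[2L], "wt")
  writeLines(vcf, con)
  close(con)
  writeLines(gtf, paths[3L])
  invisible(paths)
}
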