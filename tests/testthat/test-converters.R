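toy_header <- function(samples = character(0), extra = character(0)) {
  c("##fileformat=VCFv4.1",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele freq\">",
    "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"dbSNP\">",
    extra,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
}

test_that("VCF headers map to schemas with namespaced columns", {
  s <- vcf_header_to_schema(toy_header())
  nm <- vapply(s$columns, function(c) c$name, "")
  expect_equal(nm[1:7],
               c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER"))
  expect_true(all(c("INFO.DP", "INFO.AF", "INFO.DB") %in% nm))
  dp <- s$columns[[match("INFO.DP", nm)]]
  expect_equal(dp$ctype, "int")       # no stats: 4-byte default
  expect_equal(dp$num_elements, 1L)
  af <- s$columns[[match("INFO.AF", nm)]]
  expect_equal(af$ctype, "float")
  expect_true(is.na(af$num_elements)) # Number=A is variable
  db <- s$columns[[match("INFO.DB", nm)]]
  expect_equal(c(db$ctype, db$element_size), c("uint", "1"))

  s2 <- vcf_header_to_schema(toy_header(samples = c("NA1", "NA2")))
  nm2 <- vapply(s2$columns, function(c) c$name, "")
  expect_true(all(c("NA1.GT", "NA2.GT") %in% nm2))

  expect_error(vcf_header_to_schema("##fileformat=VCFv4.1"), "#CHROM")
  expect_error(vcf_header_to_schema(c(toy_header(),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"again\">")),
    "duplicate INFO")
})

test_that("VCF records parse with the dot-means-missing rules", {
  meta <- wtab:::parse_vcf_meta(toy_header(samples = c("NA1", "NA2")))
  p <- function(line) wtab:::parse_vcf_record(line, meta)
  v <- p("2L\t5000\t.\tA\tG\t31.5\tPASS\tDP=10\tGT\t0/1\t1/1")
  expect_equal(v[[1]], "2L")
  expect_equal(v[[2]], 5000)
  expect_true(is.na(v[[3]]))
  expect_equal(v[[4]], "A")
  expect_equal(v[[5]], "G")
  expect_equal(v[[6]], 31.5)
  expect_equal(v[[7]], "PASS")
  expect_equal(v[[8]], 10)            # INFO.DP
  expect_true(is.na(v[[9]]))          # INFO.AF absent
  expect_true(is.na(v[[10]]))         # INFO.DB flag absent
  expect_equal(v[[11]], "0/1")
  expect_equal(v[[12]], "1/1")

  v <- p("2L\t1\t.\tA\tG,T\t.\tq10\tAF=0.5,0.25;DB\tGT\t./.\t.")
  expect_equal(v[[5]], c("G", "T"))   # ALT splits on comma
  expect_true(is.na(v[[6]]))          # QUAL "."
  expect_equal(v[[9]], c(0.5, 0.25))
  expect_equal(v[[10]], 1)            # flag present
  expect_equal(v[[11]], "./.")
  expect_true(is.na(v[[12]]))

  expect_error(p("2L\t1\tA"), "fields")
  expect_error(p("2L\txx\t.\tA\tG\t.\t.\tDP=1\tGT\t0/1\t0/0"),
               "cannot parse POS")
})

test_that("two-pass conversion infers the smallest integer sizes", {
  lines <- c(toy_header(), sprintf("2L\t%d\t.\tA\tG\t10\tPASS\tDP=%d",
                                   c(100, 5000, 60000), c(3, 200, 17)))
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  tab <- vcf_to_table(f, new_table_dir())
  nm <- schema_names_of(tab$schema)
  dp <- column_of(tab$schema, "INFO.DP")
  expect_equal(dp$ctype, "uint")
  expect_equal(dp$element_size, 1L)   # max 200 fits uint1's [0, 254]
  pos <- column_of(tab$schema, "POS")
  expect_equal(pos$element_size, 2L)  # max 60000 fits uint2's [0, 65534]
  expect_equal(vapply(wt_cursor(tab, "INFO.DP"), `[[`, 0, "INFO.DP"),
               c(3, 200, 17))
  # single-pass keeps 4-byte defaults
  tab2 <- vcf_to_table(f, new_table_dir(), single_pass = TRUE)
  expect_equal(column_of(tab2$schema, "INFO.DP")$element_size, 4L)
})

test_that("undeclared INFO keys become variable char columns", {
  lines <- c(toy_header(), "2L\t10\t.\tA\tC\t5\tPASS\tDP=4;XX=a,b")
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  tab <- vcf_to_table(f, new_table_dir())
  xx <- column_of(tab$schema, "INFO.XX")
  expect_equal(xx$ctype, "char")
  expect_equal(wt_cursor(tab, "INFO.XX")[[1]]$`INFO.XX`, "a,b")
})

test_that("toy VCF converts with full field-level fidelity", {
  vcf_lines <- generate_toy_vcf(num_rows = 100, num_samples = 3, seed = 4)
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines, f)
  tab <- vcf_to_table(f, new_table_dir())
  expect_equal(tab$num_rows, 100)
  src <- do.call(rbind, strsplit(grep("^#", vcf_lines, value = TRUE,
                                      invert = TRUE), "\t", fixed = TRUE))
  rows <- wt_cursor(tab, c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                           "FILTER"))
  for (i in seq_len(nrow(src))) {
    r <- rows[[i]]
    expect_identical(r$CHROM, src[i, 1])
    expect_equal(r$POS, as.numeric(src[i, 2]))
    expect_identical(if (is.na(r$ID)) "." else r$ID, src[i, 3])
    expect_identical(r$REF, src[i, 4])
    expect_identical(r$ALT, src[i, 5])
    if (src[i, 6] == ".") expect_true(is.na(r$QUAL))
    else expect_equal(r$QUAL, as.numeric(src[i, 6]), tolerance = 1e-6)
    expect_identical(r$FILTER, src[i, 7])
  }
})

test_that("conversion agrees with an independent VCF parser", {
  skip_if_not_installed("vcfR")
  vcf_lines <- generate_toy_vcf(num_rows = 60, num_samples = 2, seed = 12)
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines, f)
  oracle <- vcfR::read.vcfR(f, verbose = FALSE)
  tab <- vcf_to_table(f, new_table_dir())
  fix <- oracle@fix
  rows <- wt_cursor(tab, c("CHROM", "POS", "REF", "ALT", "QUAL"))
  expect_equal(tab$num_rows, nrow(fix))
  for (i in seq_len(nrow(fix))) {
    expect_identical(rows[[i]]$CHROM, unname(fix[i, "CHROM"]))
    expect_equal(rows[[i]]$POS, as.numeric(fix[i, "POS"]))
    expect_identical(rows[[i]]$REF, unname(fix[i, "REF"]))
    expect_identical(rows[[i]]$ALT, unname(fix[i, "ALT"]))
    q <- fix[i, "QUAL"]
    if (is.na(q)) expect_true(is.na(rows[[i]]$QUAL))
    else expect_equal(rows[[i]]$QUAL, as.numeric(q), tolerance = 1e-6)
  }
  # genotypes survive as strings
  gt <- vcfR::extract.gt(oracle)
  got_gt <- vapply(wt_cursor(tab, "NA0001.GT"), function(r)
    sub(":.*", "", r$`NA0001.GT`), "")
  want <- unname(gt[, "NA0001"])
  expect_equal(got_gt, ifelse(is.na(want), "./.", want))
})

test_that("gzip input yields a byte-identical table", {
  vcf_lines <- generate_toy_vcf(num_rows = 30, num_samples = 1, seed = 5)
  f1 <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines, f1)
  f2 <- tempfile(fileext = ".vcf.gz")
  con <- gzfile(f2, "wt"); writeLines(vcf_lines, con); close(con)
  d1 <- new_table_dir(); d2 <- new_table_dir()
  vcf_to_table(f1, d1)
  vcf_to_table(f2, d2)
  for (part in c("rows.dat", "rowindex.db", "schema.xml"))
    expect_identical(unname(tools::md5sum(file.path(d1, part))),
                     unname(tools::md5sum(file.path(d2, part))))
})

test_that("GTF files convert with attribute extraction", {
  gtf_lines <- generate_toy_gtf(num_genes = 8, seed = 3)
  f <- tempfile(fileext = ".gtf")
  writeLines(gtf_lines, f)
  tab <- gtf_to_table(f, new_table_dir())
  data_lines <- grep("^#", gtf_lines, value = TRUE, invert = TRUE)
  expect_equal(tab$num_rows, length(data_lines))
  src <- do.call(rbind, strsplit(data_lines, "\t", fixed = TRUE))
  rows <- wt_cursor(tab)
  for (i in seq_len(nrow(src))) {
    r <- rows[[i]]
    expect_identical(r$seqname, src[i, 1])
    expect_equal(r$start, as.numeric(src[i, 4]))
    expect_equal(r$end, as.numeric(src[i, 5]))
    expect_identical(r$strand, src[i, 7])
    if (src[i, 8] == ".") expect_true(is.na(r$frame))
    else expect_equal(r$frame, as.numeric(src[i, 8]))
    expect_match(src[i, 9], r$gene_id, fixed = TRUE)
    expect_identical(r$attributes, src[i, 9])
  }
  expect_equal(
    gtf_to_table(f, new_table_dir()) |> wt_cursor("transcript_id") |>
      vapply(function(r) grepl("^TG", r$transcript_id), TRUE) |> all(),
    TRUE)
  bad <- tempfile(fileext = ".gtf")
  writeLines("chr1\tx\tgene\t1\t100\t.\t+\t.", bad)   # 8 fields
  expect_error(gtf_to_table(bad, new_table_dir()), "9")
})

test_that("transition/transversion counts follow the purine rule", {
  schema <- wt_schema(list(wt_column("REF", "char", 1L, WT_VARIABLE),
                           wt_column("ALT", "char", 1L, WT_VARIABLE)))
  pairs <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"),
                c("T", "C"))
  tab <- build_table(schema, lapply(pairs, as.list))
  expect_equal(count_transitions_transversions(tab), c(ts = 3, tv = 2))
  # multi-allelic and indel handling
  tab2 <- build_table(schema, list(list("A", "G,C"), list("AT", "A"),
                                   list("C", "<DEL>")))
  expect_equal(count_transitions_transversions(tab2), c(ts = 1, tv = 1))
  empty <- build_table(schema, list())
  expect_equal(count_transitions_transversions(empty), c(ts = 0, tv = 0))
  expect_error(count_transitions_transversions(
    build_table(wt_schema(list(wt_column("x", "uint", 1L))),
                list(list(1)))), "REF/ALT")
})

test_that("scan and index routes agree on random call sets", {
  vcf_lines <- generate_toy_vcf(num_rows = 100, num_samples = 0, seed = 21)
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines, f)
  tab <- vcf_to_table(f, new_table_dir())
  scan <- count_transitions_transversions(tab, "scan")
  indexed <- count_transitions_transversions(tab, "index")
  expect_equal(indexed, scan)
  expect_gt(sum(scan), 0)
})
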