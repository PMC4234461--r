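hex <- function(r) paste(sprintf("%02x", as.integer(r)), collapse = "")

acgt_table <- function() {
  schema <- wt_schema(list(wt_column("REF", "char", 1L, 1L),
                           wt_column("POS", "uint", 4L)))
  build_table(schema, list(list("A", 1), list("A", 2), list("G", 3),
                           list("T", 4)))
}

test_that("key encodings are order-preserving concatenations", {
  ref <- wt_column("REF", "char", 1L, 1L)
  expect_equal(hex(wtab:::encode_key_column(ref, NA, "A")), "41")
  chrom <- wt_column("CHROM", "char", 1L, WT_VARIABLE)
  pos <- wt_column("POS", "uint", 4L)
  key <- wtab:::encode_index_key(list(chrom, pos), NULL, list("2L", 5000))
  expect_equal(hex(key), "324c0000001389")     # "2L", NUL, 5000 + 1
  qual <- wt_column("QUAL", "float", 2L)
  key <- wtab:::encode_index_key(list(qual), 0.5, list(1.2))
  expect_equal(hex(key), "8000000000000002")   # bin 2 as biased int8
  # decoding inverts the encoding
  expect_equal(wtab:::decode_index_key(list(chrom, pos), NULL,
                                       wtab:::hex_to_raw("324c0000001389")),
               list(CHROM = "2L", POS = 5000))
  expect_equal(wtab:::decode_index_key(list(qual), 0.5,
                                       wtab:::hex_to_raw("8000000000000002")),
               list(QUAL = 2))
})

test_that("byte order of encoded keys equals value order (isomorphism)", {
  specs <- list(
    list(col = wt_column("u", "uint", 1L),
         vals = c(NA, 0, 1, 7, 253, 254)),
    list(col = wt_column("i", "int", 2L),
         vals = c(NA, -32767, -100, -1, 0, 1, 99, 32767)),
    list(col = wt_column("f", "float", 4L),
         vals = c(NA, -1e6, -1.5, -1e-8, 0, 1e-8, 0.5, 2, 1e6)),
    list(col = wt_column("s", "char", 1L, WT_VARIABLE),
         vals = c(NA, "2", "2L", "2R", "A", "AB", "B")))
  for (sp in specs) {
    enc <- vapply(sp$vals, function(v)
      hex(wtab:::encode_key_column(sp$col, NA, v)), "")
    expect_identical(order(enc, method = "radix"), seq_along(enc),
                     label = paste("order for", sp$col$ctype))
  }
  # binned float column: byte order follows bin ids, negatives included
  qual <- wt_column("q", "float", 4L)
  vals <- c(-3.7, -0.6, -0.3, 0, 0.49, 0.5, 1.2, 9.9)
  enc <- vapply(vals, function(v)
    hex(wtab:::encode_key_column(qual, 0.5, v)), "")
  expect_identical(order(unique(enc), method = "radix"),
                   order(unique(floor(vals / 0.5)), method = "radix"))
})

test_that("bin_value floors onto half-open intervals", {
  expect_equal(bin_value(1.2, 0.5), 2)
  expect_equal(bin_value(-0.3, 0.5), -1)
  expect_equal(bin_value(12345, 1000), 12)
  expect_true(is.na(bin_value(NA, 2)))
  expect_error(bin_value(1, 0), "positive")
  expect_error(bin_value(Inf, 1), "non-finite")
})

test_that("building and querying a single-column index", {
  tab <- acgt_table()
  ix <- wt_index_build(tab, "REF")
  expect_equal(length(ix$positions), 4)
  expect_equal(unlist(lapply(wt_index_keys(ix), `[[`, "REF")),
               c("A", "G", "T"))
  expect_equal(wt_key_count(ix, "A"), 2)
  expect_equal(wt_key_count(ix, "C"), 0)
  expect_error(wt_key_count(ix, list("A", 1)), "full key tuple")
  h <- wt_histogram(ix)
  expect_equal(h$counts, c(2, 1, 1))
  expect_equal(sum(h$counts), tab$num_rows)
  kr <- wt_key_range(ix)
  expect_equal(kr$min$REF, "A")
  expect_equal(kr$max$REF, "T")
  # rebuilding under the same name is refused; removing enables it
  expect_error(wt_index_build(tab, "REF"), "already exists")
  wt_index_remove(tab, "REF")
  expect_error(wt_index_open(tab, "REF"), "no index")
  expect_silent(wt_index_build(tab, "REF"))
})

test_that("binned histograms group values into floor(v/w) bins", {
  schema <- wt_schema(list(wt_column("POS", "uint", 4L)))
  tab <- build_table(schema, list(list(100), list(900), list(1500)))
  ix <- wt_index_build(tab, "POS", bins = 1000)
  h <- wt_histogram(ix)
  expect_equal(unlist(lapply(h$keys, `[[`, "POS")), c(0, 1))
  expect_equal(h$counts, c(2, 1))
  # every row under bin b satisfies b*w <= v < (b+1)*w
  for (i in seq_along(h$counts)) {
    b <- h$keys[[i]]$POS
    rows <- wt_index_cursor(ix, "POS", start = list(b * 1000),
                            stop = list((b + 1) * 1000))
    v <- vapply(rows, `[[`, 0, "POS")
    expect_true(all(v >= b * 1000 & v < (b + 1) * 1000))
  }
  qtab <- build_table(wt_schema(list(wt_column("QUAL", "float", 4L))),
                      list(list(1), list(9), list(15)))
  qix <- wt_index_build(qtab, "QUAL", bins = 10)
  expect_equal(unlist(lapply(wt_index_keys(qix), `[[`, "QUAL")), c(0, 1))
})

test_that("partial-key cursors select chromosome windows", {
  g <- build_genomic_table(500, seed = 99)
  tab <- g$table
  ix <- wt_index_build(tab, c("CHROM", "POS"))
  # whole-chromosome partial key
  rows <- wt_index_cursor(ix, c("CHROM", "POS"),
                          start = list("2L"), stop = list("2R"))
  want <- which(g$chrom == "2L")
  expect_equal(length(rows), length(want))
  expect_equal(vapply(rows, `[[`, 0, "POS"), sort(g$pos[want]))
  expect_true(all(vapply(rows, `[[`, "", "CHROM") == "2L"))
  # 1 kb window
  at <- g$pos[want][1]
  rows <- wt_index_cursor(ix, "POS", start = list("2L", at),
                          stop = list("2L", at + 1000))
  expect_equal(sort(vapply(rows, `[[`, 0, "POS")),
               sort(g$pos[g$chrom == "2L" & g$pos >= at &
                            g$pos < at + 1000]))
  # start == stop is empty; over-long tuples are refused
  expect_equal(wt_index_cursor(ix, "POS", start = list("2L"),
                               stop = list("2L")), list())
  expect_error(wt_index_cursor(ix, "POS", start = list("2L", 1, 2)),
               "longer than")
})

test_that("index cursors equal a brute-force sort and filter", {
  checked <- 0
  seed <- 0
  while (checked < 12) {
    seed <- seed + 1
    rt <- random_table(seed + 5000, max_columns = 4, max_rows = 40)
    idx_cols <- indexable_columns(rt$schema)
    if (length(idx_cols) == 0) next
    checked <- checked + 1
    tab <- build_table(rt$schema, rt$rows)
    set.seed(seed)
    key_cols <- sample(idx_cols, sample(seq_along(idx_cols), 1))
    cols <- lapply(key_cols, function(nm) column_of(rt$schema, nm))
    ix <- wt_index_build(tab, key_cols)
    key_rows <- lapply(rt$rows, function(r)
      r[match(key_cols, schema_names_of(rt$schema))])
    want_order <- bf_order(key_rows, cols)
    got <- wt_index_cursor(ix)
    expect_equal(got, lapply(want_order, function(p) wt_row(tab, p)),
                 label = paste("full cursor, seed", seed))
    # random partial-key range against a brute-force filter
    k <- sample(length(key_cols), 1)
    pick_bound <- function() {
      r <- key_rows[[sample(length(key_rows), 1)]]
      r[seq_len(k)]
    }
    start <- pick_bound(); stop <- pick_bound()
    got <- wt_index_cursor(ix, start = start, stop = stop)
    keep <- want_order[vapply(want_order + 1, function(i)
      bf_in_range(key_rows[[i]], start, stop, cols), TRUE)]
    expect_equal(got, lapply(keep, function(p) wt_row(tab, p)),
                 label = paste("range cursor, seed", seed))
  }
})

test_that("histogram conservation and key_count agreement hold", {
  for (seed in c(101, 202)) {
    rt <- random_table(seed, max_columns = 4, max_rows = 30)
    idx_cols <- indexable_columns(rt$schema)
    if (length(idx_cols) == 0) next
    tab <- build_table(rt$schema, rt$rows)
    ix <- wt_index_build(tab, idx_cols[1])
    h <- wt_histogram(ix)
    expect_equal(sum(h$counts), tab$num_rows)
    for (i in seq_along(h$counts))
      expect_equal(wt_key_count(ix, h$keys[[i]]), h$counts[i])
  }
})

test_that("variable-count numeric columns cannot be indexed", {
  schema <- wt_schema(list(wt_column("x", "int", 2L, WT_VARIABLE),
                           wt_column("y", "uint", 1L)))
  tab <- build_table(schema, list(list(c(1, 2), 3)))
  expect_error(wt_index_build(tab, "x"), "cannot be indexed")
  expect_error(wt_index_build(tab, c("y", "y")), "repeated")
  expect_error(wt_index_build(tab, c("y", "nope")), "unknown column")
})
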