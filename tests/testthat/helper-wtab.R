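# Shared helpers: building throwaway tables and independent brute-force
# oracles for key ordering, range filtering and histograms. The oracles work
# on decoded values only — they never touch the package's key encodings.

new_table_dir <- function() tempfile("wtab-test-")

build_table <- function(schema, rows, dir = new_table_dir()) {
  b <- wt_create(dir, schema)
  for (r in rows) wt_append(b, r)
  wt_finalise(b)
}

# hex rendering of a string's bytes; used only as a locale-proof way to sort
# strings byte-lexicographically in the oracles
str_hex <- function(s) {
  vapply(s, function(x) {
    if (is.na(x)) "" else paste(sprintf("%02x", as.integer(charToRaw(x))),
                                collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Stable brute-force sort of row positions (0-based) by the decoded values of
# the key columns: MISSING first, numeric order for numbers, byte order for
# strings, bin ids for binned columns, ties by row position.
bf_order <- function(key_rows, cols, bins = NULL) {
  n <- length(key_rows)
  if (n == 0L) return(integer(0))
  ord_keys <- list()
  for (i in seq_along(cols)) {
    col <- cols[[i]]
    vals <- lapply(key_rows, function(r) r[[i]])
    w <- if (is.null(bins)) NA_real_ else bins[i]
    if (col$ctype == "char") {
      ord_keys[[length(ord_keys) + 1L]] <-
        str_hex(vapply(vals, function(v) v[1L], ""))
    } else {
      n_el <- if (!is.na(w)) 1L else col$num_elements
      for (j in seq_len(n_el)) {
        x <- vapply(vals, function(v) {
          v <- if (length(v) == 1L && is.na(v)) rep(NA_real_, n_el) else v
          as.numeric(v[j])
        }, 0)
        if (!is.na(w)) x <- floor(x / w)
        ord_keys[[length(ord_keys) + 1L]] <- x
      }
    }
  }
  ord_keys$na.last <- FALSE
  ord_keys$method <- "radix"
  do.call(order, ord_keys) - 1L
}

# compare one decoded key tuple against a (possibly partial) bound tuple:
# -1 / 0 / +1 over the bound's prefix, MISSING first
bf_cmp_prefix <- function(key, bound, cols, bins = NULL) {
  for (i in seq_along(bound)) {
    col <- cols[[i]]
    a <- key[[i]]; b <- bound[[i]]
    w <- if (is.null(bins)) NA_real_ else bins[i]
    if (col$ctype == "char") {
      ah <- str_hex(a); bh <- str_hex(b)
      if (ah < bh) return(-1L)
      if (ah > bh) return(1L)
    } else {
      if (!is.na(w)) { a <- floor(a / w); b <- floor(b / w) }
      n_el <- max(length(a), length(b))
      a <- c(as.numeric(a), rep(NA_real_, n_el - length(a)))
      b <- c(as.numeric(b), rep(NA_real_, n_el - length(b)))
      for (j in seq_len(n_el)) {
        an <- is.na(a[j]); bn <- is.na(b[j])
        if (an && bn) next
        if (an) return(-1L)
        if (bn) return(1L)
        if (a[j] < b[j]) return(-1L)
        if (a[j] > b[j]) return(1L)
      }
    }
  }
  0L
}

bf_in_range <- function(key, start, stop, cols, bins = NULL) {
  (is.null(start) || bf_cmp_prefix(key, start, cols, bins) >= 0L) &&
    (is.null(stop) || bf_cmp_prefix(key, stop, cols, bins) < 0L)
}

# columns of a schema that the index module accepts as key columns
indexable_columns <- function(schema) {
  nm <- schema_names_of(schema)
  keep <- vapply(schema$columns, function(col)
    col$ctype == "char" || !is.na(col$num_elements), TRUE)
  nm[keep]
}

schema_names_of <- function(schema)
  vapply(schema$columns, function(c) c$name, "")

column_of <- function(schema, name)
  schema$columns[[match(name, schema_names_of(schema))]]

# simple CHROM/POS-shaped table for window-query tests
build_genomic_table <- function(n, seed, chroms = c("2L", "2R", "3L", "X"),
                                max_pos = 2e6) {
  set.seed(seed)
  chrom <- sample(chroms, n, replace = TRUE)
  pos <- sample.int(max_pos, n, replace = TRUE)
  qual <- round(runif(n, 0, 100), 2)
  schema <- wt_schema(list(
    wt_column("CHROM", "char", 1L, WT_VARIABLE),
    wt_column("POS", "uint", 4L),
    wt_column("QUAL", "float", 4L)))
  dir <- new_table_dir()
  b <- wt_create(dir, schema)
  for (i in seq_len(n))
    wt_append(b, list(chrom[i], pos[i],
                      wtab:::float_quantize(qual[i], 4L)))
  list(table = wt_finalise(b), chrom = chrom, pos = pos)
}
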