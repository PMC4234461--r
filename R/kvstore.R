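# Ordered key-value store.
#
# The store contract this package relies on: byte-string keys iterated in
# ascending lexicographic order, point lookups, range scans from a start key,
# and duplicate keys. Because tables are write-once, the concrete backend is
# an immutable sorted flat file ("WTKV"): once built it is never modified,
# which makes tables freely copyable between systems. Keys are handled
# in-memory as lowercase hex strings (two digits per byte), whose string
# order equals byte order.
#
# File format (all integers big-endian):
#   magic "WTKV" | uint8 version | uint64 record count |
#   then per record, in key order: uint32 key length | key bytes |
#   uint32 value length | value bytes.
# Duplicate keys are stored as adjacent records; their relative order is the
# insertion order (for indexes: ascending row position).

KV_MAGIC <- charToRaw("WTKV")
KV_VERSION <- 1L

# Sort pairs into contract order. order(method = "radix") is a stable
# byte-wise sort, locale-independent for the hex alphabet.
kv_sort <- function(keys_hex, values) {
  o <- order(keys_hex, method = "radix")
  list(keys = keys_hex[o], values = values[o])
}

kv_write <- function(path, keys_hex, values, sorted = FALSE) {
  if (!sorted) {
    s <- kv_sort(keys_hex, values)
    keys_hex <- s$keys
    values <- s$values
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(KV_MAGIC, con)
  writeBin(as.raw(KV_VERSION), con)
  writeBin(uint_to_be(length(keys_hex), 8L), con)
  for (i in seq_along(keys_hex)) {
    kb <- hex_to_raw(keys_hex[i])
    vb <- values[[i]]
    writeBin(uint_to_be(length(kb), 4L), con)
    if (length(kb)) writeBin(kb, con)
    writeBin(uint_to_be(length(vb), 4L), con)
    if (length(vb)) writeBin(vb, con)
  }
  invisible(path)
}

kv_read <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 13L || !identical(buf[1:4], KV_MAGIC))
    stop("not a WTKV file: ", path, call. = FALSE)
  n <- be_to_uint(buf[6:13])
  keys <- character(n)
  values <- vector("list", n)
  pos <- 14L
  for (i in seq_len(n)) {
    klen <- be_to_uint(buf[pos:(pos + 3L)]); pos <- pos + 4L
    keys[i] <- if (klen) raw_to_hex(buf[pos:(pos + klen - 1L)]) else ""
    pos <- pos + klen
    vlen <- be_to_uint(buf[pos:(pos + 3L)]); pos <- pos + 4L
    values[[i]] <- if (vlen) buf[pos:(pos + vlen - 1L)] else raw(0)
    pos <- pos + vlen
  }
  list(keys = keys, values = values, n = n)
}

# In-memory backend satisfying the same contract; used by tests and as the
# staging structure during builds.
kv_memory <- function(keys_hex = character(0), values = list()) {
  kv_sort(keys_hex, values)
}

# Range scan over a loaded store: indexes of records with
# enc(start) <= key < enc(stop); NULL bounds are open.
kv_range <- function(kv, start_hex = NULL, stop_hex = NULL) {
  lo <- if (is.null(start_hex)) 1L else hex_lower_bound(kv$keys, start_hex)
  hi <- if (is.null(stop_hex)) length(kv$keys) + 1L
        else hex_lower_bound(kv$keys, stop_hex)
  if (lo >= hi) integer(0) else seq.int(lo, hi - 1L)
}
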