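# wtab on-disk format (version 1.0)

This document is normative for the `wtab` package: the byte-level encoding
below, not any implementation, defines what a valid table is. All multi-byte
integers anywhere in a table directory are **big-endian**; a table directory
copied byte-for-byte between machines of any architecture reads
identically.

## Table directory

```
<table>/
  schema.xml        column definitions (see below)
  rows.dat          encoded rows, stored sequentially, no framing
  rowindex.db       WTKV: 8-byte BE row position -> 8-byte BE offset ++ 4-byte BE length
  metadata.xml      format version, num_rows, registered indexes + bin widths
  index_<name>.db   WTKV per secondary index: key bytes -> 8-byte BE row position
```

`<name>` is the index's key columns joined by `+`. Tables are write-once:
after finalisation only `metadata.xml` changes (and only to register or
deregister indexes).

## Schema XML

```xml
<?xml version="1.0" encoding="UTF-8"?>
<schema version="1.0">
  <columns>
    <column name="POS" ctype="uint" element_size="4" num_elements="1" description=""/>
    <column name="ALT" ctype="char" element_size="1" num_elements="var" description=""/>
  </columns>
</schema>
```

Document order is column order. `ctype` is one of `uint`, `int`, `float`,
`char`; `element_size` is bytes per element (1–8 for integers; 2, 4 or 8 —
IEEE 754 half/single/double — for floats; always 1 for char);
`num_elements` is a positive count or `var`. Column names match
`[A-Za-z_][A-Za-z0-9_.]*`. Serialization is canonical: fixed attribute
order, two-space indentation, LF line endings, so equal schemas have
byte-identical XML.

## Row encoding

A row is a **fixed region** followed by a **variable region**; total length
at most 65,535 bytes.

The fixed region concatenates, in schema order, with no padding:

* fixed-count column: `element_size × num_elements` bytes of encoded
  elements;
* variable-length column: a 4-byte pointer — 2-byte offset of the payload
  from the start of the row, then 2-byte element count. A missing or empty
  value stores the pointer `(0, 0)`. Payloads follow in the variable region
  in schema order, unpadded; a column may hold at most 65,535 elements.

Element encodings (one element = `element_size` = *s* bytes):

| type  | valid values                         | stored bytes                          | missing |
|-------|--------------------------------------|---------------------------------------|---------|
| uint  | `[0, 2^(8s) − 2]`                    | `value + 1`, BE                       | all zero |
| int   | `[−2^(8s−1) + 1, 2^(8s−1) − 1]`      | `value + 2^(8s−1)` as unsigned, BE    | all zero |
| float | finite IEEE half/single/double       | raw IEEE 754 bit pattern, BE          | canonical quiet NaN: `0x7E00` / `0x7FC00000` / `0x7FF8000000000000` |
| char  | bytes, one per element               | raw bytes                             | (no reserved pattern; fixed-length char cannot be missing, variable-length uses the `(0,0)` pointer) |

The biased integer encodings reserve the all-zero pattern for missing (one
value of range) and make the byte order of encoded values equal their
numeric order, missing first. Non-finite floats are invalid. Through this R
binding, integer values are additionally limited to `|v| ≤ 2^53 − 1` (the
exact-integer range of a double); the byte format itself is full-width.

### Worked row

Schema `[a: uint×2 bytes, b: char var, c: float×4 bytes × 2 elements]`,
values `(5, "AC", (1.0, missing))`:

```
0006 000E 0002 3F800000 7FC00000 4143        (16 bytes)
 a    b-ptr      c[0]     c[1]    "AC"
```

## WTKV: the ordered key-value store

Write-once tables let the ordered key-value store contract (ascending
byte-lexicographic key iteration, point gets, range scans, duplicate keys)
be realised as an immutable sorted flat file:

```
"WTKV" | uint8 version (=1) | uint64 record count |
record*: uint32 key length | key bytes | uint32 value length | value bytes
```

Records are sorted by key bytes; duplicate keys are adjacent, in insertion
order (ascending row position for indexes).

## Index key encoding

An index key is the concatenation of per-column order-preserving encodings;
byte-lexicographic order of keys equals column-wise value order, missing
first:

* `uint` / `int`: the row element encoding (already order-preserving);
* `float`: the IEEE bit pattern transformed for sorting — if the sign bit is
  set, invert all bits, otherwise set the sign bit; missing encodes as all
  zero bytes;
* `char`, fixed length: raw bytes;
* `char`, variable length: raw bytes followed by a `0x00` terminator
  (embedded NUL bytes are rejected for indexed values); missing is the bare
  terminator. The terminator preserves prefix order (`"2" < "2L"`);
* multi-element columns: element encodings concatenated (variable-count
  numeric columns cannot be indexed — their element count is not
  recoverable from the key);
* binned columns: `floor(value / width)` encoded as an 8-byte signed
  (biased) integer regardless of source type, so negative bins order
  correctly.

A partial key — values for a prefix of the key columns — encodes the same
way and serves directly as a byte-lexicographic range bound: a cursor
returns rows with `enc(start) ≤ key < enc(stop)`.
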