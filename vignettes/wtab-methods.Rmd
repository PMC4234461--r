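---
title: "wtab: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wtab: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtab)
```

## The problem and the approach

Genome-scale tabular data — variant call sets, gene annotations — is almost
always exchanged as tab-delimited text. Text is a fine interchange format
and a poor processing format: every pass over the data re-parses every
field, and nothing short of a full scan answers "which rows have this
value". Loading into a relational database fixes both problems at the cost
of a server, a schema design exercise and SQL, none of which is warranted
for data that is written once and never updated.

`wtab` takes the write-once read-many (WORM) middle road. A source file is
converted once into a self-contained table directory: rows packed in a
typed binary format, a row-pointer database for random access, and as many
secondary indexes as the analysis needs, added or removed at any time
without touching the data. After conversion, reading a column is a memory
copy plus a fixed-width decode, not a parse; reading a key range is an
ordered scan of a precomputed index.

## The row format

A schema is an ordered list of typed columns (unsigned/signed integers of
1–8 bytes, IEEE 754 half/single/double floats, fixed- or variable-length
char). Each row is a *fixed region* — scalars and, for each variable-length
column, a 4-byte (offset, count) pointer — followed by a *variable region*
holding the variable-length payloads. Column projection falls out of the
layout: to decode three columns of an 18-column row, only those columns'
bytes are touched.

Three choices here were genuinely open and are worth recording:

* **Big-endian everywhere.** The format, not the host, defines byte order,
  so a table directory is portable byte-for-byte between architectures. The
  cost (a byte swap on little-endian hosts) is irrelevant in R, where
  decode cost is dominated by interpreter overhead anyway.
* **Reserved missing patterns.** VCF and GTF both need missing values
  (`.`), so missingness is a first-class cell value. Integers are stored
  biased (`+1` for unsigned, `+2^(8s−1)` for signed) with the all-zero
  pattern reserved for missing — costing exactly one value of range and
  making encoded byte order equal numeric order with missing first, which
  the index module relies on. Floats reserve the canonical quiet NaN.
  Fixed-length char columns have no spare pattern and therefore cannot hold
  missing; the converters only emit fixed char for fields that are always
  present (e.g. GTF strand). Variable-length columns store missing as the
  `(0, 0)` pointer, which means *empty and missing coincide*: decoding
  canonicalises both to missing. The fixture generators respect this by
  never emitting a bare empty string, so round-trip properties are exact.
* **2+2-byte variable pointers.** The pointer width caps a row at 65,535
  bytes and a value at 65,535 elements, comfortably above realistic VCF/GTF
  rows, and keeps the fixed region compact. Overflow is a clear error, not
  a silent truncation.

One binding-specific limit: R carries integers in doubles, so 7- and 8-byte
integer columns accept values only up to `2^53 − 1` in magnitude; beyond
that, encoding refuses rather than rounding silently. The byte format
itself is full-width.

## The ordered key-value store

Row pointers and indexes need an ordered key-value store: ascending
byte-lexicographic iteration, point gets, range scans from a key, duplicate
keys. Because tables are write-once, the store never needs inserts after
construction, so the package realises the contract as an immutable sorted
flat file (`WTKV`, see `FORMAT.md`) built in one shot from the sorted pair
list and searched by binary search in memory. An in-memory pair list
satisfies the same contract and backs parts of the test suite. The contract
is the interface; any ordered store (a B-tree library, LMDB, …) could be
swapped in behind it without changing the format semantics of keys and
values.

Keys are handled internally as lowercase hex strings, two digits per byte —
a representation whose string order equals byte order in any locale, which
lets R's stable radix sort and plain string comparison implement the
ordered contract without locale hazards.

## Order-preserving index keys

An index key is the concatenation of per-column encodings whose byte order
equals value order: biased integers as stored; float bit patterns with the
sign bit flipped (all bits inverted for negatives); raw bytes for fixed
char; raw bytes plus a `0x00` terminator for variable char. The terminator
is what preserves prefix ordering (`"2" < "2L"`) across column boundaries
— and is also why embedded NUL bytes are rejected for indexed
variable-length values. Missing always encodes as the minimal pattern and
sorts first.

Consequences that follow from the concatenation design:

* **Partial keys are free.** A prefix of the key columns encodes to a
  prefix of the key bytes, so "all of chromosome 2L" or "2L positions
  [10^6, 10^6 + 1000)" are just byte-range bounds on a CHROM+POS index —
  the half-open `enc(start) ≤ key < enc(stop)` contract.
* **Ties break by row position.** Duplicate keys are stored as adjacent
  records in insertion order, so equal-key rows come back in table order —
  the stable-sort semantics the property tests assert.
* **Variable-count numeric columns cannot be indexed**: their element count
  is not recoverable from the concatenated key. The converters sidestep
  this for the one place it matters (ALT and other multi-valued string
  fields) by storing them comma-joined in a single variable char column, so
  the classic REF+ALT index works unchanged.
* **Binned columns** encode `floor(value/width)` as an 8-byte signed
  integer regardless of source type, so negative bins (possible for signed
  and float data) order correctly and partial-key arithmetic sees one
  uniform width. `bin_value()` guards the floor against floating-point
  edge effects: after `b <- floor(v/w)` it nudges `b` by one if rounding
  put `v` outside `[b·w, (b+1)·w)`, so bin containment holds identically,
  not just almost always.

## Converters and smallest-type inference

`vcf_to_table()` is two-pass. Pass one accumulates per-column statistics
(integer extrema, element counts, missingness) and discovers INFO keys used
in the data but absent from the header (these become variable char columns
— an extension, flagged in the column description). Pass two builds the
table with the smallest legal type per column: non-negative integer columns
become `uint` of the smallest size whose valid range (net of the reserved
missing pattern) covers the observed maximum, signed ones `int` likewise —
so a depth field with maximum 200 costs one byte per row, and a field
spanning −5…300 costs two. `Number=n` declarations fix the element count;
`A`/`G`/`R`/`.` map to variable. Float fields (and QUAL) default to IEEE
single rather than half, because VCF qualities routinely exceed half
precision's exact-integer range (2048); half is available per column for
data that tolerates ~3 significant digits. Genotype fields stay strings:
the package demonstrates column access, not genotype semantics. A
`single_pass` option trades minimal sizes for one pass with 4-byte
defaults. POS stays 1-based; no coordinate is ever shifted.

`gtf_to_table()` maps the nine GTF fields plus `gene_id` and
`transcript_id` extracted from the attributes string (kept raw in its own
column, so nothing is lost).

The worked analysis, `count_transitions_transversions()`, classifies each
single-base REF/ALT pair by the purine/pyrimidine rule (A↔G, C↔T are
transitions), counting per alternate allele and skipping indels and
symbolic alleles — a rule stated explicitly so the numbers are
reproducible; the source format does not define one. It runs either as a
projected scan of two columns or from a REF+ALT index histogram; both
routes must and do agree exactly, which the tests assert.

## What the fixtures emulate — and what they do not

The toy VCF generator produces format-faithful data: five INFO fields
covering every declared type (including a Flag and `Number=A` fields),
per-sample GT/GQ, strictly increasing positions per chromosome, occasional
indels, multi-allelic sites and missing values. The random-table generator
draws schemas over every type/size combination and biases values towards
range extremes, missing, and empty variable payloads — uniform sampling
almost never hits reserved patterns. Both are deterministic per seed with
pinned RNG kinds, and restore the caller's RNG state.

What they deliberately do not emulate: linkage or any population-genetic
structure, realistic allele-frequency spectra, header zoo diversity
(pedigrees, contigs, symbolic ALT grammar), or malformed input. Passing
tests therefore demonstrate format-level correctness — encodings,
ordering, conversion fidelity, query semantics — not robustness to the
full diversity of wild VCFs, and the toy Ts/Tv ratio is the uniform-draw
expectation (~0.5), not the ~2 of a real call set.

## Problem sizes and numerical tolerances

The property suites run at sizes chosen to exercise the mechanisms densely
with fast feedback: 10^3 random schema/row fixtures for codec round-trips,
100 random tables (up to 10^3 rows) against brute-force sort/filter
oracles, 10^4 random (value, width) pairs for bin containment, 100-row ×
3-sample VCFs for conversion fidelity (cross-checked against the
independent `vcfR` parser), and 100 random 1 kb windows on a 10^4-row
CHROM+POS-indexed table against brute-force filtering. Integer and string
round-trips are compared exactly; floats are compared exactly *at stored
precision* (generators pre-quantize, so equality is bitwise). The only
deliberate tolerance anywhere is in comparing decoded single-precision
values against decimal source text (10^-6 relative).

## Known limitations

* No interval/overlap search: a CHROM+POS index finds features *starting*
  in a window, not those spanning it.
* No compression of the data file, and no in-place updates or deletes —
  write-once is the contract, not a missing feature.
* One writer, sequential build; no concurrency control of any kind.
* 8-byte integer columns are limited to the double-exact range through this
  binding.
* The admin CLI covers the listed verbs (`ls`, `add`, `rm`, `show`,
  `dump`, `hist`); it is not an interactive shell.
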