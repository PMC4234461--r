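# wtab — write-once read-many binary tables for genome-scale data

Most genome-scale tabular data — variant calls (VCF), gene annotations
(GTF), and the like — lives in tab-delimited text. Every analysis then pays
the same price twice: each row must be re-parsed from text, and there is no
way to reach "the rows with REF = A" or "chromosome 2L around position 10<sup>6</sup>"
without scanning the whole file. `wtab` is an R implementation of the
write-once read-many (WORM) table idea for this setting: convert the file
*once* into a compact, portable binary table, then read it many times with
random row access, column-projected cursors and secondary indexes — without
a database server, and without ever parsing text again.

## What it provides

* **A compact binary row format.** Each row is a *fixed region* (scalars and
  4-byte pointers for variable-length columns, at schema-defined offsets)
  followed by a *variable region* holding variable-length payloads. Columns
  are typed: unsigned/signed integers of 1–8 bytes, IEEE 754 half/single/
  double floats, and fixed- or variable-length character data, so every
  column can use the smallest type that represents its data. All multi-byte
  values are big-endian, making table directories byte-identical across
  architectures. The exact bit-level layout is documented in
  [`FORMAT.md`](FORMAT.md) and is normative for this package.
* **A table store.** A table is a directory: `rows.dat` (rows stored
  sequentially), `rowindex.db` (an ordered key-value database mapping row
  position to the row's offset and length), `schema.xml` and
  `metadata.xml`. Row *i* is fetched by one key lookup and one read of
  exactly that row's bytes.
* **Secondary indexes with order-preserving keys.** An index over any
  combination of columns stores `enc(key columns) → row position` in an
  ordered key-value database, where `enc` is an order-preserving byte
  encoding (missing first, numeric order for numbers, byte order for
  strings). Range queries, partial-key (prefix) queries, exact key counts
  and histograms are then sorted scans. Optional *binned* indexes map the
  half-open interval `[b·w, (b+1)·w)` to the single key `b = floor(v/w)` —
  cheap histograms over, say, quality scores.
* **Converters and tooling.** `vcf_to_table()` (VCF 4.x, plain or gzip,
  two-pass smallest-type inference), `gtf_to_table()`, the
  `count_transitions_transversions()` worked analysis, deterministic toy
  fixture generators, and command-line scripts `wtadmin`, `vcf2wt`,
  `gtf2wt`, `make-fixtures` under `inst/bin/`.

## Worked example

```r
library(wtab)

# a deterministic 1000-row, 3-sample toy VCF (5 INFO fields, GT/GQ per sample)
writeLines(generate_toy_vcf(num_rows = 1000, num_samples = 3, seed = 1),
           "/tmp/toy.vcf")

tab <- vcf_to_table("/tmp/toy.vcf", "/tmp/toy.wt")
tab
#> wt_table at '/tmp/toy.wt': 1000 rows, 18 columns
```

The two-pass conversion stored each column in the smallest type that covers
its data — the depth field `INFO.DP` (max 250 in this file) landed in a
single byte, and `POS` in three:

```r
format(tab$schema$columns[[2]])
#> [1] "POS:uint3[1]"
```

Counting transitions and transversions needs only the REF and ALT columns;
the cursor decodes nothing else:

```r
count_transitions_transversions(tab)
#>  ts  tv
#> 402 760
```

(The toy generator draws alternate alleles uniformly, so transversions are
twice as common — the Ts/Tv ratio of ~0.5 is the random-expectation value,
not the ~2 typical of a real call set. The same computation via a `REF+ALT`
index histogram returns identical counts.)

Genomic range queries go through a CHROM+POS index and a partial key:

```r
ix <- wt_index_build(tab, c("CHROM", "POS"))
rows <- wt_index_cursor(ix, c("POS", "REF", "ALT"),
                        start = list("2L", 100000), stop = list("2L", 200000))
length(rows)
#> [1] 19
str(rows[[1]])
#> List of 3
#>  $ POS: num 1e+05
#>  $ REF: chr "C"
#>  $ ALT: chr "T"
```

A binned index gives a histogram of qualities in units of 100 (the `NA` bin
collects rows whose QUAL is missing — missing always sorts first):

```r
qix <- wt_index_build(tab, "QUAL", bins = 100)
h <- wt_histogram(qix)
data.frame(bin = unlist(lapply(h$keys, `[[`, "QUAL")), count = h$counts)
#>    bin count
#> 1   NA    58
#> 2    0    87
#> 3    1    87
#> ...
```

The same administration tasks are available from a shell:

```sh
inst/bin/wtadmin add /tmp/toy.wt REF+ALT
inst/bin/wtadmin ls /tmp/toy.wt
inst/bin/wtadmin hist /tmp/toy.wt REF+ALT | head
inst/bin/wtadmin dump /tmp/toy.wt --columns CHROM,POS,REF,ALT --start 0 --stop 5
```

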