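Package: wtab
Title: Write-Once Read-Many Binary Tables for Genome-Scale Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A portable write-once read-many (WORM) store for large tabular
    data such as variant calls and gene annotations. Rows are packed into a
    compact big-endian binary format described by an XML schema, giving random
    access without text parsing. Secondary indexes over arbitrary column
    combinations use order-preserving key encodings, support partial-key range
    cursors, exact key counts, and binned histograms. Includes converters from
    VCF 4.x and GTF with two-pass smallest-type inference, a worked
    transition/transversion analysis, an administration command-line tool
    (wtadmin), and deterministic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
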