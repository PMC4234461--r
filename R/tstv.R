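#' Count transitions and transversions
#'
#' Classifies every single-nucleotide substitution in a VCF-derived table:
#' for each row with a single-base REF, each single-base ALT allele is a
#' transition when the pair is purine–purine or pyrimidine–pyrimidine
#' (A<->G, C<->T) and a transversion otherwise. Indels, symbolic alleles and
#' non-ACGT bases are skipped; multi-allelic rows contribute one count per
#' alternate allele. The transition/transversion ratio is a standard quality
#' diagnostic for variant call sets (typically around 2 genome-wide).
#'
#' The `"scan"` method streams the REF and ALT columns with a projected
#' cursor. The `"index"` method classifies the histogram of a `REF+ALT`
#' index instead — one weighted count per distinct (REF, ALT) key — building
#' the index if the table does not have one yet. Both routes return
#' identical counts.
#'
#' @param table A `wt_table` with `REF` and `ALT` columns (comma-joined
#'   alternate alleles, as written by [vcf_to_table()]).
#' @param method `"scan"` (full table scan) or `"index"`.
#' @return Named numeric vector `c(ts = ..., tv = ...)`.
#' @export
count_transitions_transversions <- function(table,
                                            method = c("scan", "index")) {
  method <- match.arg(method)
  nm <- schema_names(table$schema)
  if (!all(c("REF", "ALT") %in% nm))
    stop("table has no REF/ALT columns", call. = FALSE)
  classify <- function(ref, alt, weight = 1) {
    # returns c(ts, tv) contribution of one (REF, ALT-string) pair
    if (is.na(ref) || is.na(alt)) return(c(0, 0))
    ref <- toupper(ref)
    if (nchar(ref) != 1L || !(ref %in% c("A", "C", "G", "T")))
      return(c(0, 0))
    ts <- 0; tv <- 0
    for (a in strsplit(toupper(alt), ",", fixed = TRUE)[[1L]]) {
      if (nchar(a) != 1L || !(a %in% c("A", "C", "G", "T")) || a == ref) next
      pair <- paste(sort(c(ref, a)), collapse = "")
      if (pair %in% c("AG", "CT")) ts <- ts + 1 else tv <- tv + 1
    }
    c(ts, tv) * weight
  }
  total <- c(0, 0)
  if (method == "scan") {
    for (row in wt_cursor(table, c("REF", "ALT")))
      total <- total + classify(row$REF, row$ALT)
  } else {
    name <- index_name_for(c("REF", "ALT"))
    meta <- read_metadata_xml(table_paths(table$dir)$metadata)
    ix <- if (name %in% names(meta$indexes)) wt_index_open(table, name)
          else wt_index_build(table, c("REF", "ALT"))
    h <- wt_histogram(ix)
    for (i in seq_along(h$counts))
      total <- total + classify(h$keys[[i]]$REF, h$keys[[i]]$ALT,
                                h$counts[i])
  }
  c(ts = total[1L], tv = total[2L])
}
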