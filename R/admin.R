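#' Table administration (the `wtadmin` command)
#'
#' Implements the administration verbs behind the `wtadmin` command-line
#' script: listing, adding and removing indexes, printing the schema,
#' dumping rows as TSV and printing index histograms. The script in
#' `inst/bin/wtadmin` is a thin wrapper around this function.
#'
#' Verbs:
#' \describe{
#'   \item{`ls TABLE`}{list indexes with bin widths and entry counts}
#'   \item{`add TABLE COLS [--bins w1,w2]`}{build the index named by the
#'     `+`-joined columns; empty slots in `--bins` leave a column unbinned}
#'   \item{`rm TABLE NAME`}{delete an index}
#'   \item{`show TABLE`}{print the schema}
#'   \item{`dump TABLE [--columns a,b] [--start N] [--stop N]`}{write rows as
#'     TSV on standard output, `.` for missing, multi-element values joined
#'     by `,`}
#'   \item{`hist TABLE INDEX`}{print `key<TAB>count` lines in key order}
#' }
#'
#' @param argv Character vector of command-line arguments (after the program
#'   name).
#' @return Exit status, invisibly: 0 on success, 1 on error (with a one-line
#'   diagnostic on standard error). A failed `add` leaves the table
#'   directory unchanged.
#' @export
run_admin <- function(argv) {
  usage <- paste(
    "usage: wtadmin <verb> TABLE [args]",
    "verbs: ls | add TABLE COLS [--bins w1,w2] | rm TABLE NAME | show |",
    "       dump [--columns a,b] [--start N] [--stop N] | hist TABLE INDEX",
    sep = "\n")
  fail <- function(...) {
    message("wtadmin: ", ...)
    invisible(1L)
  }
  if (length(argv) == 0L) {
    message(usage)
    return(invisible(1L))
  }
  # pull --flag value pairs out of argv
  flags <- list()
  pos_args <- character(0)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      nm <- substring(a, 3L)
      if (nm == "verbose") { flags$verbose <- TRUE; i <- i + 1L; next }
      if (i == length(argv)) return(fail("flag --", nm, " needs a value"))
      flags[[nm]] <- argv[i + 1L]
      i <- i + 2L
    } else {
      pos_args <- c(pos_args, a)
      i <- i + 1L
    }
  }
  verb <- pos_args[1L]
  known <- c("ls", "add", "rm", "show", "dump", "hist")
  if (!(verb %in% known)) return(fail("unknown verb '", verb, "'\n", usage))
  arity <- c(ls = 2L, add = 3L, rm = 3L, show = 2L, dump = 2L, hist = 3L)
  if (length(pos_args) != arity[[verb]])
    return(fail("wrong number of arguments for '", verb, "'\n", usage))

  out <- tryCatch({
    table <- wt_open(pos_args[2L])
    switch(verb,
      ls = {
        lst <- wt_index_list(table)
        if (nrow(lst)) {
          cat(sprintf("%s\t%s\t%s\n", lst$name,
                      ifelse(nzchar(lst$bins), lst$bins, "-"),
                      format(lst$entries, scientific = FALSE)), sep = "")
        }
        0L
      },
      add = {
        columns <- strsplit(pos_args[3L], "+", fixed = TRUE)[[1L]]
        bins <- NULL
        if (!is.null(flags$bins)) {
          parts <- strsplit(flags$bins, ",", fixed = TRUE)[[1L]]
          parts <- c(parts, rep("", length(columns) - length(parts)))
          bins <- suppressWarnings(as.numeric(parts))
          bad <- is.na(bins) & nzchar(parts)
          if (any(bad)) stop("bad bin width '", parts[bad][1L], "'",
                             call. = FALSE)
        }
        wt_index_build(table, columns, bins)
        0L
      },
      rm = {
        wt_index_remove(table, pos_args[3L])
        0L
      },
      show = {
        print(table$schema)
        0L
      },
      dump = {
        columns <- if (is.null(flags$columns)) NULL
                   else strsplit(flags$columns, ",", fixed = TRUE)[[1L]]
        start <- if (is.null(flags$start)) 0 else as.numeric(flags$start)
        stop_ <- if (is.null(flags$stop)) table$num_rows
                 else as.numeric(flags$stop)
        for (row in wt_cursor(table, columns, start, stop_))
          cat(paste(vapply(row, render_cell, ""), collapse = "\t"), "\n",
              sep = "")
        0L
      },
      hist = {
        ix <- wt_index_open(table, pos_args[3L])
        h <- wt_histogram(ix)
        for (i in seq_along(h$counts)) {
          key <- paste(vapply(h$keys[[i]], render_cell, ""), collapse = "\t")
          cat(key, "\t", format(h$counts[i], scientific = FALSE), "\n",
              sep = "")
        }
        0L
      })
  }, error = function(e) fail(conditionMessage(e)))
  invisible(if (is.numeric(out)) as.integer(out) else 1L)
}

# one TSV cell: "." for MISSING, multi-element values joined by ","
render_cell <- function(v) {
  if (length(v) == 1L && is.na(v)) return(".")
  if (is.character(v)) return(v)
  paste(vapply(v, function(x)
    if (is.na(x)) "." else as.character(x), ""), collapse = ",")
}
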