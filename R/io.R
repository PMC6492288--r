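# Readers for the three trial-data dialects and labelled matrix writers.
# CSV/TSV only, UTF-8, RFC 4180 quoting. Treatment codes are always read as
# strings ("01" stays "01"); nothing here touches outcome data.

#' Read an arm-level (long) trial table
#'
#' One row per study arm, with columns `study` and `treatment`. Each study
#' contributes a complete subgraph among its arms, so multi-arm trials are
#' handled naturally. Duplicate (study, treatment) rows are collapsed with
#' a warning.
#'
#' @param file path to a CSV or TSV file.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the first line.
#' @return An [evidence_network()] with labels in first-appearance order
#'   and the per-study records retained in `$studies`.
#' @export
read_long_arm_table <- function(file, sep = NULL) {
  tab <- read_delim_table(file, sep = sep, header = TRUE)
  names(tab) <- tolower(names(tab))
  if (!all(c("study", "treatment") %in% names(tab))) {
    stop_invalid_input(
      "long arm table needs columns 'study' and 'treatment'")
  }
  if (any(!nzchar(tab$study)) || any(!nzchar(tab$treatment))) {
    stop_invalid_input("'study' and 'treatment' values must be non-empty")
  }
  key <- paste(tab$study, tab$treatment, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate (study, treatment) row(s) collapsed",
                    sum(duplicated(key))))
    tab <- tab[!duplicated(key), , drop = FALSE]
  }
  ids <- unique(tab$study)
  studies <- lapply(ids, function(id) {
    list(study_id = id, arms = tab$treatment[tab$study == id])
  })
  network_from_studies(studies)
}

#' Read a wide one-row-per-study treatment matrix
#'
#' The layout used for treatment structure in technical support documents
#' for multi-treatment evidence synthesis: one row per study, treatment
#' columns `t1`, `t2`, ..., with a missing marker in unused arm slots. Any
#' column whose name matches `t<number>` is taken as a treatment column
#' (the exact column naming convention varies between sources); other
#' columns are ignored. `NA`, the empty string and `.` are all recognized
#' as missing, covering both R- and Stata-flavoured exports.
#'
#' @inheritParams read_long_arm_table
#' @param header does the file carry a header row? With `header = FALSE`
#'   every column is treated as a treatment column and named `t1..tK`.
#' @return An [evidence_network()].
#' @export
read_dsu_wide <- function(file, sep = NULL, header = TRUE) {
  tab <- read_delim_table(file, sep = sep, header = header)
  if (!header) {
    names(tab) <- paste0("t", seq_along(tab))
  }
  tcols <- grep("^[tT][0-9]+$", names(tab), value = TRUE)
  if (!length(tcols)) {
    stop_invalid_input("no treatment columns (t1, t2, ...) found")
  }
  arms_by_row <- apply(as.matrix(tab[tcols]), 1L, function(r) {
    r[!is.na(r) & nzchar(r) & r != "NA" & r != "."]
  }, simplify = FALSE)
  empty <- lengths(arms_by_row) == 0L
  if (any(empty)) {
    warning(sprintf("skipping %d row(s) with no non-missing treatments",
                    sum(empty)))
    arms_by_row <- arms_by_row[!empty]
  }
  studies <- lapply(seq_along(arms_by_row), function(i) {
    list(study_id = paste0("study_", i), arms = unname(arms_by_row[[i]]))
  })
  network_from_studies(studies)
}

#' Read a plain edge list
#'
#' Two columns of treatment labels, one direct comparison per row. Columns
#' named `t_from`/`t_to` are used when present; otherwise the first two
#' columns. Duplicate pairs collapse to one edge; a self-comparison is an
#' error naming the offending row.
#'
#' @inheritParams read_long_arm_table
#' @return An [evidence_network()].
#' @export
read_edge_list <- function(file, sep = NULL) {
  tab <- read_delim_table(file, sep = sep, header = TRUE)
  names(tab) <- tolower(names(tab))
  if (all(c("t_from", "t_to") %in% names(tab))) {
    tab <- tab[c("t_from", "t_to")]
  } else if (ncol(tab) >= 2L) {
    tab <- tab[1:2]
  } else {
    stop_invalid_input("edge list needs two columns of treatment labels")
  }
  self <- which(tab[[1L]] == tab[[2L]])
  if (length(self)) {
    stop_invalid_input(sprintf(
      "self-comparison '%s'-'%s' in edge list row %d",
      tab[[1L]][self[1L]], tab[[2L]][self[1L]], self[1L]))
  }
  evidence_network(edges = cbind(tab[[1L]], tab[[2L]]))
}

#' Write a labelled (optionally block-collected) matrix
#'
#' Writes a square labelled matrix as CSV/TSV with the treatment labels as
#' first row and first column, the layout used for published distance
#' matrices. With `blocked = TRUE` the matrix is first collected into
#' block-diagonal component order; off-block (unconnected) cells are then
#' rendered according to `unconnected`: `"zero"` writes 0, `"blank"` leaves
#' the cell empty (the usual presentation of block-collected tables),
#' `"inf"` writes `Inf`. Output round-trips through
#' [read_labeled_matrix()] bit-exactly.
#'
#' @param m square numeric matrix with identical row and column labels
#'   (e.g. from [distance_matrix()] or [indirect_connection()]).
#' @param file output path, or `""` to write to standard output.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @param blocked collect into block-diagonal order first?
#' @param partition optional [connected_components()] partition; when
#'   `NULL` and `blocked = TRUE` it is derived from the nonzero pattern of
#'   `m`.
#' @param unconnected rendering of unconnected (off-block / zero
#'   off-diagonal / `NA`) cells: `"zero"`, `"blank"` or `"inf"`.
#' @return Invisibly, the character vector of lines written.
#' @export
write_labeled_matrix <- function(m, file, sep = ",", blocked = FALSE,
                                 partition = NULL,
                                 unconnected = c("zero", "blank", "inf")) {
  unconnected <- match.arg(unconnected)
  lines <- format_labeled_matrix(m, sep = sep, blocked = blocked,
                                 partition = partition,
                                 unconnected = unconnected)
  if (identical(file, "")) {
    writeLines(lines)
  } else {
    writeLines(lines, file)
  }
  invisible(lines)
}

format_labeled_matrix <- function(m, sep = ",", blocked = FALSE,
                                  partition = NULL, unconnected = "zero") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_invalid_input("`m` must be a square matrix")
  }
  labels <- rownames(m)
  if (is.null(labels) || !identical(labels, colnames(m))) {
    stop_invalid_input("`m` must carry identical row and column labels")
  }
  if (blocked && nrow(m) > 0L) {
    if (is.null(partition)) {
      partition <- connected_components(connectivity_relation(m))
    }
    sorted <- block_sort(m, partition)
    m <- sorted$matrix
    labels <- sorted$labels
  }
  n <- nrow(m)
  cells <- matrix("", n, n)
  if (n > 0L) {
    unreach <- is.na(m) | (m == 0 & row(m) != col(m))
    cells[] <- vapply(as.numeric(m), function(v) {
      if (is.na(v)) "" else formatC(v, format = "d")
    }, character(1L))
    cells[unreach] <- switch(unconnected,
                             zero = "0", blank = "", inf = "Inf")
  }
  header <- paste(c("", quote_cells(labels, sep)), collapse = sep)
  rows <- vapply(seq_len(n), function(i) {
    paste(c(quote_cells(labels[i], sep), cells[i, ]), collapse = sep)
  }, character(1L))
  c(header, rows)
}

# 0/1 symmetric zero-diagonal relation underlying a distance or indirect
# connection matrix, used to recover a partition when none is supplied
connectivity_relation <- function(m) {
  m[is.na(m)] <- 0
  rel <- indicator(m)
  diag(rel) <- 0
  rel
}

#' Read a labelled matrix written by [write_labeled_matrix()]
#'
#' @param file path to the CSV/TSV file.
#' @param sep field separator; `NULL` auto-detects.
#' @param blank value substituted for empty and `Inf` cells (unconnected
#'   pairs in blocked output): `0` by default, use `NA` to keep them
#'   missing.
#' @return Square numeric matrix with the stored labels as dimnames.
#' @export
read_labeled_matrix <- function(file, sep = NULL, blank = 0) {
  tab <- read_delim_table(file, sep = sep, header = TRUE)
  labels <- names(tab)[-1L]
  if (nrow(tab) != length(labels)) {
    stop_invalid_input("labelled matrix file is not square")
  }
  vals <- as.matrix(tab[-1L])
  vals[vals == "" | vals == "Inf"] <- NA_character_
  m <- matrix(as.numeric(vals), nrow(tab), length(labels))
  m[is.na(m)] <- blank
  dimnames(m) <- list(tab[[1L]], labels)
  if (!identical(rownames(m), colnames(m))) {
    stop_invalid_input("row labels do not match column labels")
  }
  m
}

# ---- shared plumbing -------------------------------------------------------

read_delim_table <- function(file, sep = NULL, header = TRUE) {
  if (!is.character(file) || length(file) != 1L || !file.exists(file)) {
    stop_invalid_input(sprintf("cannot read input file '%s'",
                               paste(file, collapse = ", ")))
  }
  first <- readLines(file, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    stop_invalid_input(sprintf("input file '%s' is empty", file))
  }
  if (is.null(sep)) {
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  tab <- tryCatch(
    utils::read.table(file, sep = sep, header = header,
                      colClasses = "character", check.names = FALSE,
                      quote = "\"", comment.char = "",
                      na.strings = character(), fill = FALSE,
                      blank.lines.skip = TRUE, strip.white = TRUE,
                      fileEncoding = "UTF-8"),
    error = function(e) {
      stop_invalid_input(sprintf("malformed table in '%s': %s",
                                 file, conditionMessage(e)))
    })
  if (header && anyDuplicated(names(tab))) {
    stop_invalid_input("duplicate column names in header")
  }
  tab
}

# RFC 4180: quote cells containing the delimiter, quotes or newlines
quote_cells <- function(x, sep) {
  needs <- grepl(sep, x, fixed = TRUE) | grepl("[\"\n\r]", x)
  x[needs] <- paste0("\"", gsub("\"", "\"\"", x[needs]), "\"")
  x
}
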