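#' Evidence networks for network meta-analysis
#'
#' An evidence network is a graph whose vertices are treatments and whose
#' edges are the direct head-to-head comparisons available from at least one
#' randomized trial. `evidence_network()` constructs one from an explicit
#' edge list, a list of study records, or both; treatments that appear only
#' as isolated vertices can be added through `labels`.
#'
#' Treatment labels are arbitrary strings and are preserved verbatim
#' (numeric codes stay `"1"`, `"01"`, ...). Unless `labels` is supplied, the
#' vertex order is first-appearance order in the input; all orderings give
#' equivalent matrices, but a fixed order makes printed matrices
#' reproducible. A study with k arms contributes all k(k-1)/2 pairwise
#' edges; repeated comparisons of the same pair collapse to a single edge.
#'
#' @param edges two-column matrix or data frame of treatment label pairs,
#'   one direct comparison per row. `NULL` for a network defined only by
#'   `studies` or isolated `labels`.
#' @param labels optional character vector fixing the vertex order; must
#'   contain every label used in `edges`/`studies` and may add isolated
#'   vertices.
#' @param studies optional list of study records, each a list with elements
#'   `study_id` (string) and `arms` (character vector of treatment labels,
#'   no duplicates within a study). Retained on the object for provenance.
#' @return An object of class `evidence_network`: a list with elements
#'   `labels` (character), `edges` (two-column character matrix of
#'   deduplicated unordered pairs) and `studies`.
#' @examples
#' net <- evidence_network(edges = cbind(
#'   c("1", "2", "2", "4", "6", "7"),
#'   c("2", "3", "5", "5", "7", "8")))
#' net
#' adjacency_matrix(net)
#' @seealso [adjacency_matrix()], [connectivity_summary()], [example_network()]
#' @export
evidence_network <- function(edges = NULL, labels = NULL, studies = NULL) {
  study_edges <- NULL
  study_labels <- character()
  if (!is.null(studies)) {
    studies <- lapply(studies, validate_study)
    study_labels <- unlist(lapply(studies, `[[`, "arms"), use.names = FALSE)
    study_edges <- do.call(rbind, lapply(studies, function(s) arm_pairs(s$arms)))
  }
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (length(edges) == 0L) {
      edges <- matrix(character(), 0L, 2L)
    }
    if (ncol(edges) != 2L) {
      stop_invalid_network("`edges` must have exactly two columns")
    }
    storage.mode(edges) <- "character"
    if (anyNA(edges) || any(!nzchar(edges))) {
      stop_invalid_network("edge endpoints must be non-missing, non-empty labels")
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      bad <- which(edges[, 1L] == edges[, 2L])[1L]
      stop_invalid_network(sprintf(
        "self-comparison '%s'-'%s' (edge row %d) is not allowed",
        edges[bad, 1L], edges[bad, 2L], bad))
    }
  } else {
    edges <- matrix(character(), 0L, 2L)
  }
  all_edges <- rbind(edges, study_edges)
  seen <- c(t(edges), study_labels)
  if (is.null(labels)) {
    labels <- unique(seen)
  } else {
    labels <- as.character(labels)
    if (anyDuplicated(labels)) {
      stop_invalid_network(sprintf(
        "duplicate treatment label '%s'", labels[duplicated(labels)][1L]))
    }
    missing <- setdiff(seen, labels)
    if (length(missing)) {
      stop_invalid_network(sprintf(
        "edge endpoint '%s' does not appear in `labels`", missing[1L]))
    }
  }
  structure(
    list(labels = labels,
         edges = dedupe_edges(all_edges, labels),
         studies = studies),
    class = "evidence_network")
}

#' @export
print.evidence_network <- function(x, ...) {
  cat(sprintf("Evidence network: %d treatments, %d direct comparisons\n",
              length(x$labels), nrow(x$edges)))
  cat("Treatments:", paste(x$labels, collapse = ", "), "\n")
  if (nrow(x$edges)) {
    cat("Comparisons:",
        paste(x$edges[, 1L], x$edges[, 2L], sep = "-", collapse = ", "), "\n")
  }
  if (!is.null(x$studies)) {
    cat(sprintf("Built from %d studies\n", length(x$studies)))
  }
  invisible(x)
}

#' Build an evidence network from study records
#'
#' Convenience wrapper over [evidence_network()] for data already grouped by
#' study: each record contributes a complete subgraph among its arms.
#'
#' @param studies list of study records (`study_id`, `arms`); see
#'   [evidence_network()].
#' @param labels optional explicit vertex order.
#' @return An `evidence_network`.
#' @export
network_from_studies <- function(studies, labels = NULL) {
  evidence_network(labels = labels, studies = studies)
}

validate_study <- function(s) {
  if (is.null(s$arms) || length(s$arms) < 1L) {
    stop_invalid_network("a study record must have at least one arm")
  }
  s$arms <- as.character(s$arms)
  if (anyDuplicated(s$arms)) {
    stop_invalid_network(sprintf(
      "study '%s' lists treatment '%s' in more than one arm",
      as.character(s$study_id), s$arms[duplicated(s$arms)][1L]))
  }
  s$study_id <- as.character(s$study_id)
  s
}

# all unordered pairs among the arms of one study (k arms -> k(k-1)/2 edges)
arm_pairs <- function(arms) {
  k <- length(arms)
  if (k < 2L) return(matrix(character(), 0L, 2L))
  idx <- utils::combn(k, 2L)
  cbind(arms[idx[1L, ]], arms[idx[2L, ]])
}

# collapse duplicates and orientations; rows ordered by (min index, max index)
dedupe_edges <- function(edges, labels) {
  if (is.null(edges) || nrow(edges) == 0L) {
    return(matrix(character(), 0L, 2L, dimnames = list(NULL, c("from", "to"))))
  }
  i <- match(edges[, 1L], labels)
  j <- match(edges[, 2L], labels)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  keep <- !duplicated(cbind(lo, hi))
  ord <- order(lo[keep], hi[keep])
  out <- cbind(labels[lo[keep]][ord], labels[hi[keep]][ord])
  dimnames(out) <- list(NULL, c("from", "to"))
  out
}

stop_invalid_network <- function(msg) {
  stop(errorCondition(msg,
                      class = c("nmaconnect_invalid_network",
                                "nmaconnect_error", "error", "condition")))
}

stop_invalid_input <- function(msg) {
  stop(errorCondition(msg,
                      class = c("nmaconnect_invalid_input",
                                "nmaconnect_error", "error", "condition")))
}

stop_domain <- function(msg) {
  stop(errorCondition(msg,
                      class = c("nmaconnect_domain_error",
                                "nmaconnect_error", "error", "condition")))
}
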