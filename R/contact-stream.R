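#' Construct a contact stream
#'
#' A contact stream is a time-ordered sequence of undirected pairwise
#' interaction events ("contacts"), e.g. face-to-face proximity detections
#' between conference participants. Node identifiers are opaque strings; the
#' two endpoints of every event are stored in canonical (lexicographic) order
#' and events are sorted by timestamp, breaking ties by the canonical pair.
#' This total order is what fixes the global contact index used by the
#' decaying-weight aggregation schemes.
#'
#' @param timestamp Numeric vector of event times in seconds from stream
#'   onset (nonnegative).
#' @param node_a,node_b Character vectors (or coercible) of endpoint
#'   identifiers. Self-contacts (`node_a == node_b`) are an error.
#' @param extra_nodes Optional character vector of identifiers to include in
#'   the node registry even if they appear in no event (e.g. participants
#'   that were present but never detected).
#'
#' @return An object of class `contact_stream`: a list with elements
#'   `events` (data frame with columns `timestamp`, `node_a`, `node_b`,
#'   sorted and canonicalized) and `nodes` (sorted character vector, the
#'   union of all endpoint identifiers and `extra_nodes`).
#' @examples
#' cs <- contact_stream(c(40, 20, 20), c("5", "3", "5"), c("9", "5", "3"))
#' cs$events
#' cs$nodes
#' @export
contact_stream <- function(timestamp, node_a, node_b, extra_nodes = character()) {
  timestamp <- as.numeric(timestamp)
  node_a <- as.character(node_a)
  node_b <- as.character(node_b)
  n <- length(timestamp)
  if (length(node_a) != n || length(node_b) != n)
    stop("timestamp, node_a and node_b must have equal length")
  if (n > 0) {
    if (anyNA(timestamp) || any(!is.finite(timestamp)))
      stop("timestamps must be finite numbers")
    if (any(timestamp < 0))
      stop("timestamps must be nonnegative")
    self <- node_a == node_b
    if (any(self))
      stop("self-contact (identical endpoints) at event ",
           which(self)[1L], ": '", node_a[which(self)[1L]], "'")
    swap <- node_a > node_b
    if (any(swap)) {
      tmp <- node_a[swap]
      node_a[swap] <- node_b[swap]
      node_b[swap] <- tmp
    }
    o <- order(timestamp, node_a, node_b, method = "radix")
    timestamp <- timestamp[o]
    node_a <- node_a[o]
    node_b <- node_b[o]
  }
  nodes <- sort(unique(c(node_a, node_b, as.character(extra_nodes))),
                method = "radix")
  structure(
    list(events = data.frame(timestamp = timestamp, node_a = node_a,
                             node_b = node_b, stringsAsFactors = FALSE),
         nodes = nodes),
    class = "contact_stream")
}

#' @export
print.contact_stream <- function(x, ...) {
  cat("<contact_stream>", nrow(x$events), "events among",
      length(x$nodes), "nodes")
  if (nrow(x$events) > 0)
    cat(sprintf(", time span [%.6g, %.6g] s",
                x$events$timestamp[1L],
                x$events$timestamp[nrow(x$events)]))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.contact_stream <- function(x, ...) x$events

#' Number of events in a contact stream
#' @param stream A `contact_stream`.
#' @return Integer event count.
#' @export
n_events <- function(stream) {
  stopifnot(inherits(stream, "contact_stream"))
  nrow(stream$events)
}

#' Read a contact stream from a delimited text file
#'
#' Two dialects are supported. `sociopatterns_tsv` is the format used by
#' proximity-badge deployments: no header, whitespace-separated
#' `timestamp id_a id_b`, one detected contact per row.  `event_csv` is a
#' generic event log: CSV with header `timestamp,source,target`; any
#' direction information is discarded because the resulting stream is
#' undirected.
#'
#' Input row order never affects the result: events are sorted and endpoint
#' pairs canonicalized on read.
#'
#' @param path Path to the input file.
#' @param dialect One of `"sociopatterns_tsv"` or `"event_csv"`.
#' @return A [contact_stream].
#' @export
read_contact_stream <- function(path,
                                dialect = c("sociopatterns_tsv", "event_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "sociopatterns_tsv") {
    keep <- nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L)
      return(contact_stream(numeric(0), character(0), character(0)))
    parts <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(parts)
    if (any(nf != 3L))
      stop("parse error at line ", lineno[which(nf != 3L)[1L]],
           ": expected 3 whitespace-separated fields, got ",
           nf[which(nf != 3L)[1L]])
    m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
    ts <- suppressWarnings(as.numeric(m[, 1L]))
    if (anyNA(ts))
      stop("parse error at line ", lineno[which(is.na(ts))[1L]],
           ": non-numeric timestamp '", m[which(is.na(ts))[1L], 1L], "'")
    bad <- m[, 2L] == m[, 3L]
    if (any(bad))
      stop("self-contact at line ", lineno[which(bad)[1L]],
           ": node '", m[which(bad)[1L], 2L], "' paired with itself")
    contact_stream(ts, m[, 2L], m[, 3L])
  } else {
    if (length(lines) == 0L || !nzchar(trimws(lines[1L])))
      return(contact_stream(numeric(0), character(0), character(0)))
    header <- tolower(gsub("[\" ]", "", lines[1L]))
    if (header != "timestamp,source,target")
      stop("parse error at line 1: expected header 'timestamp,source,target', got '",
           lines[1L], "'")
    body <- lines[-1L]
    keep <- nzchar(trimws(body))
    lineno <- which(keep) + 1L
    body <- body[keep]
    if (length(body) == 0L)
      return(contact_stream(numeric(0), character(0), character(0)))
    parts <- strsplit(body, ",", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 3L))
      stop("parse error at line ", lineno[which(nf != 3L)[1L]],
           ": expected 3 comma-separated fields, got ", nf[which(nf != 3L)[1L]])
    m <- matrix(trimws(gsub("\"", "", unlist(parts))), ncol = 3L, byrow = TRUE)
    ts <- suppressWarnings(as.numeric(m[, 1L]))
    if (anyNA(ts))
      stop("parse error at line ", lineno[which(is.na(ts))[1L]],
           ": non-numeric timestamp '", m[which(is.na(ts))[1L], 1L], "'")
    bad <- m[, 2L] == m[, 3L]
    if (any(bad))
      stop("self-contact at line ", lineno[which(bad)[1L]],
           ": node '", m[which(bad)[1L], 2L], "' paired with itself")
    contact_stream(ts, m[, 2L], m[, 3L])
  }
}

#' Write a contact stream to a file
#'
#' Inverse of [read_contact_stream()], in either dialect.
#'
#' @param stream A [contact_stream].
#' @param path Output path.
#' @param dialect Output dialect, see [read_contact_stream()].
#' @return `path`, invisibly.
#' @export
write_contact_stream <- function(stream, path,
                                 dialect = c("sociopatterns_tsv", "event_csv")) {
  stopifnot(inherits(stream, "contact_stream"))
  dialect <- match.arg(dialect)
  ev <- stream$events
  ts <- sprintf("%.10g", ev$timestamp)
  if (dialect == "sociopatterns_tsv") {
    writeLines(if (nrow(ev)) paste(ts, ev$node_a, ev$node_b) else character(0),
               path)
  } else {
    writeLines(c("timestamp,source,target",
                 if (nrow(ev)) paste(ts, ev$node_a, ev$node_b, sep = ",")),
               path)
  }
  invisible(path)
}

#' Write a weighted graph as a plain-text edge list
#'
#' One row per edge, `id_a id_b weight`, endpoints in canonical order.
#' Weights are printed with enough significant digits that reading the file
#' back reproduces the graph (exactly for integer weights, to within 1e-9
#' relative for real weights).
#'
#' @param graph A [weighted_graph].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_edge_list()]
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "weighted_graph"))
  e <- graph$edges
  lines <- if (nrow(e))
    paste(e$node_a, e$node_b, sprintf("%.12g", e$weight))
  else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted graph from a plain-text edge list
#'
#' @param path Path to a file written by [write_edge_list()] (rows
#'   `id_a id_b weight`).
#' @param nodes Optional character vector of node identifiers to include as
#'   isolated nodes in addition to edge endpoints.
#' @return A [weighted_graph].
#' @export
read_edge_list <- function(path, nodes = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(weighted_graph(nodes = as.character(nodes)))
  parts <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(parts) != 3L))
    stop("parse error: expected rows 'id_a id_b weight'")
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  w <- as.numeric(m[, 3L])
  if (anyNA(w)) stop("parse error: non-numeric weight")
  weighted_graph(node_a = m[, 1L], node_b = m[, 2L], weight = w,
                 nodes = as.character(nodes))
}

#' Activity histogram of a contact stream
#'
#' Counts events in consecutive half-open time bins `[k*w, (k+1)*w)` starting
#' at zero, the standard view of bursty contact data (e.g. hourly activity
#' over a multi-day conference, with busy daytime blocks and quiet nights).
#'
#' @param stream A [contact_stream].
#' @param bin_width Positive bin width in seconds.
#' @return Data frame with columns `bin_start` (seconds) and `count`;
#'   intermediate empty bins are included, counts sum to the number of
#'   events. Empty stream gives a zero-row data frame.
#' @examples
#' cs <- contact_stream(c(10, 25, 70), c("a", "a", "b"), c("b", "c", "c"))
#' activity_histogram(cs, 60)
#' @export
activity_histogram <- function(stream, bin_width) {
  stopifnot(inherits(stream, "contact_stream"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L ||
      !is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be a positive number")
  t <- stream$events$timestamp
  if (length(t) == 0L)
    return(data.frame(bin_start = numeric(0), count = integer(0)))
  k <- floor(t / bin_width)
  kmax <- max(k)
  counts <- tabulate(k + 1L, nbins = kmax + 1L)
  data.frame(bin_start = (0:kmax) * bin_width, count = counts)
}
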