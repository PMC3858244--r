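#' Training-window specification
#'
#' The training window selects the contacts from which the input graph for
#' link prediction is built. In `by_time` mode it is the half-open interval
#' `[t0, t1)`; in `by_contact_count` mode it is the last `n_contacts` events
#' with timestamp strictly before `t1`, so the window length is measured in
#' contacts rather than seconds (useful when activity is strongly bursty and
#' wall-clock length is a poor proxy for information content).
#'
#' @param t0 Window start in seconds (ignored in `by_contact_count` mode).
#' @param t1 Window end / prediction time in seconds; must exceed `t0`.
#' @param mode `"by_time"` or `"by_contact_count"`.
#' @param n_contacts Positive integer, required in `by_contact_count` mode.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(t0, t1, mode = c("by_time", "by_contact_count"),
                        n_contacts = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(t0), is.numeric(t1), length(t0) == 1L, length(t1) == 1L)
  if (!(t0 < t1)) stop("window requires t0 < t1")
  if (mode == "by_contact_count") {
    if (is.null(n_contacts) || n_contacts < 1)
      stop("by_contact_count mode requires n_contacts >= 1")
    n_contacts <- as.integer(n_contacts)
  }
  structure(list(t0 = as.numeric(t0), t1 = as.numeric(t1), mode = mode,
                 n_contacts = n_contacts),
            class = "window_spec")
}

#' Contact-weighting scheme
#'
#' Controls how much each training contact contributes to the weight of its
#' edge. With training contacts `c_1, ..., c_n` indexed globally in stream
#' order, contact `c_k` increments its pair's weight by:
#' \describe{
#'   \item{flat}{1 — the edge weight is the plain contact count.}
#'   \item{linear}{`k / n` — contributions decay linearly with age; the
#'     newest contact contributes 1, the oldest `1/n`.}
#'   \item{exponential}{`gamma^(n - k)` with `gamma = epsilon^(1/n)` — the
#'     newest contact contributes 1 and contributions decay geometrically so
#'     that the oldest contributes `gamma^(n-1)`, approaching `epsilon`.}
#' }
#' Decaying weights encode the spatiotemporal locality of face-to-face
#' interaction: recent contacts are more informative about imminent link
#' formation than old ones.
#'
#' @param kind `"flat"`, `"linear"` or `"exponential"`.
#' @param epsilon Decay floor for the exponential scheme, a small positive
#'   real in (0, 1). Default 0.01. As `epsilon` approaches 1 the exponential
#'   scheme degenerates to flat weighting.
#' @return An object of class `weighting_scheme`.
#' @export
weighting_scheme <- function(kind = c("flat", "linear", "exponential"),
                             epsilon = 0.01) {
  kind <- match.arg(kind)
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      !is.finite(epsilon) || epsilon <= 0 || epsilon >= 1)
    stop("epsilon must be a number in (0, 1)")
  structure(list(kind = kind, epsilon = as.numeric(epsilon)),
            class = "weighting_scheme")
}

#' Construct a weighted undirected graph
#'
#' The graph container used throughout the package: a node registry plus a
#' set of undirected edges with strictly positive weights, stored with
#' endpoints in canonical (lexicographic) order. Registry members without
#' any edge are isolated nodes; they participate in candidate enumeration
#' but have empty neighborhoods.
#'
#' @param node_a,node_b Character vectors of edge endpoints.
#' @param weight Numeric vector of positive edge weights.
#' @param nodes Optional identifiers to add to the registry as isolated
#'   nodes.
#' @return An object of class `weighted_graph`: list with `nodes` (sorted
#'   character vector) and `edges` (data frame `node_a`, `node_b`,
#'   `weight`).
#' @export
weighted_graph <- function(node_a = character(), node_b = character(),
                           weight = numeric(), nodes = character()) {
  node_a <- as.character(node_a)
  node_b <- as.character(node_b)
  weight <- as.numeric(weight)
  m <- length(node_a)
  if (length(node_b) != m || length(weight) != m)
    stop("node_a, node_b and weight must have equal length")
  if (m > 0) {
    if (any(node_a == node_b)) stop("self-loops are not allowed")
    if (anyNA(weight) || any(!is.finite(weight)) || any(weight <= 0))
      stop("edge weights must be finite and positive")
    swap <- node_a > node_b
    if (any(swap)) {
      tmp <- node_a[swap]
      node_a[swap] <- node_b[swap]
      node_b[swap] <- tmp
    }
    key <- paste(node_a, node_b, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    o <- order(node_a, node_b, method = "radix")
    node_a <- node_a[o]; node_b <- node_b[o]; weight <- weight[o]
  }
  structure(
    list(nodes = sort(unique(c(node_a, node_b, as.character(nodes))),
                      method = "radix"),
         edges = data.frame(node_a = node_a, node_b = node_b,
                            weight = weight, stringsAsFactors = FALSE)),
    class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat("<weighted_graph>", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' @export
as.data.frame.weighted_graph <- function(x, ...) x$edges

# Internal adjacency index: integer neighbor lists and aligned weights,
# plus degree and alpha-strength helpers used by the predictors.
wg_index <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  e <- graph$edges
  ai <- match(e$node_a, nodes)
  bi <- match(e$node_b, nodes)
  nbr <- vector("list", n)
  wts <- vector("list", n)
  if (nrow(e)) {
    ends <- c(ai, bi)
    other <- c(bi, ai)
    w <- c(e$weight, e$weight)
    o <- order(ends, other)
    ends <- ends[o]; other <- other[o]; w <- w[o]
    runs <- split(seq_along(ends), ends)
    for (k in names(runs)) {
      i <- as.integer(k)
      idx <- runs[[k]]
      nbr[[i]] <- other[idx]
      wts[[i]] <- w[idx]
    }
  }
  for (i in seq_len(n)) {
    if (is.null(nbr[[i]])) { nbr[[i]] <- integer(0); wts[[i]] <- numeric(0) }
  }
  list(nodes = nodes, nbr = nbr, wts = wts,
       deg = vapply(nbr, length, integer(1)))
}

#' Aggregate a contact stream into a weighted graph
#'
#' Selects the training contacts according to `window` and accumulates edge
#' weights under `scheme` (see [weighting_scheme()] for the per-contact
#' increments; the contact index `k` runs over all selected contacts in
#' stream order, not per pair). Under flat weighting the edge weight equals
#' the integer number of contacts between its endpoints within the window.
#' All registry nodes of the stream are carried into the graph, so
#' participants with no training contact appear as isolated nodes.
#'
#' @param stream A [contact_stream].
#' @param window A [window_spec]. Training events are those with
#'   `t0 <= timestamp < t1` (`by_time`), or the last `n_contacts` events with
#'   `timestamp < t1` (`by_contact_count`; a warning is issued if fewer are
#'   available).
#' @param scheme A [weighting_scheme]; default flat.
#' @return A [weighted_graph]. A window containing no events yields a graph
#'   with nodes but no edges.
#' @examples
#' cs <- contact_stream(c(1, 2, 3), rep("a", 3), rep("b", 3))
#' build_graph(cs, window_spec(0, 10))$edges          # flat weight 3
#' build_graph(cs, window_spec(0, 10),
#'             weighting_scheme("linear"))$edges      # (1+2+3)/3 = 2
#' @export
build_graph <- function(stream, window, scheme = weighting_scheme("flat")) {
  stopifnot(inherits(stream, "contact_stream"),
            inherits(window, "window_spec"),
            inherits(scheme, "weighting_scheme"))
  ev <- stream$events
  if (window$mode == "by_time") {
    sel <- which(ev$timestamp >= window$t0 & ev$timestamp < window$t1)
  } else {
    avail <- which(ev$timestamp < window$t1)
    if (length(avail) < window$n_contacts) {
      warning("only ", length(avail), " contacts available before t1; ",
              "requested ", window$n_contacts)
      sel <- avail
    } else {
      sel <- avail[seq.int(length(avail) - window$n_contacts + 1L,
                           length(avail))]
    }
  }
  n <- length(sel)
  if (n == 0L)
    return(weighted_graph(nodes = stream$nodes))
  inc <- switch(scheme$kind,
    flat = rep(1, n),
    linear = seq_len(n) / n,
    exponential = {
      gamma <- scheme$epsilon^(1 / n)
      gamma^(n - seq_len(n))
    })
  key <- paste(ev$node_a[sel], ev$node_b[sel], sep = "\r")
  w <- rowsum(inc, key, reorder = TRUE)
  pair <- strsplit(rownames(w), "\r", fixed = TRUE)
  weighted_graph(node_a = vapply(pair, `[`, "", 1L),
                 node_b = vapply(pair, `[`, "", 2L),
                 weight = as.numeric(w),
                 nodes = stream$nodes)
}

#' Enumerate candidate pairs for link prediction
#'
#' A candidate is an unordered pair of registry nodes with no recorded
#' contact at any time strictly before the prediction time `t1` — exclusion
#' uses the full observed history from stream onset, not just the training
#' window, so a pair once connected never re-enters the candidate set.
#'
#' @param stream A nonempty [contact_stream].
#' @param t1 Prediction time in seconds.
#' @return Data frame with columns `node_a`, `node_b` (canonical order),
#'   one row per candidate pair.
#' @export
candidate_pairs <- function(stream, t1) {
  stopifnot(inherits(stream, "contact_stream"))
  nodes <- stream$nodes
  if (length(nodes) == 0L) stop("candidate_pairs requires a nonempty stream")
  if (length(nodes) < 2L)
    return(data.frame(node_a = character(0), node_b = character(0),
                      stringsAsFactors = FALSE))
  idx <- which(upper.tri(matrix(0, length(nodes), length(nodes))),
               arr.ind = TRUE)
  a <- nodes[idx[, 1L]]
  b <- nodes[idx[, 2L]]
  ev <- stream$events
  pre <- ev$timestamp < t1
  seen <- unique(paste(ev$node_a[pre], ev$node_b[pre], sep = "\r"))
  keep <- !(paste(a, b, sep = "\r") %in% seen)
  data.frame(node_a = a[keep], node_b = b[keep], stringsAsFactors = FALSE)
}

#' Descriptive network statistics
#'
#' Summary statistics of the aggregated (binary-topology) graph, of the sort
#' used to compare contact networks with other network families: size,
#' average degree, clustering, characteristic path length, and the degree
#' histogram. Edge weights are ignored; paths are unweighted.
#'
#' @param graph A [weighted_graph].
#' @return An object of class `network_stats`: list with `n_nodes`,
#'   `n_edges`, `avg_degree` (`2 * n_edges / n_nodes`),
#'   `clustering` (mean local clustering coefficient, nodes of degree < 2
#'   contributing 0), `transitivity` (global clustering, for reference),
#'   `avg_path_length` (mean pairwise shortest-path distance within the
#'   largest connected component), and `degree_hist` (data frame `degree`,
#'   `count`).
#' @export
network_stats <- function(graph) {
  stopifnot(inherits(graph, "weighted_graph"))
  n <- length(graph$nodes)
  if (n == 0L || nrow(graph$edges) == 0L) {
    warning("graph has no edges; all statistics are 0")
    return(structure(list(n_nodes = n, n_edges = 0L, avg_degree = 0,
                          clustering = 0, transitivity = 0,
                          avg_path_length = 0,
                          degree_hist = data.frame(degree = integer(0),
                                                   count = integer(0))),
                     class = "network_stats"))
  }
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = graph$nodes))
  deg <- igraph::degree(g)
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  apl <- if (igraph::vcount(giant) > 1L)
    igraph::mean_distance(giant, directed = FALSE, unconnected = FALSE)
  else 0
  tab <- table(factor(deg, levels = 0:max(deg)))
  structure(list(
    n_nodes = n,
    n_edges = nrow(graph$edges),
    avg_degree = 2 * nrow(graph$edges) / n,
    clustering = mean(loc),
    transitivity = igraph::transitivity(g, type = "global"),
    avg_path_length = apl,
    degree_hist = data.frame(degree = as.integer(names(tab)),
                             count = as.integer(tab))),
    class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("<network_stats>\n")
  cat(sprintf("  nodes              %d\n", x$n_nodes))
  cat(sprintf("  edges              %d\n", x$n_edges))
  cat(sprintf("  average degree     %.4g\n", x$avg_degree))
  cat(sprintf("  clustering (local) %.4g\n", x$clustering))
  cat(sprintf("  transitivity       %.4g\n", x$transitivity))
  cat(sprintf("  avg path length    %.4g\n", x$avg_path_length))
  invisible(x)
}
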