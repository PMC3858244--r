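#' Available link-prediction methods
#'
#' Five classic neighborhood scores for unweighted graphs and their
#' weighted counterparts. With \eqn{\Gamma(x)} the neighbor set of `x`,
#' \eqn{w(x,y)} the edge weight, \eqn{O = \Gamma(x) \cap \Gamma(y)} the
#' common neighbors, and the \eqn{\alpha}-strength
#' \eqn{s_\alpha(z) = \sum_{u \in \Gamma(z)} w(z,u)^\alpha}:
#'
#' \describe{
#'   \item{CN}{\eqn{|O|} — common neighbors.}
#'   \item{AA}{\eqn{\sum_{z \in O} 1 / \log|\Gamma(z)|} — Adamic/Adar,
#'     discounting high-degree common neighbors.}
#'   \item{PA}{\eqn{|\Gamma(x)| \cdot |\Gamma(y)|} — preferential
#'     attachment.}
#'   \item{JC}{\eqn{|O| / |\Gamma(x) \cup \Gamma(y)|} — Jaccard
#'     coefficient.}
#'   \item{RA}{\eqn{\sum_{z \in O} 1 / |\Gamma(z)|} — resource allocation.}
#'   \item{WCN}{\eqn{\sum_{z \in O} (w(x,z)^\alpha + w(z,y)^\alpha)}.}
#'   \item{WAA}{\eqn{\sum_{z \in O} (w(x,z)^\alpha + w(z,y)^\alpha) /
#'     \log(1 + s_\alpha(z))}.}
#'   \item{WPA}{\eqn{s_\alpha(x) \cdot s_\alpha(y)}.}
#'   \item{WJC}{\eqn{\sum_{z \in O} (w(x,z)^\alpha + w(z,y)^\alpha) /
#'     (s_\alpha(x) + s_\alpha(y))}.}
#'   \item{WRA}{\eqn{\sum_{z \in O} (w(x,z)^\alpha + w(z,y)^\alpha) /
#'     s_\alpha(z)}.}
#' }
#'
#' The exponent \eqn{\alpha \in [0,1]} controls the contribution of link
#' weights: \eqn{\alpha = 0} ignores weights (every weight collapses to 1,
#' so e.g. WCN ranks identically to CN), while \eqn{\alpha = 1} uses the raw
#' weights (under flat aggregation, the plain contact counts). Intermediate
#' values damp heavy weights, boosting the relative contribution of weak
#' ties. Natural logarithms are used throughout; a common neighbor
#' necessarily has degree \eqn{\ge 2}, so \eqn{\log|\Gamma(z)|} is never
#' zero, and WAA uses \eqn{\log(1+s)} which is positive for any positive
#' strength.
#'
#' @format Character vector of the ten method names.
#' @export
lp_methods <- c("CN", "AA", "PA", "JC", "RA",
                "WCN", "WAA", "WPA", "WJC", "WRA")

lp_weighted_methods <- c("WCN", "WAA", "WPA", "WJC", "WRA")

check_method_alpha <- function(method, alpha) {
  if (!(method %in% lp_methods))
    stop("unknown method '", method, "'; must be one of ",
         paste(lp_methods, collapse = ", "))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a number in [0, 1]")
  invisible(TRUE)
}

# Score one pair from a precomputed wg_index. Degenerate conventions: an
# empty common neighborhood gives 0 for every O-summing method; an isolated
# endpoint gives 0 for PA/WPA (degree product) and JC/WJC (0/0 -> 0).
score_pair_idx <- function(idx, i, j, method, alpha, s_alpha = NULL) {
  ni <- idx$nbr[[i]]; nj <- idx$nbr[[j]]
  di <- length(ni); dj <- length(nj)
  if (method == "PA") return(as.numeric(di) * dj)
  if (method == "WPA") return(s_alpha[i] * s_alpha[j])
  if (method == "JC") {
    u <- length(unique(c(ni, nj)))
    if (u == 0L) return(0)
    return(length(intersect(ni, nj)) / u)
  }
  o <- intersect(ni, nj)
  if (length(o) == 0L) return(0)
  if (method == "CN") return(as.numeric(length(o)))
  if (method == "AA") return(sum(1 / log(idx$deg[o])))
  if (method == "RA") return(sum(1 / idx$deg[o]))
  # weighted O-summing methods share the alpha-powered endpoint term
  wio <- idx$wts[[i]][match(o, ni)]^alpha
  wjo <- idx$wts[[j]][match(o, nj)]^alpha
  term <- wio + wjo
  switch(method,
    WCN = sum(term),
    WAA = sum(term / log(1 + s_alpha[o])),
    WJC = {
      den <- s_alpha[i] + s_alpha[j]
      if (den == 0) 0 else sum(term) / den
    },
    WRA = sum(term / s_alpha[o]))
}

alpha_strengths <- function(idx, alpha) {
  vapply(idx$wts, function(w) sum(w^alpha), numeric(1))
}

#' Link-prediction score for a single node pair
#'
#' @param graph A [weighted_graph].
#' @param x,y Node identifiers; both must be in the graph's node set
#'   (possibly isolated).
#' @param method One of [lp_methods].
#' @param alpha Weight-contribution exponent in \[0, 1\]; ignored by the
#'   unweighted methods. Default 1.
#' @return A finite nonnegative score; higher means more likely link
#'   formation. Symmetric in `x`, `y`.
#' @examples
#' g1 <- weighted_graph(c("x", "x", "y", "y"), c("a", "b", "a", "b"),
#'                      c(2, 1, 3, 1))
#' score_pair(g1, "x", "y", "CN")           # 2
#' score_pair(g1, "x", "y", "WCN")          # (2+3) + (1+1) = 7
#' @export
score_pair <- function(graph, x, y, method = "CN", alpha = 1) {
  stopifnot(inherits(graph, "weighted_graph"))
  check_method_alpha(method, alpha)
  i <- match(as.character(x), graph$nodes)
  j <- match(as.character(y), graph$nodes)
  if (is.na(i)) stop("unknown node '", x, "'")
  if (is.na(j)) stop("unknown node '", y, "'")
  if (i == j) stop("score_pair requires two distinct nodes")
  idx <- wg_index(graph)
  s_alpha <- if (method %in% c("WPA", "WAA", "WJC", "WRA"))
    alpha_strengths(idx, alpha) else NULL
  score_pair_idx(idx, i, j, method, alpha, s_alpha)
}

#' Score a set of candidate pairs
#'
#' Applies one method to every candidate pair, producing a score table.
#' Candidates must be disjoint from the graph's existing edges (a candidate
#' is by definition a pair that has not yet interacted).
#'
#' @param graph A [weighted_graph].
#' @param candidates Data frame with columns `node_a`, `node_b` (as from
#'   [candidate_pairs()]), or a two-column character matrix.
#' @param method One of [lp_methods].
#' @param alpha Weight-contribution exponent in \[0, 1\]; default 1.
#' @return An object of class `score_table`: data frame `node_a`, `node_b`,
#'   `score` with attributes `method` and `alpha`.
#' @export
score_candidates <- function(graph, candidates, method = "CN", alpha = 1) {
  stopifnot(inherits(graph, "weighted_graph"))
  check_method_alpha(method, alpha)
  if (is.matrix(candidates))
    candidates <- data.frame(node_a = candidates[, 1L],
                             node_b = candidates[, 2L],
                             stringsAsFactors = FALSE)
  a <- as.character(candidates$node_a)
  b <- as.character(candidates$node_b)
  swap <- a > b
  if (any(swap)) { tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp }
  i <- match(a, graph$nodes)
  j <- match(b, graph$nodes)
  if (anyNA(i) || anyNA(j))
    stop("unknown node in candidates: '",
         c(a[is.na(i)], b[is.na(j)])[1L], "'")
  if (any(i == j)) stop("candidate pair with identical endpoints")
  if (nrow(graph$edges)) {
    ek <- paste(graph$edges$node_a, graph$edges$node_b, sep = "\r")
    hit <- paste(a, b, sep = "\r") %in% ek
    if (any(hit))
      stop("candidate pair (", a[hit][1L], ", ", b[hit][1L],
           ") is an existing edge")
  }
  idx <- wg_index(graph)
  s_alpha <- if (method %in% c("WPA", "WAA", "WJC", "WRA"))
    alpha_strengths(idx, alpha) else NULL
  score <- numeric(length(i))
  for (k in seq_along(i))
    score[k] <- score_pair_idx(idx, i[k], j[k], method, alpha, s_alpha)
  structure(data.frame(node_a = a, node_b = b, score = score,
                       stringsAsFactors = FALSE),
            method = method, alpha = alpha,
            class = c("score_table", "data.frame"))
}

#' Write a score table as TSV
#'
#' Rows `id_a id_b score` in canonical pair order.
#'
#' @param scores A `score_table` (from [score_candidates()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(inherits(scores, "score_table"))
  lines <- if (nrow(scores))
    paste(scores$node_a, scores$node_b, sprintf("%.10g", scores$score),
          sep = "\t")
  else character(0)
  writeLines(lines, path)
  invisible(path)
}
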