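# Independent oracles and small fixture builders shared across tests.
# The score oracle works on a dense weight matrix with explicit set
# arithmetic; it shares no code with the package's adjacency-list scoring.

# toy graph used in worked examples: x-a (2), x-b (1), y-a (3), y-b (1)
toy_graph_g1 <- function() {
  weighted_graph(c("x", "x", "y", "y"), c("a", "b", "a", "b"),
                 c(2, 1, 3, 1))
}

graph_to_matrix <- function(graph) {
  n <- length(graph$nodes)
  W <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    W[e$node_a[r], e$node_b[r]] <- e$weight[r]
    W[e$node_b[r], e$node_a[r]] <- e$weight[r]
  }
  W
}

# brute-force score via set arithmetic on the weight matrix
oracle_score <- function(W, x, y, method, alpha = 1) {
  Gx <- which(W[x, ] > 0)
  Gy <- which(W[y, ] > 0)
  O <- Gx[Gx %in% Gy]
  deg <- function(z) length(which(W[z, ] > 0))
  s_a <- function(z) sum(W[z, which(W[z, ] > 0)]^alpha)
  sum0 <- function(v) if (length(v)) sum(v) else 0
  switch(method,
    CN = length(O),
    AA = sum0(vapply(O, function(z) 1 / log(deg(z)), 0)),
    PA = deg(x) * deg(y),
    JC = {
      U <- union(Gx, Gy)
      if (length(U) == 0) 0 else length(O) / length(U)
    },
    RA = sum0(vapply(O, function(z) 1 / deg(z), 0)),
    WCN = sum0(vapply(O, function(z) W[x, z]^alpha + W[z, y]^alpha, 0)),
    WAA = sum0(vapply(O, function(z)
      (W[x, z]^alpha + W[z, y]^alpha) / log(1 + s_a(z)), 0)),
    WPA = s_a(x) * s_a(y),
    WJC = {
      den <- s_a(x) + s_a(y)
      if (den == 0) 0 else
        sum0(vapply(O, function(z) W[x, z]^alpha + W[z, y]^alpha, 0)) / den
    },
    WRA = sum0(vapply(O, function(z)
      (W[x, z]^alpha + W[z, y]^alpha) / s_a(z), 0)))
}

# Erdos-Renyi weighted graph on letter-named nodes
random_weighted_graph <- function(n, p = 0.3, max_w = 5L) {
  nodes <- sprintf("v%02d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p
  weighted_graph(nodes[idx[keep, 1L]], nodes[idx[keep, 2L]],
                 sample.int(max_w, sum(keep), replace = TRUE),
                 nodes = nodes)
}

all_pairs <- function(graph) {
  n <- length(graph$nodes)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(node_a = graph$nodes[idx[, 1L]],
             node_b = graph$nodes[idx[, 2L]],
             stringsAsFactors = FALSE)
}

non_edge_pairs <- function(graph) {
  p <- all_pairs(graph)
  if (nrow(graph$edges) == 0) return(p)
  ek <- paste(graph$edges$node_a, graph$edges$node_b, sep = "\r")
  p[!(paste(p$node_a, p$node_b, sep = "\r") %in% ek), , drop = FALSE]
}

# labeled candidates assembled directly from score/label vectors
make_labeled <- function(score, positive) {
  contactpred:::labeled_from_vectors(score, positive)
}

# trapezoidal area under the empirical ROC, the geometric AUC oracle
trapezoid_auc <- function(score, positive) {
  o <- order(score, decreasing = TRUE)
  pos <- positive[o]
  s <- score[o]
  last <- which(!duplicated(s, fromLast = TRUE))
  fpr <- c(0, cumsum(!pos)[last] / sum(!positive))
  tpr <- c(0, cumsum(pos)[last] / sum(positive))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
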