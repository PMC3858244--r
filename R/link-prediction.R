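#' Fit and evaluate a link predictor on one training/testing split
#'
#' The central entry point: builds the training graph from the contacts in
#' `[t0, t1)` (or the last `n_contacts` before `t1`) under the chosen
#' weighting scheme, enumerates the candidate pairs (no contact at any time
#' before `t1`), scores them with one method, labels them against the
#' testing window `[t1, t2)` with strong-tie threshold `S`, and computes
#' ROC/AUC.
#'
#' @param stream A [contact_stream].
#' @param t1 Prediction time (training end / testing start), seconds.
#' @param t2 Testing window end, seconds; `t1 < t2`.
#' @param t0 Training window start, seconds. Default 0.
#' @param method One of [lp_methods]. Default `"CN"`.
#' @param alpha Weight-contribution exponent in \[0, 1\]. Default 1.
#' @param S Strong-tie threshold (positive integer). Default 1.
#' @param weighting A [weighting_scheme()]. Default flat.
#' @param n_contacts If given, the training window is the last `n_contacts`
#'   contacts before `t1` instead of `[t0, t1)`.
#' @param threshold Optional score threshold for a precision/recall
#'   operating point.
#' @return An object of class `link_prediction`: list with `graph`,
#'   `labeled` (scored and labeled candidates), `eval` (an `eval_result`),
#'   `auc`, and the settings. Methods: `print`, `summary`, `coef` (named
#'   vector with the AUC and counts), `predict` (score new pairs on the
#'   training graph), `plot` (ROC curve).
#' @examples
#' fx <- planted_fixture("stationary")
#' fit <- link_prediction(fx$stream, t1 = fx$t1, t2 = fx$t2, method = "CN")
#' fit$auc
#' @export
link_prediction <- function(stream, t1, t2, t0 = 0, method = "CN",
                            alpha = 1, S = 1,
                            weighting = weighting_scheme("flat"),
                            n_contacts = NULL, threshold = NULL) {
  stopifnot(inherits(stream, "contact_stream"))
  window <- if (is.null(n_contacts)) window_spec(t0, t1)
            else window_spec(t0, t1, "by_contact_count", n_contacts)
  graph <- build_graph(stream, window, weighting)
  cand <- candidate_pairs(stream, t1)
  scores <- score_candidates(graph, cand, method, alpha)
  labeled <- label_candidates(stream, scores, t1, t2, S)
  eval <- roc_auc(labeled, threshold)
  structure(list(graph = graph, labeled = labeled, eval = eval,
                 auc = eval$auc, method = method, alpha = alpha, S = S,
                 window = window, weighting = weighting,
                 n_candidates = nrow(labeled),
                 n_positives = sum(labeled$positive),
                 call = match.call()),
            class = "link_prediction")
}

#' @export
print.link_prediction <- function(x, ...) {
  cat("<link_prediction>", x$method,
      if (x$method %in% lp_weighted_methods)
        sprintf("(alpha = %g)", x$alpha) else "",
      "\n")
  cat(sprintf("  training window [%g, %g) s, %s weighting\n",
              x$window$t0, x$window$t1, x$weighting$kind))
  cat(sprintf("  %d candidates, %d positives (S = %d)\n",
              x$n_candidates, x$n_positives, x$S))
  cat(sprintf("  AUC = %.4f\n", x$auc))
  invisible(x)
}

#' @export
summary.link_prediction <- function(object, ...) {
  print(object)
  pr <- pr_curve(object$labeled)
  best <- pr[which.max(ifelse(pr$precision + pr$recall > 0,
                              2 * pr$precision * pr$recall /
                                (pr$precision + pr$recall), 0)), ]
  cat(sprintf(
    "  best-F1 operating point: threshold %.4g, precision %.3f, recall %.3f\n",
    best$threshold, best$precision, best$recall))
  invisible(object)
}

#' @export
coef.link_prediction <- function(object, ...) {
  c(auc = object$auc, n_candidates = object$n_candidates,
    n_positives = object$n_positives)
}

#' @export
predict.link_prediction <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) return(object$labeled)
  score_candidates(object$graph, pairs, object$method, object$alpha)
}

#' @export
plot.link_prediction <- function(x, ...) {
  roc <- x$eval$roc
  plot(roc$fpr, roc$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "false positive rate", ylab = "recall (true positive rate)",
       main = sprintf("%s ROC, AUC = %.3f", x$method, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
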