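#' Compare several link-prediction methods on one split
#'
#' Scores all candidates with each method on a fixed training/testing
#' split, and reports per-method AUC together with the matrix of pairwise
#' DeLong tests (all methods are evaluated on the same candidates and
#' labels, so the paired design applies).
#'
#' @param stream A [contact_stream].
#' @param t1,t2,t0,S,weighting,n_contacts As in [link_prediction()].
#' @param methods Character vector of methods from [lp_methods]. Default
#'   all ten.
#' @param alpha Weight-contribution exponent for the weighted methods.
#' @return An object of class `lp_comparison`: list with `table` (data
#'   frame `method`, `auc`, `n_candidates`, `n_positives`), `delong_p` and
#'   `delong_dauc` (square matrices), and `labeled` (per-method labeled
#'   candidates, for further analysis).
#' @export
run_method_comparison <- function(stream, t1, t2, t0 = 0,
                                  methods = lp_methods, alpha = 1, S = 1,
                                  weighting = weighting_scheme("flat"),
                                  n_contacts = NULL) {
  stopifnot(all(methods %in% lp_methods))
  window <- if (is.null(n_contacts)) window_spec(t0, t1)
            else window_spec(t0, t1, "by_contact_count", n_contacts)
  graph <- build_graph(stream, window, weighting)
  cand <- candidate_pairs(stream, t1)
  labeled <- lapply(methods, function(m)
    label_candidates(stream, score_candidates(graph, cand, m, alpha),
                     t1, t2, S))
  names(labeled) <- methods
  auc <- vapply(labeled, function(l) roc_auc(l)$auc, numeric(1))
  k <- length(methods)
  p <- matrix(1, k, k, dimnames = list(methods, methods))
  d <- matrix(0, k, k, dimnames = list(methods, methods))
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      dl <- delong_test(labeled[[i]], labeled[[j]])
      p[i, j] <- p[j, i] <- dl$p_value
      d[i, j] <- dl$auc_a - dl$auc_b
      d[j, i] <- -d[i, j]
    }
  }
  structure(list(
    table = data.frame(method = methods, auc = unname(auc),
                       n_candidates = nrow(cand),
                       n_positives = sum(labeled[[1L]]$positive),
                       stringsAsFactors = FALSE),
    delong_p = p, delong_dauc = d, labeled = labeled),
    class = "lp_comparison")
}

#' @export
print.lp_comparison <- function(x, ...) {
  cat("<lp_comparison>", nrow(x$table), "methods,",
      x$table$n_candidates[1L], "candidates,",
      x$table$n_positives[1L], "positives\n")
  print(x$table[order(-x$table$auc), c("method", "auc")], row.names = FALSE)
  invisible(x)
}

#' Sweep the weight-contribution exponent alpha
#'
#' Evaluates weighted methods over a grid of `alpha` values on a fixed
#' split. At `alpha = 0` the weighted scores rank candidates identically to
#' their unweighted counterparts (for WCN/WPA/WRA/WJC), so that row
#' reproduces the unweighted AUC; `alpha = 1` uses the raw aggregated
#' weights. A dip at `alpha = 1` below `alpha = 0` indicates that raw
#' contact counts are a noisy signal and weak ties deserve more weight.
#'
#' @param stream,t1,t2,t0,S,weighting,n_contacts As in [link_prediction()].
#' @param methods Weighted methods to sweep. Default all five.
#' @param alpha_grid Numeric vector of exponents in \[0, 1\].
#' @return Data frame `method`, `alpha`, `auc`.
#' @export
sweep_alpha <- function(stream, t1, t2, t0 = 0,
                        methods = lp_weighted_methods,
                        alpha_grid = seq(0, 1, by = 0.1), S = 1,
                        weighting = weighting_scheme("flat"),
                        n_contacts = NULL) {
  if (!all(methods %in% lp_weighted_methods))
    stop("sweep_alpha applies to weighted methods only")
  if (any(alpha_grid < 0 | alpha_grid > 1))
    stop("alpha grid must lie within [0, 1]")
  window <- if (is.null(n_contacts)) window_spec(t0, t1)
            else window_spec(t0, t1, "by_contact_count", n_contacts)
  graph <- build_graph(stream, window, weighting)
  cand <- candidate_pairs(stream, t1)
  grid <- expand.grid(method = methods, alpha = alpha_grid,
                      stringsAsFactors = FALSE)
  grid$auc <- vapply(seq_len(nrow(grid)), function(r) {
    lab <- label_candidates(
      stream,
      score_candidates(graph, cand, grid$method[r], grid$alpha[r]),
      t1, t2, S)
    roc_auc(lab)$auc
  }, numeric(1))
  grid[order(grid$method, grid$alpha), ]
}

#' Sweep the strong-tie threshold S
#'
#' Relabels the candidates for each `S` in the grid and recomputes AUC.
#' The positive set shrinks monotonically as `S` grows; cells where no
#' positive (or no negative) remains are reported with `auc = NA` rather
#' than dropped.
#'
#' @param stream,t1,t2,t0,alpha,weighting,n_contacts As in
#'   [link_prediction()].
#' @param methods Methods to evaluate. Default the five unweighted ones.
#' @param S_grid Vector of positive integers.
#' @return Data frame `method`, `S`, `n_positives`, `auc` (`NA` when
#'   undefined).
#' @export
sweep_strong_ties <- function(stream, t1, t2, t0 = 0,
                              methods = c("CN", "AA", "PA", "JC", "RA"),
                              S_grid = c(1, 2, 4, 6, 8), alpha = 1,
                              weighting = weighting_scheme("flat"),
                              n_contacts = NULL) {
  stopifnot(all(methods %in% lp_methods), all(S_grid >= 1))
  window <- if (is.null(n_contacts)) window_spec(t0, t1)
            else window_spec(t0, t1, "by_contact_count", n_contacts)
  graph <- build_graph(stream, window, weighting)
  cand <- candidate_pairs(stream, t1)
  scored <- lapply(methods, function(m)
    score_candidates(graph, cand, m, alpha))
  names(scored) <- methods
  grid <- expand.grid(method = methods, S = as.integer(S_grid),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    lab <- label_candidates(stream, scored[[grid$method[r]]], t1, t2,
                            grid$S[r])
    npos <- sum(lab$positive)
    auc <- if (npos == 0L || npos == nrow(lab)) NA_real_
           else roc_auc(lab)$auc
    c(n_positives = npos, auc = auc)
  })
  grid$n_positives <- vapply(res, `[[`, numeric(1), "n_positives")
  grid$auc <- vapply(res, `[[`, numeric(1), "auc")
  grid[order(grid$method, grid$S), ]
}

#' Sweep the training-window length
#'
#' Evaluates one method while varying either the training start `t0`
#' (window measured in time) or the number of most recent contacts used
#' (window measured in contacts). The candidate set depends only on the
#' history before `t1`, so it is identical across the grid; only the
#' training graph changes. On bursty, drifting contact data a longer
#' window is not necessarily better — old contacts can actively mislead.
#'
#' @param stream,t1,t2,method,alpha,S,weighting As in [link_prediction()].
#' @param t0_grid Numeric vector of training starts (seconds), or `NULL`.
#' @param n_contacts_grid Integer vector of contact counts, or `NULL`.
#'   Exactly one of `t0_grid`, `n_contacts_grid` must be given.
#' @return Data frame with the grid column (`t0` or `n_contacts`),
#'   `n_train_contacts`, and `auc` (`NA` where the window has no training
#'   contact or a single-class labeling).
#' @export
sweep_training_window <- function(stream, t1, t2, t0_grid = NULL,
                                  n_contacts_grid = NULL, method = "CN",
                                  alpha = 1, S = 1,
                                  weighting = weighting_scheme("flat")) {
  if (is.null(t0_grid) == is.null(n_contacts_grid))
    stop("give exactly one of t0_grid or n_contacts_grid")
  cand <- candidate_pairs(stream, t1)
  one <- function(window) {
    ntr <- if (window$mode == "by_time")
      sum(stream$events$timestamp >= window$t0 &
          stream$events$timestamp < window$t1)
    else min(window$n_contacts, sum(stream$events$timestamp < window$t1))
    if (ntr == 0L) return(c(ntr, NA_real_))
    graph <- build_graph(stream, window, weighting)
    lab <- label_candidates(stream,
                            score_candidates(graph, cand, method, alpha),
                            t1, t2, S)
    npos <- sum(lab$positive)
    auc <- if (npos == 0L || npos == nrow(lab)) NA_real_
           else roc_auc(lab)$auc
    c(ntr, auc)
  }
  if (!is.null(t0_grid)) {
    res <- vapply(t0_grid, function(t0) one(window_spec(t0, t1)),
                  numeric(2))
    data.frame(t0 = t0_grid, n_train_contacts = res[1L, ],
               auc = res[2L, ])
  } else {
    res <- vapply(n_contacts_grid, function(nc)
      suppressWarnings(one(window_spec(0, t1, "by_contact_count", nc))),
      numeric(2))
    data.frame(n_contacts = as.integer(n_contacts_grid),
               n_train_contacts = res[1L, ], auc = res[2L, ])
  }
}

#' Compare flat and decaying weighting schemes
#'
#' Evaluates one weighted method under four aggregations: flat weighting of
#' the full history (`flat_full`), flat weighting with the training start
#' chosen from `t0_grid` to maximize AUC (`flat_optimal`, an in-sample
#' selection — the same testing window is used for selection and
#' evaluation, exactly as when tuning the training length by hand), linear
#' decay, and exponential decay over the full history. On drifting contact
#' data, decaying weights recover most of the benefit of the tuned window
#' without knowing where to cut.
#'
#' @param stream,t1,t2,method,alpha,S As in [link_prediction()]; `method`
#'   defaults to `"WCN"`.
#' @param t0_grid Training starts searched for `flat_optimal`; the first
#'   element is also the `flat_full` start (default 0).
#' @param epsilon Exponential decay floor, see [weighting_scheme()].
#' @return An object of class `lp_weighting_comparison`: list with `table`
#'   (data frame `scheme`, `t0`, `auc`), `delong_exp_vs_flat_full` and
#'   `delong_exp_vs_flat_optimal` (paired [delong_test()] results).
#' @export
compare_weighting <- function(stream, t1, t2, method = "WCN", alpha = 1,
                              S = 1, t0_grid = c(0, 12, 24, 36) * 3600,
                              epsilon = 0.01) {
  cand <- candidate_pairs(stream, t1)
  lab_for <- function(scheme, t0) {
    graph <- build_graph(stream, window_spec(t0, t1), scheme)
    label_candidates(stream,
                     score_candidates(graph, cand, method, alpha),
                     t1, t2, S)
  }
  t0_full <- t0_grid[1L]
  flat <- weighting_scheme("flat")
  lab_flat <- lapply(t0_grid, function(t0) lab_for(flat, t0))
  auc_flat <- vapply(lab_flat, function(l) roc_auc(l)$auc, numeric(1))
  best <- which.max(auc_flat)
  lab_lin <- lab_for(weighting_scheme("linear"), t0_full)
  lab_exp <- lab_for(weighting_scheme("exponential", epsilon), t0_full)
  tab <- data.frame(
    scheme = c("flat_full", "flat_optimal", "linear", "exponential"),
    t0 = c(t0_full, t0_grid[best], t0_full, t0_full),
    auc = c(auc_flat[1L], auc_flat[best], roc_auc(lab_lin)$auc,
            roc_auc(lab_exp)$auc),
    stringsAsFactors = FALSE)
  structure(list(
    table = tab,
    delong_exp_vs_flat_full = delong_test(lab_exp, lab_flat[[1L]]),
    delong_exp_vs_flat_optimal = delong_test(lab_exp, lab_flat[[best]])),
    class = "lp_weighting_comparison")
}

#' @export
print.lp_weighting_comparison <- function(x, ...) {
  cat("<lp_weighting_comparison>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  exponential vs flat_full:    p = %.4g\n",
              x$delong_exp_vs_flat_full$p_value))
  cat(sprintf("  exponential vs flat_optimal: p = %.4g\n",
              x$delong_exp_vs_flat_optimal$p_value))
  invisible(x)
}

#' Read a flat key-value experiment configuration file
#'
#' Minimal YAML-style configuration: one `key: value` per line, `#`
#' comments, blank lines ignored. Values that parse as numbers become
#' numeric; comma-separated values become vectors. Used by the command-line
#' interface; every flag there overrides the file.
#'
#' @param path Path to the configuration file.
#' @return Named list of values.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.-]+)\\s*:\\s*(.*?)\\s*$",
                                ln))[[1L]]
    if (length(m) != 3L) stop("malformed config line: '", ln, "'")
    vals <- trimws(strsplit(m[3L], ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(vals))
    out[[m[2L]]] <- if (length(vals) && !anyNA(num)) num else vals
  }
  out
}
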