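h <- 3600

test_that("link_prediction object is internally consistent", {
  fx <- planted_fixture("stationary", seed = 2)
  fit <- link_prediction(fx$stream, t1 = fx$t1, t2 = fx$t2, method = "RA",
                         threshold = 0.2)
  expect_s3_class(fit, "link_prediction")
  expect_equal(fit$auc, roc_auc(fit$labeled)$auc)
  expect_equal(fit$n_candidates,
               nrow(candidate_pairs(fx$stream, fx$t1)))
  expect_equal(unname(coef(fit)["auc"]), fit$auc)
  expect_output(print(fit), "AUC")
  expect_output(summary(fit), "operating point")
  # predict() rescales arbitrary pairs on the training graph
  p <- predict(fit, data.frame(node_a = fit$labeled$node_a[1],
                               node_b = fit$labeled$node_b[1]))
  expect_equal(p$score, fit$labeled$score[1])
})

test_that("method comparison is consistent with single-shot runs", {
  fx <- planted_fixture("stationary", seed = 2)
  cmp <- run_method_comparison(fx$stream, fx$t1, fx$t2,
                               methods = c("CN", "RA", "PA"))
  fit <- link_prediction(fx$stream, t1 = fx$t1, t2 = fx$t2, method = "RA")
  expect_equal(cmp$table$auc[cmp$table$method == "RA"], fit$auc)
  # diagonal of the DeLong matrix is the trivial self-comparison
  expect_true(all(diag(cmp$delong_p) == 1))
  expect_equal(cmp$delong_dauc["CN", "RA"], -cmp$delong_dauc["RA", "CN"])
  # duplicated methods give a null paired comparison
  cmp2 <- run_method_comparison(fx$stream, fx$t1, fx$t2,
                                methods = c("CN", "CN"))
  expect_equal(cmp2$delong_p[1, 2], 1)
  expect_equal(cmp2$delong_dauc[1, 2], 0)
  # single-method config degenerates to a 1x1 matrix
  cmp1 <- run_method_comparison(fx$stream, fx$t1, fx$t2, methods = "CN")
  expect_equal(dim(cmp1$delong_p), c(1L, 1L))
  expect_equal(cmp1$delong_p[1, 1], 1)
})

test_that("common-neighbor methods beat chance on triadic-closure streams", {
  fx <- planted_fixture("stationary", seed = 1)
  cmp <- run_method_comparison(fx$stream, fx$t1, fx$t2,
                               methods = c("CN", "RA"))
  expect_gt(cmp$table$auc[cmp$table$method == "CN"], 0.6)
  expect_gt(cmp$table$auc[cmp$table$method == "RA"], 0.6)
  # a random-score baseline on the same candidates stays near 0.5
  set.seed(1)
  lab <- cmp$labeled[["CN"]]
  rnd <- replicate(50, {
    r <- lab
    r$score <- runif(nrow(r))
    roc_auc(r)$auc
  })
  expect_gt(mean(rnd), 0.45)
  expect_lt(mean(rnd), 0.55)
})

test_that("alpha sweep validates its grid and hits unweighted AUC at 0", {
  fx <- planted_fixture("stationary", seed = 3)
  expect_error(sweep_alpha(fx$stream, fx$t1, fx$t2,
                           alpha_grid = c(0, 2)), "\\[0, 1\\]")
  expect_error(sweep_alpha(fx$stream, fx$t1, fx$t2, methods = "CN"),
               "weighted")
  sw <- sweep_alpha(fx$stream, fx$t1, fx$t2,
                    methods = c("WCN", "WRA"), alpha_grid = c(0, 1))
  expect_true(all(sw$auc >= 0 & sw$auc <= 1))
  cmp <- run_method_comparison(fx$stream, fx$t1, fx$t2,
                               methods = c("CN", "RA"))
  expect_equal(sw$auc[sw$method == "WCN" & sw$alpha == 0],
               cmp$table$auc[cmp$table$method == "CN"])
  expect_equal(sw$auc[sw$method == "WRA" & sw$alpha == 0],
               cmp$table$auc[cmp$table$method == "RA"])
})

test_that("strong-tie sweep has non-increasing positives and flags empties", {
  fx <- planted_fixture("stationary", seed = 4)
  sw <- sweep_strong_ties(fx$stream, fx$t1, fx$t2, methods = "CN",
                          S_grid = c(1, 2, 4, 6, 8, 1000))
  expect_true(all(diff(sw$n_positives) <= 0))
  expect_true(is.na(sw$auc[sw$S == 1000]))   # undefined, not dropped
  expect_equal(sw$n_positives[sw$S == 1000], 0)
})

test_that("training-window sweep matches single-shot and flags empty windows", {
  fx <- planted_fixture("stationary", seed = 5)
  sw <- sweep_training_window(fx$stream, fx$t1, fx$t2,
                              t0_grid = c(0, 24 * h, fx$t1 - 1))
  one <- link_prediction(fx$stream, t1 = fx$t1, t2 = fx$t2, t0 = 24 * h)
  expect_equal(sw$auc[sw$t0 == 24 * h], one$auc)
  # a window of one second before t1 has (almost surely) no contacts
  expect_true(is.na(sw$auc[3]) || sw$n_train_contacts[3] > 0)
  swc <- sweep_training_window(fx$stream, fx$t1, fx$t2,
                               n_contacts_grid = c(500, 1000))
  expect_equal(nrow(swc), 2L)
  cfit <- link_prediction(fx$stream, t1 = fx$t1, t2 = fx$t2,
                          n_contacts = 1000)
  expect_equal(swc$auc[swc$n_contacts == 1000], cfit$auc)
  expect_error(sweep_training_window(fx$stream, fx$t1, fx$t2),
               "exactly one")
})

test_that("weighting comparison reports all four schemes coherently", {
  fx <- planted_fixture("stationary", seed = 6)
  cw <- compare_weighting(fx$stream, fx$t1, fx$t2,
                          t0_grid = c(0, 12, 24) * h)
  expect_setequal(cw$table$scheme,
                  c("flat_full", "flat_optimal", "linear", "exponential"))
  expect_gte(cw$table$auc[cw$table$scheme == "flat_optimal"],
             cw$table$auc[cw$table$scheme == "flat_full"])
  # near-flat decay reproduces flat weighting on a stationary stream
  cw1 <- compare_weighting(fx$stream, fx$t1, fx$t2, t0_grid = 0,
                           epsilon = 0.999999)
  aucs <- cw1$table$auc
  expect_lt(max(aucs) - min(aucs), 0.02)
})

test_that("single-contact streams give identical unit weights in all schemes", {
  cs <- contact_stream(5, "a", "b")
  for (kind in c("flat", "linear", "exponential")) {
    g <- build_graph(cs, window_spec(0, 10), weighting_scheme(kind))
    expect_equal(g$edges$weight, 1)
  }
})

test_that("experiment runs are reproducible end to end", {
  fx1 <- planted_fixture("drifting", seed = 11)
  fx2 <- planted_fixture("drifting", seed = 11)
  expect_identical(fx1$stream, fx2$stream)
  r1 <- sweep_strong_ties(fx1$stream, fx1$t1, fx1$t2, methods = "CN",
                          S_grid = c(1, 2))
  r2 <- sweep_strong_ties(fx2$stream, fx2$t1, fx2$t2, methods = "CN",
                          S_grid = c(1, 2))
  expect_identical(r1, r2)
})

test_that("flat key-value configs parse into typed lists", {
  path <- tempfile()
  writeLines(c("# comment", "t1: 172800", "method: CN,RA",
               "alpha_grid: 0, 0.5, 1", "input: contacts.tsv"), path)
  cfg <- read_experiment_config(path)
  expect_equal(cfg$t1, 172800)
  expect_equal(cfg$method, c("CN", "RA"))
  expect_equal(cfg$alpha_grid, c(0, 0.5, 1))
  expect_equal(cfg$input, "contacts.tsv")
  writeLines("no colon here", path)
  expect_error(read_experiment_config(path), "malformed")
})
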