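test_that("flat weights are contact counts and conserve the total", {
  cs <- contact_stream(c(1, 2, 3, 4, 5), c("1", "1", "1", "2", "3"),
                       c("2", "2", "2", "3", "4"))
  g <- build_graph(cs, window_spec(0, 10))
  expect_equal(g$edges$weight[g$edges$node_a == "1"], 3)
  expect_equal(sum(g$edges$weight), 5)  # one unit per training contact
  # only events in [t0, t1) count
  g2 <- build_graph(cs, window_spec(2, 4))
  expect_equal(sum(g2$edges$weight), 2)
  expect_identical(g2$nodes, cs$nodes)  # registry retained as isolates
})

test_that("decay increments follow the stated schedules", {
  cs <- contact_stream(1:4, rep("a", 4), rep("b", 4))
  lin <- build_graph(cs, window_spec(0, 10), weighting_scheme("linear"))
  expect_equal(lin$edges$weight, (1 + 2 + 3 + 4) / 4)
  ex <- build_graph(cs, window_spec(0, 10),
                    weighting_scheme("exponential", 0.01))
  gamma <- 0.01^(1 / 4)
  expect_equal(ex$edges$weight, gamma^3 + gamma^2 + gamma + 1)
  expect_equal(ex$edges$weight, 1.4479, tolerance = 1e-4)

  # later contacts on the same pair contribute strictly more
  mixed <- contact_stream(1:6, rep(c("a", "c"), 3), rep(c("b", "d"), 3))
  for (kind in c("linear", "exponential")) {
    inc <- switch(kind,
      linear = (1:6) / 6,
      exponential = (0.01^(1 / 6))^(6 - (1:6)))
    expect_true(all(diff(inc) > 0))
    g <- build_graph(mixed, window_spec(0, 10), weighting_scheme(kind))
    expect_equal(g$edges$weight[g$edges$node_a == "a"],
                 sum(inc[c(1, 3, 5)]))
  }
})

test_that("exponential weighting degenerates to flat as epsilon -> 1", {
  set.seed(42)
  cs <- contact_stream(sort(runif(200, 0, 100)),
                       sample(letters[1:8], 200, TRUE),
                       sample(letters[9:16], 200, TRUE))
  flat <- build_graph(cs, window_spec(0, 100))
  near <- build_graph(cs, window_spec(0, 100),
                      weighting_scheme("exponential", 0.999999))
  expect_equal(near$edges$weight, flat$edges$weight, tolerance = 1e-3)
})

test_that("contact-count windows take the most recent contacts", {
  cs <- contact_stream(1:10, rep("a", 10),
                       c(rep("b", 5), rep("c", 5)))
  g <- build_graph(cs, window_spec(0, 100, "by_contact_count",
                                   n_contacts = 5))
  # only the last five contacts (all on a-c) are used
  expect_equal(g$edges$node_b, "c")
  expect_equal(g$edges$weight, 5)
  expect_warning(
    build_graph(cs, window_spec(0, 100, "by_contact_count",
                                n_contacts = 50)),
    "available")
})

test_that("same-timestamp events do not depend on input order", {
  a <- contact_stream(c(5, 5, 5), c("x", "a", "m"), c("y", "b", "n"))
  b <- contact_stream(c(5, 5, 5), c("m", "x", "a"), c("n", "y", "b"))
  for (kind in c("linear", "exponential"))
    expect_identical(
      build_graph(a, window_spec(0, 10), weighting_scheme(kind)),
      build_graph(b, window_spec(0, 10), weighting_scheme(kind)))
})

test_that("candidate pairs are those never contacted before t1", {
  cs <- contact_stream(c(1, 2, 30), c("a", "c", "a"), c("b", "d", "c"))
  cand <- candidate_pairs(cs, 10)
  expect_equal(nrow(cand), 4L)  # C(4,2) - 2 observed pairs
  expect_setequal(paste(cand$node_a, cand$node_b),
                  c("a c", "a d", "b c", "b d"))
  # exclusion uses the full history before t1, not the training window
  cand2 <- candidate_pairs(cs, 31)
  expect_false("a c" %in% paste(cand2$node_a, cand2$node_b))
  # boundary: an event exactly at t1 does not exclude
  expect_true("a c" %in% with(candidate_pairs(cs, 30),
                              paste(node_a, node_b)))
  # no history -> all pairs; full history -> complement can be empty
  expect_equal(nrow(candidate_pairs(cs, 0)), choose(4, 2))
  tri <- contact_stream(1:3, c("a", "a", "b"), c("b", "c", "c"))
  expect_equal(nrow(candidate_pairs(tri, 10)), 0L)
})

test_that("network statistics match closed forms on small graphs", {
  tri <- weighted_graph(c("a", "a", "b"), c("b", "c", "c"), c(1, 1, 1))
  s <- network_stats(tri)
  expect_equal(s$avg_degree, 2)
  expect_equal(s$clustering, 1)
  expect_equal(s$avg_path_length, 1)

  path <- weighted_graph(c("a", "b"), c("b", "c"), c(1, 1))
  s <- network_stats(path)
  expect_equal(s$avg_degree, 4 / 3)
  expect_equal(s$clustering, 0)
  expect_equal(s$avg_path_length, 4 / 3)

  star <- weighted_graph(rep("h", 3), c("a", "b", "c"), rep(1, 3))
  s <- network_stats(star)
  expect_equal(s$avg_degree, 1.5)
  expect_equal(s$clustering, 0)
  expect_equal(sum(s$degree_hist$count), 4L)

  expect_warning(s0 <- network_stats(weighted_graph()), "no edges")
  expect_equal(s0$n_edges, 0L)
})
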