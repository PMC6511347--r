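# Blast-in-gate percentages, pattern dissimilarity and the screening call.

# a hand-made square gate_region with a uniform reference density
square_gate <- function(lo = 0, hi = 1, type = "hypergranular", n = 16) {
  gate_region(type, 1L,
              rbind(c(lo, lo), c(hi, lo), c(hi, hi), c(lo, hi)),
              density = list(grid = matrix(1 / n^2, n, n),
                             xlim = c(lo, hi), ylim = c(lo, hi), n = n),
              containment = 1.0)
}

test_that("percent_in_gate covers full, empty and half-split containment", {
  g <- square_gate()
  inside <- matrix(runif(600, 0.2, 0.8), ncol = 2)
  expect_equal(percent_in_gate(inside, g), 100)
  outside <- matrix(runif(600, 2, 3), ncol = 2)
  expect_equal(percent_in_gate(outside, g), 0)
  set.seed(51)
  pts <- matrix(runif(20000), ncol = 2)
  left <- square_gate(0, 1)
  left$vertices <- rbind(c(0, 0), c(0.5, 0), c(0.5, 1), c(0, 1))
  p <- percent_in_gate(pts, left)
  expect_lt(abs(p - 50), 3 * 100 * sqrt(0.25 / 10000))
})

test_that("percent_in_gate equals a brute-force per-point recount", {
  set.seed(53)
  ang <- 2 * pi * (0:6) / 7
  v <- cbind(0.4 * cos(ang), 0.4 * sin(ang))
  g <- square_gate(); g$vertices <- v
  pts <- matrix(runif(4000, -0.6, 0.6), ncol = 2)
  # independent scalar crossing-count oracle
  inside1 <- vapply(seq_len(nrow(pts)), function(k) {
    x <- pts[k, 1]; y <- pts[k, 2]; cnt <- 0L
    n <- nrow(v); j <- n
    for (i in seq_len(n)) {
      if ((v[i, 2] > y) != (v[j, 2] > y) &&
          x < (v[j, 1] - v[i, 1]) * (y - v[i, 2]) / (v[j, 2] - v[i, 2]) + v[i, 1])
        cnt <- cnt + 1L
      j <- i
    }
    cnt %% 2L == 1L
  }, TRUE)
  expect_equal(percent_in_gate(pts, g), 100 * mean(inside1))
})

test_that("pattern dissimilarity: identity 0, disjoint support 1", {
  g <- square_gate(n = 8)
  # a sample exactly reproducing cell centers of a known histogram
  p <- matrix(0, 8, 8); p[2, 3] <- 0.5; p[6, 7] <- 0.5
  expect_equal(radargate:::js_distance(p, p), 0)
  q <- matrix(0, 8, 8); q[4, 4] <- 1
  expect_equal(radargate:::js_distance(p, q), 1)
  expect_lt(radargate:::js_distance(p, (p + q) / 2), 1)
})

test_that("a sample drawn from the stored reference density scores low", {
  set.seed(55)
  tmpl <- tiny_template()
  g <- tmpl$gates$hypergranular[["1"]]
  d <- g$density
  # sample cells by the stored probabilities, jitter uniformly within cells
  n <- 10000
  cells <- sample.int(d$n^2, n, replace = TRUE, prob = as.vector(d$grid))
  ix <- (cells - 1) %% d$n + 1
  iy <- (cells - 1) %/% d$n + 1
  px <- d$xlim[1] + (ix - runif(n)) / d$n * diff(d$xlim)
  py <- d$ylim[1] + (iy - runif(n)) / d$n * diff(d$ylim)
  pd <- pattern_dissimilarity(cbind(px, py), g)
  expect_true(pd$defined)
  expect_lt(pd$score, 0.35)
})

test_that("too few in-gate events flag the pattern score as undefined", {
  g <- square_gate()
  pd <- pattern_dissimilarity(matrix(runif(40, 0.4, 0.6), ncol = 2), g)
  expect_false(pd$defined)
  expect_true(is.na(pd$score))
})

test_that("a held-out same-type case is called APL-positive", {
  tmpl <- tiny_template()
  sc <- simulate_case(default_phenotypes()$hypergranular,
                      n_events = 3000, seed = 61)
  r <- classify_case(sc$tubes, tmpl, case_id = sc$case_id)
  expect_s3_class(r, "case_result")
  expect_true(r$hypergranular_call)
  expect_equal(r$overall, "APL-positive")
  sub <- r$tubes[r$tubes$gate == "hypergranular", ]
  expect_equal(nrow(sub), 4)
  expect_true(all(sub$percent_in_gate >= 95))
  expect_true(all(sub$percent_in_gate <= 100))
})

test_that("a non-APL mimic is called APL-negative", {
  tmpl <- tiny_template()
  sc <- simulate_case(default_phenotypes()$non_apl, n_events = 3000, seed = 63)
  r <- classify_case(sc$tubes, tmpl, case_id = sc$case_id)
  expect_false(r$hypergranular_call)
  expect_false(r$microgranular_call)
  expect_equal(r$overall, "APL-negative")
  # the pattern second stage can only make the screen stricter
  r2 <- classify_case(sc$tubes, tmpl, pattern_check = TRUE, case_id = "n")
  expect_equal(r2$overall, "APL-negative")
})

test_that("raising the cutoff can only flip calls positive-to-negative", {
  tmpl <- tiny_template()
  sc <- simulate_case(default_phenotypes()$hypergranular,
                      n_events = 3000, seed = 65)
  cuts <- c(50, 80, 95, 99, 99.9)
  calls <- vapply(cuts, function(co)
    isTRUE(classify_case(sc$tubes, tmpl, cutoff = co)$hypergranular_call), TRUE)
  # monotone non-increasing sequence of logicals
  expect_false(is.unsorted(rev(calls)))
})

test_that("a case with a missing tube is indeterminate", {
  tmpl <- tiny_template()
  sc <- simulate_case(default_phenotypes()$hypergranular,
                      n_events = 3000, seed = 67)
  r <- classify_case(sc$tubes[c("1", "2", "3")], tmpl)
  expect_equal(r$overall, "indeterminate")
  expect_match(r$indeterminate_reason, "tube")
})
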