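# Polygon gating and marker positivity.

unit_square_gate <- function() {
  polygon_gate("sq", c("X", "Y"),
               rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
}

test_that("point-in-polygon follows the even-odd rule, boundary inside", {
  g <- unit_square_gate()
  em <- scaled_em(rbind(c(0.5, 0.5), c(2, 2), c(0, 0), c(1, 0.5), c(0.5, 0)),
                  stats::setNames(c("X", "Y"), c("X", "Y")))
  expect_equal(apply_polygon_gate(em, g), c(TRUE, FALSE, TRUE, TRUE, TRUE))
})

test_that("membership in a convex pentagon matches a half-plane oracle", {
  set.seed(7)
  ang <- 2 * pi * (0:4) / 5 + 0.3
  v <- cbind(0.5 + 0.4 * cos(ang), 0.5 + 0.4 * sin(ang))
  g <- polygon_gate("pent", c("X", "Y"), v)
  pts <- matrix(runif(20000), ncol = 2, dimnames = list(NULL, c("X", "Y")))
  em <- scaled_em(pts)
  got <- apply_polygon_gate(em, g)
  # oracle: inside a convex CCW polygon iff left of (or on) every edge
  n <- nrow(v); j <- c(2:n, 1)
  oracle <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    cr <- (v[j[i], 1] - v[i, 1]) * (pts[, 2] - v[i, 2]) -
      (v[j[i], 2] - v[i, 2]) * (pts[, 1] - v[i, 1])
    oracle <- oracle & cr >= 0
  }
  expect_identical(got, oracle)
})

test_that("gate membership is invariant under a common affine rescaling", {
  set.seed(8)
  v <- rbind(c(0, 0), c(2, 0.5), c(1.5, 2), c(0.2, 1.4))
  pts <- matrix(runif(4000, -0.5, 2.5), ncol = 2,
                dimnames = list(NULL, c("X", "Y")))
  g1 <- polygon_gate("g", c("X", "Y"), v)
  m1 <- apply_polygon_gate(scaled_em(pts), g1)
  a <- c(1000, 250); b <- c(-3, 7)
  vt <- sweep(sweep(v, 2, a, `*`), 2, b, `+`)
  pt <- sweep(sweep(pts, 2, a, `*`), 2, b, `+`)
  colnames(pt) <- c("X", "Y")
  g2 <- polygon_gate("g", c("X", "Y"), vt)
  m2 <- apply_polygon_gate(scaled_em(pt), g2)
  expect_identical(m1, m2)
})

test_that("self-intersecting polygons are rejected", {
  expect_error(polygon_gate("bow", c("X", "Y"),
                            rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               class = "rg_geometry_error")
})

test_that("gate_blasts recovers the simulated blast fraction within 2 points", {
  sc <- simulate_case(default_phenotypes()$hypergranular,
                      n_events = 5000, seed = 11)
  b <- gate_blasts(sc$tubes[["1"]])
  expect_lt(abs(b$metadata$blast_fraction - sc$blast_fraction), 0.02)
  expect_true(all(b$labels$population == "blast"))
})

test_that("an empty gate sets the zero-blast flag; a full gate gives 100%", {
  em <- scaled_em(matrix(0.5, 50, 2, dimnames = list(NULL, c("CD45", "SSC"))))
  empty <- polygon_gate("e", c("CD45", "SSC"),
                        rbind(c(10, 10), c(11, 10), c(11, 11), c(10, 11)))
  expect_warning(out <- gate_blasts(em, empty), "no events")
  expect_true(out$metadata$zero_blast)
  full <- polygon_gate("f", c("CD45", "SSC"),
                       rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(gate_blasts(em, full)$metadata$blast_fraction, 1)
})

test_that("population positivity uses strict inequalities at both levels", {
  # 25% of events above the cutoff, threshold 0.20 -> positive
  em <- raw_marker_em("CD34", c(rep(1000, 25), rep(10, 75)))
  r <- marker_positivity(em, positivity_rule("CD34"))
  expect_equal(r$fraction, 0.25)
  expect_true(r$call)
  # exactly 10% positive with a 10% threshold -> negative (strict ">")
  em2 <- raw_marker_em("cyMPO", c(rep(1000, 10), rep(10, 90)))
  r2 <- marker_positivity(em2, positivity_rule("cyMPO"))
  expect_equal(r2$fraction, 0.10)
  expect_equal(positivity_rule("cyMPO")$threshold, 0.10)
  expect_false(r2$call)
  # all events below the cutoff -> fraction 0, negative
  r3 <- marker_positivity(raw_marker_em("CD34", rep(10, 50)),
                          positivity_rule("CD34"))
  expect_equal(r3$fraction, 0)
  expect_false(r3$call)
})

test_that("positive fraction is monotone as the cutoff decreases", {
  set.seed(13)
  em <- raw_marker_em("CD117", rlnorm(2000, log(500), 0.8))
  cuts <- seq(3, 0, by = -0.5)
  fr <- vapply(cuts, function(co)
    marker_positivity(em, positivity_rule("CD117", cutoff = co))$fraction, 0)
  expect_false(is.unsorted(fr))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("called fraction recovers a simulated mixture fraction", {
  set.seed(17)
  n <- 10000; f <- 0.3
  x <- c(rlnorm(n * f, log(3000), 0.47), rlnorm(n * (1 - f), log(50), 0.47))
  r <- marker_positivity(raw_marker_em("CD34", x), positivity_rule("CD34"))
  expect_lt(abs(r$fraction - f), 3 * sqrt(f * (1 - f) / n) + 0.005)
  expect_true(r$call)
})

test_that("empty blast populations are rejected", {
  em <- raw_marker_em("CD34", c(1, 2))
  em$metadata$zero_blast <- TRUE
  expect_error(marker_positivity(em, positivity_rule("CD34")),
               class = "rg_input_error")
})
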