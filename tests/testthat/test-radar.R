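# Star-coordinate projection, separation scoring and layout optimization.

abcd_em <- function(values, markers = c("A", "B", "C", "D")) {
  values <- matrix(values, ncol = length(markers),
                   dimnames = list(NULL, markers))
  scaled_em(values)
}

test_that("projection arithmetic: origin, single axis, symmetric cancellation", {
  em4 <- abcd_em(rbind(c(0, 0, 0, 0), c(1, 0, 0, 0)))
  P <- project_radar(em4, radar_layout(1, c("A", "B", "C", "D")))
  expect_equal(unname(P[1, ]), c(0, 0))
  expect_equal(unname(P[2, ]), c(0.25, 0))
  # K=3, all channels 1: equally spaced unit vectors cancel
  em3 <- abcd_em(rbind(c(1, 1, 1)), markers = c("A", "B", "C"))
  P3 <- project_radar(em3, radar_layout(1, c("A", "B", "C")))
  expect_equal(unname(P3[1, ]), c(0, 0), tolerance = 1e-12)
})

test_that("cyclic layout shifts rotate the projection (equivariance)", {
  set.seed(21)
  K <- 6
  mk <- paste0("M", 1:K)
  X <- matrix(runif(600 * K), ncol = K, dimnames = list(NULL, mk))
  em <- scaled_em(X)
  P0 <- project_radar(em, radar_layout(1, mk))
  P1 <- project_radar(em, radar_layout(1, mk[c(2:K, 1)]))
  th <- -2 * pi / K
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_lt(max(abs(P1 - P0 %*% t(R))), 1e-9)
  # all projections stay inside the unit disc
  expect_true(all(sqrt(rowSums(P0^2)) <= 1 + 1e-12))
})

test_that("unscaled input and missing layout channels are rejected", {
  em <- abcd_em(rbind(c(2, 0, 0, 0)))
  expect_error(project_radar(em, radar_layout(1, c("A", "B", "C", "D"))),
               class = "rg_input_error")
  em2 <- abcd_em(rbind(c(0.1, 0.1, 0.1, 0.1)))
  expect_error(project_radar(em2, radar_layout(1, c("A", "B", "Z"))),
               class = "rg_config_error")
})

test_that("separation score matches hand-computed standardized distances", {
  # each population: 4 points at mu +/- e1, mu +/- e2 -> sigma^2 = 1 exactly
  cloud <- function(mu) rbind(mu + c(1, 0), mu - c(1, 0),
                              mu + c(0, 1), mu - c(0, 1))
  pts <- rbind(cloud(c(0, 0)), cloud(c(2, 2)))
  lab <- rep(c("a", "b"), each = 4)
  s <- separation_score(pts, lab)
  # centroid distance 2*sqrt(2), sigma_a^2 = sigma_b^2 = 1 -> score 2
  expect_equal(s$aggregate, 2, tolerance = 1e-12)
  # identical clouds score 0
  s0 <- separation_score(rbind(cloud(c(1, 1)), cloud(c(1, 1))),
                         rep(c("a", "b"), each = 4))
  expect_equal(s0$aggregate, 0)
})

test_that("aggregate equals the minimum over independently computed pairs", {
  set.seed(23)
  pts <- rbind(matrix(rnorm(200, 0), ncol = 2),
               matrix(rnorm(200, 3), ncol = 2),
               matrix(rnorm(200, 7), ncol = 2))
  lab <- rep(c("a", "b", "c"), each = 100)
  s <- separation_score(pts, lab)
  indep <- vapply(list(c("a", "b"), c("a", "c"), c("b", "c")), function(pp) {
    keep <- lab %in% pp
    separation_score(pts[keep, ], lab[keep])$aggregate
  }, 0)
  expect_equal(s$aggregate, min(indep), tolerance = 1e-12)
  expect_equal(sort(s$pairs$score), sort(indep), tolerance = 1e-12)
})

test_that("K=3 has a single circular ordering and is returned as such", {
  set.seed(25)
  X <- matrix(runif(300), ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  lab <- rep(c("p", "q"), each = 50)
  X[lab == "q", 1] <- X[lab == "q", 1] * 0.2 + 0.8
  lay <- optimize_layout(scaled_em(X), c("A", "B", "C"), labels = lab)
  expect_setequal(lay$channels, c("A", "B", "C"))
})

test_that("the optimizer equals an exhaustive oracle at K=5", {
  set.seed(27)
  K <- 5; n <- 120
  mk <- paste0("M", 1:K)
  centers <- rbind(c(0.2, 0.8, 0.5, 0.3, 0.7),
                   c(0.8, 0.2, 0.5, 0.7, 0.3),
                   c(0.5, 0.5, 0.9, 0.1, 0.5))
  X <- do.call(rbind, lapply(1:3, function(g)
    pmin(pmax(matrix(rnorm(n * K, centers[g, ], 0.08),
                     ncol = K, byrow = TRUE), 0), 1)))
  colnames(X) <- mk
  lab <- rep(c("g1", "g2", "g3"), each = n)
  em <- scaled_em(X)
  lay <- optimize_layout(em, mk, labels = lab)

  # oracle: score every distinct circular ordering through the point-level
  # separation_score on actual projections
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  cand <- Filter(function(p) p[1] < p[length(p)], perms(2:K))
  scores <- vapply(cand, function(p) {
    ord <- c(1L, p)
    separation_score(project_radar(em, radar_layout(1, mk[ord])), lab)$aggregate
  }, 0)
  expect_equal(length(scores), factorial(K - 1) / 2)
  expect_equal(attr(lay, "score"), max(scores), tolerance = 1e-9)
})

test_that("subset selection drops a pure-noise channel", {
  set.seed(29)
  n <- 150
  mk <- c("S1", "S2", "S3", "S4", "NOISE")
  centers <- rbind(c(0.2, 0.8, 0.2, 0.8), c(0.8, 0.2, 0.8, 0.2),
                   c(0.5, 0.5, 0.1, 0.9))
  X <- do.call(rbind, lapply(1:3, function(g)
    cbind(pmin(pmax(matrix(rnorm(n * 4, centers[g, ], 0.06),
                           ncol = 4, byrow = TRUE), 0), 1),
          runif(n))))
  colnames(X) <- mk
  lab <- rep(c("g1", "g2", "g3"), each = n)
  lay <- optimize_layout(scaled_em(X), mk, labels = lab, n_channels = 4)
  expect_false("NOISE" %in% lay$channels)
})

test_that("optimized score beats 1000 random orderings", {
  set.seed(31)
  K <- 6; n <- 100
  mk <- paste0("M", 1:K)
  X <- rbind(matrix(runif(n * K, 0, 0.45), ncol = K),
             matrix(runif(n * K, 0.55, 1), ncol = K))
  colnames(X) <- mk
  lab <- rep(c("a", "b"), each = n)
  em <- scaled_em(X)
  lay <- optimize_layout(em, mk, labels = lab)
  best <- attr(lay, "score")
  for (i in 1:1000) {
    ord <- sample(K)
    s <- separation_score(project_radar(em, radar_layout(1, mk[ord])), lab)$aggregate
    expect_lte(s, best + 1e-9)
  }
})

test_that("separation score is invariant under rotation and translation", {
  set.seed(33)
  pts <- rbind(matrix(rnorm(300, 0), ncol = 2), matrix(rnorm(300, 2), ncol = 2))
  lab <- rep(c("a", "b"), each = 150)
  s1 <- separation_score(pts, lab)$aggregate
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  s2 <- separation_score(sweep(pts %*% t(R), 2, c(5, -3), `+`), lab)$aggregate
  expect_equal(s1, s2, tolerance = 1e-12)
})
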