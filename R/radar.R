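# Star-coordinate (radar) projection and layout optimization.
#
# A radar layout places K channels at equally spaced angles
# theta_i = 2*pi*(i-1)/K (axis 1 at angle 0, counter-clockwise); an event
# with unit-scaled values x projects to p = (1/K) * sum_i x_i (cos t_i, sin t_i),
# so every event lies in the unit disc.

#' Construct a radar layout
#'
#' @param tube_id tube number the layout belongs to.
#' @param channels ordered character vector of 3-10 unique marker names; the
#'   order fixes the (equally spaced) axis angles.
#' @return a `radar_layout` with an `angles` component derived from the order.
#' @export
radar_layout <- function(tube_id, channels) {
  channels <- as.character(channels)
  K <- length(channels)
  if (K < 3 || K > 10)
    stop_rg("rg_config_error", "a radar layout needs 3..10 channels, got %d", K)
  if (anyDuplicated(normalize_marker(channels)))
    stop_rg("rg_config_error", "radar layout channels must be unique")
  structure(list(tube_id = as.integer(tube_id), channels = channels,
                 angles = 2 * pi * (seq_len(K) - 1) / K),
            class = "radar_layout")
}

#' Default per-tube radar layouts
#'
#' The shipped axis orderings for the four AML screening tubes:
#' \enumerate{
#'   \item SSC, CD4, CD64, CD11b, CD13, HLA-DR, CD14, CD300e, CD45
#'   \item CD15, CD123, SSC, CD34, CD13, HLA-DR, CD45
#'   \item CD34, CD117, CD56, CD45, CD33, SSC
#'   \item cyFXIII-A, cyMPO, HLA-DR, SSC, CD117, CD45
#' }
#' These orderings were chosen so that blast populations of differing
#' morphology separate maximally in the projection; [optimize_layout()]
#' re-derives such orderings from labelled reference data.
#'
#' @return named list of four `radar_layout` objects ("1".."4").
#' @export
default_layouts <- function() {
  list(
    "1" = radar_layout(1L, c("SSC", "CD4", "CD64", "CD11b", "CD13",
                             "HLA-DR", "CD14", "CD300e", "CD45")),
    "2" = radar_layout(2L, c("CD15", "CD123", "SSC", "CD34", "CD13",
                             "HLA-DR", "CD45")),
    "3" = radar_layout(3L, c("CD34", "CD117", "CD56", "CD45", "CD33", "SSC")),
    "4" = radar_layout(4L, c("cyFXIII-A", "cyMPO", "HLA-DR", "SSC",
                             "CD117", "CD45"))
  )
}

# 2 x K matrix of unit axis vectors (columns) for a layout
layout_axes <- function(layout) {
  rbind(cos(layout$angles), sin(layout$angles))
}

#' Project scaled events into radar coordinates
#'
#' @param em an `event_matrix` scaled to [0,1] (see [scale_to_unit()]); values
#'   outside [0,1] raise an input error.
#' @param layout a `radar_layout` whose channels are all present in `em`.
#' @return numeric n x 2 matrix of radar coordinates (columns `x`, `y`).
#' @export
project_radar <- function(em, layout) {
  cols <- vapply(layout$channels, function(m) marker_channel(em, m), "")
  X <- em$values[, cols, drop = FALSE]
  if (any(X < -1e-9 | X > 1 + 1e-9))
    stop_rg("rg_input_error",
            "events must be scaled to [0,1] before radar projection")
  A <- layout_axes(layout)
  K <- length(layout$channels)
  P <- X %*% t(A) / K
  colnames(P) <- c("x", "y")
  P
}

#' Pairwise separation of labelled populations in a 2D projection
#'
#' For each population pair (a, b) the score is
#' `||centroid_a - centroid_b|| / sqrt(sigma_a^2 + sigma_b^2)`, where
#' `sigma^2` is the mean squared distance of a population's points to its own
#' centroid. The aggregate is the minimum over pairs — the worst-separated
#' pair governs.
#'
#' @param points n x 2 coordinate matrix.
#' @param labels population label per point (>= 2 populations, each with
#'   >= 2 points).
#' @return a `separation_score`: list with `pairs` (data.frame a, b, score)
#'   and `aggregate`.
#' @export
separation_score <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2)
    stop_rg("rg_input_error", "need >= 2 labelled populations")
  stats_of <- lapply(groups, function(g) {
    P <- points[labels == g, , drop = FALSE]
    if (nrow(P) < 2)
      stop_rg("rg_input_error", "population '%s' has < 2 points", g)
    mu <- colMeans(P)
    list(mu = mu, s2 = mean(rowSums(sweep(P, 2, mu)^2)))
  })
  names(stats_of) <- groups
  cmb <- utils::combn(groups, 2)
  score <- apply(cmb, 2, function(ab) {
    a <- stats_of[[ab[1]]]; b <- stats_of[[ab[2]]]
    sqrt(sum((a$mu - b$mu)^2)) / sqrt(a$s2 + b$s2)
  })
  structure(list(
    pairs = data.frame(a = cmb[1, ], b = cmb[2, ], score = score,
                       stringsAsFactors = FALSE),
    aggregate = min(score)), class = "separation_score")
}

# --------------------------------------------------------------------------
# Layout optimization. The projection is linear, so for a fixed channel set
# the per-population centroid and dispersion in radar space follow exactly
# from the channel-space mean vector and covariance matrix:
#   centroid = A m / K,   sigma^2 = tr(A C A') / K^2
# (C the divisor-n covariance). Scoring an ordering is then O(K^2) instead of
# O(n K), which makes exhaustive search over (K-1)!/2 circular orderings
# cheap.

population_moments <- function(X, labels, subsample = 20000, seed = 1L) {
  groups <- sort(unique(labels))
  out <- lapply(groups, function(g) {
    P <- X[labels == g, , drop = FALSE]
    if (nrow(P) < 2)
      stop_rg("rg_input_error", "population '%s' has < 2 points", g)
    if (nrow(P) > subsample) {
      set.seed(seed)
      P <- P[sample.int(nrow(P), subsample), , drop = FALSE]
    }
    n <- nrow(P)
    list(m = colMeans(P), C = stats::cov(P) * (n - 1) / n)
  })
  names(out) <- groups
  out
}

score_ordering <- function(moments, ord, K) {
  ang <- 2 * pi * (seq_len(K) - 1) / K
  A <- rbind(cos(ang), sin(ang))
  best <- Inf
  groups <- names(moments)
  mus <- lapply(moments, function(mo) as.vector(A %*% mo$m[ord]) / K)
  s2s <- vapply(moments, function(mo)
    sum(diag(A %*% mo$C[ord, ord] %*% t(A))) / K^2, 0)
  for (i in seq_len(length(groups) - 1)) for (j in seq.int(i + 1, length(groups))) {
    s <- sqrt(sum((mus[[i]] - mus[[j]])^2)) / sqrt(s2s[i] + s2s[j])
    if (s < best) best <- s
  }
  best
}

# distinct circular orderings of 1..K up to rotation and reflection:
# fix 1 first; among the remaining permutations keep those whose second
# element is smaller than the last (kills reflections)
circular_orderings <- function(K) {
  if (K == 3) return(list(1:3))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  rest <- perms(2:K)
  rest <- Filter(function(p) p[1] < p[length(p)], rest)
  lapply(rest, function(p) c(1L, p))
}

#' Optimize the radar axis ordering for population separation
#'
#' Searches for the circular ordering of channels that maximizes the
#' aggregate [separation_score()] of the projected labelled reference —
#' the formalization of picking "parameters and locations" so that the
#' populations differ from each other the most. The search is exhaustive
#' over distinct circular orderings up to rotation and reflection
#' ((K-1)!/2 candidates) for K <= 9 and greedy insertion beyond. Ties are
#' broken toward the lexicographically smallest channel sequence. With
#' `n_channels < length(channels)`, every channel subset of that size is
#' scored and the best subset/ordering pair is returned.
#'
#' @param em scaled `event_matrix` with a `population` label column (or
#'   `labels` supplied separately).
#' @param channels candidate channel (marker) names.
#' @param labels population label per event; defaults to
#'   `em$labels$population`.
#' @param n_channels optional subset size K <= length(channels).
#' @param tube_id tube id stored in the returned layout.
#' @param subsample per-population subsample cap used when computing the
#'   moments that drive the search (the returned `score` is recomputed on the
#'   full data).
#' @param seed subsampling seed.
#' @return a `radar_layout` with an attached `score`.
#' @export
optimize_layout <- function(em, channels, labels = NULL, n_channels = NULL,
                            tube_id = NA_integer_, subsample = 20000,
                            seed = 1L) {
  if (is.null(labels)) labels <- em$labels$population
  if (is.null(labels) || length(unique(labels)) < 2)
    stop_rg("rg_input_error", "need >= 2 labelled populations")
  cols <- vapply(channels, function(m) marker_channel(em, m), "")
  X <- em$values[, cols, drop = FALSE]
  if (is.null(n_channels)) n_channels <- length(channels)
  if (n_channels > length(channels) || n_channels < 3)
    stop_rg("rg_config_error", "n_channels must be in 3..length(channels)")

  subsets <- if (n_channels == length(channels))
    list(seq_along(channels))
  else
    utils::combn(length(channels), n_channels, simplify = FALSE)

  best <- list(score = -Inf, ord = NULL, subset = NULL)
  for (sub in subsets) {
    moments <- population_moments(X[, sub, drop = FALSE], labels,
                                  subsample = subsample, seed = seed)
    K <- length(sub)
    cands <- if (K <= 9) circular_orderings(K)
             else greedy_orderings(moments, K)
    for (ord in cands) {
      s <- score_ordering(moments, ord, K)
      seq_names <- channels[sub][ord]
      if (s > best$score + 1e-12 ||
          (abs(s - best$score) <= 1e-12 && !is.null(best$ord) &&
           paste(seq_names, collapse = "\r") <
           paste(channels[best$subset][best$ord], collapse = "\r"))) {
        best <- list(score = s, ord = ord, subset = sub)
      }
    }
  }
  layout <- radar_layout(tube_id, channels[best$subset][best$ord])
  # final reported score on the full data
  P <- X[, best$subset, drop = FALSE][, best$ord, drop = FALSE] %*%
    t(layout_axes(layout)) / length(best$ord)
  attr(layout, "score") <- separation_score(P, labels)$aggregate
  layout
}

# greedy insertion for K > 9: start from the best triple, insert each
# remaining channel at its best position
greedy_orderings <- function(moments, K) {
  ord <- 1:3
  for (ch in 4:K) {
    best_s <- -Inf; best_ord <- NULL
    for (pos in seq_len(length(ord) + 1)) {
      cand <- append(ord, ch, after = pos - 1)
      s <- score_ordering(lapply(moments, function(mo)
        list(m = mo$m[cand], C = mo$C[cand, cand])),
        seq_along(cand), length(cand))
      if (s > best_s) { best_s <- s; best_ord <- cand }
    }
    ord <- best_ord
  }
  list(ord)
}
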