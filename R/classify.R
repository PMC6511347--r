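# Case screening: per-tube blast-in-gate percentages, in-gate pattern
# dissimilarity, and the APL screening call.

#' Percentage of projected blasts inside a gate
#'
#' @param points n x 2 matrix of projected blast coordinates (n >= 1).
#' @param gate a `gate_region`.
#' @return percentage in [0, 100]; boundary points count as inside.
#' @export
percent_in_gate <- function(points, gate) {
  points <- as.matrix(points)
  if (nrow(points) < 1)
    stop_rg("rg_input_error", "percent_in_gate needs >= 1 blast event")
  100 * mean(points_in_polygon(points[, 1], points[, 2], gate$vertices))
}

#' Jensen-Shannon pattern dissimilarity of in-gate blasts
#'
#' Histograms the case's in-gate points on the gate's stored density grid
#' (same bounding box, same resolution, same light smoothing) and returns the
#' base-2 Jensen-Shannon distance (the square root of the divergence) to the
#' stored reference density. 0 means identical patterns, 1 disjoint support —
#' the formalization of "the blasts concentrated in one segment of the gate
#' rather than dispersing like the reference".
#'
#' @param points n x 2 matrix of projected blast coordinates for the case.
#' @param gate a `gate_region`.
#' @param min_events minimum in-gate events for a defined score (default 50).
#' @return list with `score` in [0,1] (NA when undefined), `defined`,
#'   and `n_in_gate`.
#' @export
pattern_dissimilarity <- function(points, gate, min_events = 50) {
  points <- as.matrix(points)
  inside <- points_in_polygon(points[, 1], points[, 2], gate$vertices)
  n_in <- sum(inside)
  if (n_in < min_events)
    return(list(score = NA_real_, defined = FALSE, n_in_gate = n_in))
  d <- gate$density
  h <- hist2d(points[inside, 1], points[inside, 2], d$xlim, d$ylim, d$n)
  q <- blur3(h)
  q <- q / sum(q)
  list(score = js_distance(d$grid, q), defined = TRUE, n_in_gate = n_in)
}

# base-2 Jensen-Shannon distance between two probability arrays
js_distance <- function(p, q) {
  p <- as.vector(p); q <- as.vector(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log2(a[i]) - log2(b[i])))
  }
  sqrt(pmax(0, (kl(p, m) + kl(q, m)) / 2))
}

#' Screen one case against a template
#'
#' Runs the full per-case protocol: gate blasts on CD45/SSC in each tube,
#' scale with the template's frozen scaling, project with the tube layout,
#' and compare against both gate types. The hypergranular call requires the
#' blast-in-gate percentage to reach `cutoff` in at least `k_of_4` tubes
#' (default: all four) and — when the pattern check is enabled — the pattern
#' dissimilarity to stay at or below `pattern_max` in those tubes; the
#' microgranular call is analogous. The overall screen is APL-positive if
#' either type matches, APL-negative otherwise, and indeterminate when any
#' tube is missing or has no gateable blasts.
#'
#' @param tubes named list ("1".."4") of `event_matrix` objects (raw events).
#' @param template a `cohort_template`.
#' @param cutoff case-level cut-off percentage; defaults to the template's
#'   stored cut-off (95).
#' @param pattern_check enable the pattern-dissimilarity second stage
#'   (default FALSE: the percentage rule is the primary screen).
#' @param pattern_max maximum allowed pattern dissimilarity (default 0.5).
#' @param k_of_4 number of tubes that must pass (default 4: conjunctive rule).
#' @param pre_gated set TRUE when `tubes` already hold pure blasts.
#' @param case_id identifier carried into the result.
#' @return a `case_result`.
#' @export
classify_case <- function(tubes, template, cutoff = NULL,
                          pattern_check = FALSE, pattern_max = 0.5,
                          k_of_4 = 4, pre_gated = FALSE, case_id = "case") {
  if (is.null(cutoff)) cutoff <- template$cutoff
  if (!(cutoff > 0 && cutoff < 100))
    stop_rg("rg_config_error", "cutoff must lie in (0,100)")
  tube_ids <- as.character(1:4)
  missing_tubes <- setdiff(tube_ids, names(tubes))
  rows <- list()
  indeterminate_reason <- if (length(missing_tubes))
    sprintf("missing tube(s): %s", paste(missing_tubes, collapse = ",")) else NULL

  for (tid in intersect(tube_ids, names(tubes))) {
    em <- tubes[[tid]]
    blasts <- if (pre_gated) em else
      suppressWarnings(gate_blasts(em, template$blast_gate))
    if (isTRUE(blasts$metadata$zero_blast)) {
      indeterminate_reason <- c(indeterminate_reason,
                                sprintf("tube %s: no blasts in gate", tid))
      rows[[tid]] <- data.frame(tube = tid, gate = c("hypergranular",
                                                     "microgranular"),
                                percent_in_gate = NA_real_,
                                pattern_dissimilarity = NA_real_,
                                n_blasts = 0L, stringsAsFactors = FALSE)
      next
    }
    scaled <- scale_to_unit(blasts, template$scaling[[tid]])
    P <- project_radar(scaled, template$layouts[[tid]])
    rows[[tid]] <- do.call(rbind, lapply(
      c("hypergranular", "microgranular"), function(ty) {
        g <- template$gates[[ty]][[tid]]
        pd <- pattern_dissimilarity(P, g)
        data.frame(tube = tid, gate = ty,
                   percent_in_gate = percent_in_gate(P, g),
                   pattern_dissimilarity = pd$score,
                   n_blasts = nrow(P), stringsAsFactors = FALSE)
      }))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  call_for <- function(ty) {
    if (!is.null(indeterminate_reason)) return(NA)
    sub <- res[res$gate == ty, ]
    ok <- sub$percent_in_gate >= cutoff
    if (pattern_check)
      ok <- ok & !is.na(sub$pattern_dissimilarity) &
        sub$pattern_dissimilarity <= pattern_max
    sum(ok) >= k_of_4
  }
  hyper_call <- call_for("hypergranular")
  micro_call <- call_for("microgranular")
  overall <- if (!is.null(indeterminate_reason)) "indeterminate"
             else if (isTRUE(hyper_call) || isTRUE(micro_call)) "APL-positive"
             else "APL-negative"

  structure(list(case_id = case_id, tubes = res,
                 hypergranular_call = hyper_call,
                 microgranular_call = micro_call,
                 overall = overall, cutoff = cutoff,
                 pattern_check = pattern_check, pattern_max = pattern_max,
                 indeterminate_reason = indeterminate_reason),
            class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("case_result %s: %s\n", x$case_id, x$overall))
  cat(sprintf("  hypergranular call: %s, microgranular call: %s (cutoff %.1f%%)\n",
              x$hypergranular_call, x$microgranular_call, x$cutoff))
  print(x$tubes, digits = 4)
  invisible(x)
}

#' One summary row per case result
#'
#' @param result a `case_result`.
#' @return a one-row data.frame: case id, 8 percentages (tube x gate type),
#'   calls and overall screen.
#' @export
result_row <- function(result) {
  out <- data.frame(case_id = result$case_id, stringsAsFactors = FALSE)
  for (ty in c("hypergranular", "microgranular")) {
    sub <- result$tubes[result$tubes$gate == ty, ]
    for (tid in as.character(1:4)) {
      hit <- which(sub$tube == tid)
      out[[sprintf("pct_%s_t%s", substr(ty, 1, 5), tid)]] <-
        if (length(hit)) sub$percent_in_gate[hit[1]] else NA_real_
    }
  }
  out$hypergranular_call <- result$hypergranular_call
  out$microgranular_call <- result$microgranular_call
  out$overall <- result$overall
  out
}
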