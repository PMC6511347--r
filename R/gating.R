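# Blast selection on the CD45/SSC bivariate plot and marker positivity calls.

#' Construct a 2D polygon gate
#'
#' @param name gate name.
#' @param channels length-2 character vector: markers on the x and y axis.
#' @param vertices numeric matrix (>= 3 rows, 2 columns) of polygon vertices
#'   in the coordinates the gate is applied in (transformed units); the
#'   polygon is closed implicitly.
#' @param check_simple verify the polygon is non-self-intersecting.
#' @return a `polygon_gate`.
#' @export
polygon_gate <- function(name, channels, vertices, check_simple = TRUE) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop_rg("rg_geometry_error", "a polygon gate needs >= 3 two-dimensional vertices")
  if (length(channels) != 2)
    stop_rg("rg_config_error", "a polygon gate needs exactly 2 channels")
  if (check_simple && !is_simple_polygon(vertices))
    stop_rg("rg_geometry_error", "polygon '%s' is self-intersecting", name)
  structure(list(name = name, channels = channels, vertices = vertices),
            class = "polygon_gate")
}

# segment-intersection check (proper crossings between non-adjacent edges)
is_simple_polygon <- function(v) {
  n <- nrow(v)
  if (n < 4) return(TRUE)
  vx <- v[, 1]; vy <- v[, 2]
  nx <- c(2:n, 1)
  a1x <- vx; a1y <- vy; a2x <- vx[nx]; a2y <- vy[nx]
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2)) {
    j <- seq.int(i + 2, n)
    j <- j[!(i == 1 & j == n)]  # skip adjacent (wrap) pair
    if (!length(j)) next
    d1 <- cross(a1x[i], a1y[i], a2x[i], a2y[i], a1x[j], a1y[j])
    d2 <- cross(a1x[i], a1y[i], a2x[i], a2y[i], a2x[j], a2y[j])
    d3 <- cross(a1x[j], a1y[j], a2x[j], a2y[j], a1x[i], a1y[i])
    d4 <- cross(a1x[j], a1y[j], a2x[j], a2y[j], a2x[i], a2y[i])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

# Even-odd point-in-polygon, boundary-inclusive, vectorized over points.
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  scale <- max(abs(v), 1)
  eps <- scale * 1e-12
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    # edge crossing test (even-odd rule)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # boundary: collinear and within the segment's bounding box
    d <- abs((xj - xi) * (py - yi) - (yj - yi) * (px - xi)) /
      max(sqrt((xj - xi)^2 + (yj - yi)^2), eps)
    onseg <- d <= eps &
      px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    on_edge <- on_edge | onseg
    j <- i
  }
  inside | on_edge
}

#' Apply a polygon gate to an event matrix
#'
#' Membership is decided by the even-odd rule; points exactly on an edge or
#' vertex count as inside. The gate's channels are transformed with the
#' gate's coordinate convention: fluorescence markers are compared on the
#' asinh(x/cofactor) axis and scatter channels on the raw linear axis, unless
#' the event matrix is already scaled (`metadata$scaled`), in which case
#' values are used as stored.
#'
#' @param em an `event_matrix`.
#' @param gate a `polygon_gate`.
#' @param cofactor asinh cofactor used for fluorescence gate axes.
#' @return logical vector, one entry per event.
#' @export
apply_polygon_gate <- function(em, gate, cofactor = 150) {
  get_axis <- function(marker) {
    x <- marker_values(em, marker)
    if (isTRUE(em$metadata$scaled)) return(x)
    kind <- transform_kind(stats::setNames(marker, marker))
    apply_transform(x, kind, cofactor)
  }
  px <- get_axis(gate$channels[1])
  py <- get_axis(gate$channels[2])
  points_in_polygon(px, py, gate$vertices)
}

#' Default CD45-dim / SSC blast gate
#'
#' A rectangular gate over the CD45-dim region (asinh(CD45/150) between
#' `cd45_lo` and `cd45_hi`) across the full side-scatter range — the standard
#' CD45/SSC blast window. Blasts of any granularity (hypergranular high-SSC
#' APL included) fall in the CD45-dim band while lymphocytes, monocytes and
#' granulocytes sit at brighter CD45.
#'
#' @param cd45_lo,cd45_hi CD45 bounds on the asinh axis.
#' @param ssc_max upper SSC bound (raw units).
#' @return a `polygon_gate` on (CD45, SSC).
#' @export
default_blast_gate <- function(cd45_lo = 1.2, cd45_hi = 3.8, ssc_max = 262144) {
  polygon_gate("blasts", c("CD45", "SSC"),
               rbind(c(cd45_lo, 0), c(cd45_hi, 0),
                     c(cd45_hi, ssc_max), c(cd45_lo, ssc_max)))
}

#' Gate the blast population
#'
#' Subsets an event matrix to the events inside a CD45/SSC blast gate,
#' labelling them `population = "blast"`, and records the blast fraction of
#' total events. An empty result is returned with a `zero_blast` flag (the
#' case is then not classifiable) and a warning.
#'
#' @param em an `event_matrix`.
#' @param gate a `polygon_gate`; default [default_blast_gate()].
#' @param cofactor asinh cofactor for the gate axes.
#' @return an `event_matrix` of blasts with `metadata$blast_fraction`, or —
#'   when no event falls in the gate — the input with
#'   `metadata$zero_blast = TRUE`.
#' @export
gate_blasts <- function(em, gate = default_blast_gate(), cofactor = 150) {
  keep <- apply_polygon_gate(em, gate, cofactor = cofactor)
  if (!any(keep)) {
    warning("no events inside the blast gate; case not classifiable")
    out <- em
    out$metadata$zero_blast <- TRUE
    out$metadata$blast_fraction <- 0
    return(out)
  }
  out <- em
  out$values <- em$values[keep, , drop = FALSE]
  if (!is.null(em$labels)) out$labels <- em$labels[keep, , drop = FALSE]
  pop <- rep("blast", sum(keep))
  if (is.null(out$labels)) out$labels <- data.frame(population = pop,
                                                    stringsAsFactors = FALSE)
  else out$labels$population <- pop
  out$metadata$blast_fraction <- mean(keep)
  out$metadata$zero_blast <- FALSE
  out
}

#' Construct a positivity rule
#'
#' An event is positive when its transformed intensity lies strictly above
#' `cutoff`; the population is called positive when the positive fraction is
#' strictly above `threshold`. Thresholds follow the conventional screening
#' rule: > 10\% positive leukemic cells for cytoplasmic MPO and > 20\% for
#' all other antigens.
#'
#' @param marker marker name.
#' @param cutoff event-level cutoff in transformed (asinh) units; the default
#'   1.0 corresponds to ~176 raw units at cofactor 150.
#' @param threshold population-level positive fraction threshold; defaults to
#'   0.10 for cyMPO/MPO and 0.20 otherwise.
#' @param cofactor asinh cofactor.
#' @return a `positivity_rule`.
#' @export
positivity_rule <- function(marker, cutoff = 1.0, threshold = NULL,
                            cofactor = 150) {
  if (is.null(threshold))
    threshold <- if (normalize_marker(marker) %in% c("CYMPO", "MPO")) 0.10 else 0.20
  if (!(threshold > 0 && threshold < 1))
    stop_rg("rg_config_error", "threshold fraction must lie in (0,1)")
  if (!is.finite(cutoff)) stop_rg("rg_config_error", "cutoff must be finite")
  structure(list(marker = marker, cutoff = cutoff, threshold = threshold,
                 cofactor = cofactor), class = "positivity_rule")
}

#' Call marker positivity on a blast population
#'
#' @param blasts nonempty `event_matrix` (typically the output of
#'   [gate_blasts()]).
#' @param rule a `positivity_rule`.
#' @return list with `fraction` (share of events strictly above the cutoff)
#'   and `call` (`TRUE` iff fraction strictly exceeds the rule threshold).
#' @export
marker_positivity <- function(blasts, rule) {
  if (n_events(blasts) < 1 || isTRUE(blasts$metadata$zero_blast))
    stop_rg("rg_input_error", "empty blast population")
  x <- marker_values(blasts, rule$marker)
  if (!isTRUE(blasts$metadata$scaled))
    x <- asinh(x / rule$cofactor)
  fraction <- mean(x > rule$cutoff)
  list(marker = rule$marker, fraction = fraction,
       call = fraction > rule$threshold)
}

#' Tabulate marker positivity for a case
#'
#' Applies [marker_positivity()] for every fluorescence marker of a gated
#' blast population, reproducing the per-case antigen-expression table row
#' structure (marker, fraction, call).
#'
#' @param blasts gated blast `event_matrix`.
#' @param cutoff,cofactor see [positivity_rule()].
#' @return data.frame with columns marker, fraction, call.
#' @export
positivity_table <- function(blasts, cutoff = 1.0, cofactor = 150) {
  mks <- unname(blasts$markers[!normalize_marker(blasts$markers) %in%
                               c("FSC", "SSC")])
  rows <- lapply(mks, function(m)
    marker_positivity(blasts, positivity_rule(m, cutoff = cutoff,
                                              cofactor = cofactor)))
  data.frame(marker = mks,
             fraction = vapply(rows, `[[`, 0, "fraction"),
             call = vapply(rows, `[[`, TRUE, "call"),
             stringsAsFactors = FALSE)
}
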