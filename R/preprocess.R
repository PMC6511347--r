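# Spillover compensation and channel scaling into the bounded [0,1] space
# used by the radar projection.
#
# Fluorescence channels are transformed with asinh(x / cofactor) (default
# cofactor 150), scatter channels stay linear; an affine map then sends two
# per-channel anchors to 0 and 1, with clipping.

#' Compensate fluorescence spillover
#'
#' Removes linear spillover between fluorescence detectors. The spillover
#' matrix uses the column convention `raw_i = sum_j S[i, j] * true_j`
#' (entry \code{S[i, j]} is the fraction of the true signal of channel `j`
#' appearing in detector `i`; diagonal 1), so corrected values solve
#' `S %*% t(corrected) = t(raw)`. Scatter channels are untouched.
#'
#' @param em an `event_matrix` with raw values.
#' @param spillover square numeric spillover matrix over the fluorescence
#'   channels (rows/columns in channel order, or named with channel names);
#'   defaults to `metadata$spillover` if present.
#' @return compensated `event_matrix`.
#' @export
compensate <- function(em, spillover = NULL) {
  if (is.null(spillover)) spillover <- em$metadata$spillover
  if (is.null(spillover)) return(em)
  spillover <- as.matrix(spillover)
  if (nrow(spillover) != ncol(spillover))
    stop_rg("rg_config_error", "spillover matrix must be square")
  fluo <- which(!normalize_marker(em$markers) %in% c("FSC", "SSC"))
  if (nrow(spillover) != length(fluo))
    stop_rg("rg_config_error",
            "spillover is %dx%d but there are %d fluorescence channels",
            nrow(spillover), ncol(spillover), length(fluo))
  if (!is.null(rownames(spillover)) &&
      all(rownames(spillover) %in% colnames(em$values)))
    spillover <- spillover[colnames(em$values)[fluo], colnames(em$values)[fluo]]
  corrected <- tryCatch(
    t(solve(spillover, t(em$values[, fluo, drop = FALSE]))),
    error = function(e)
      stop_rg("rg_numeric_error", "singular spillover matrix: %s",
              conditionMessage(e)))
  out <- em
  out$values[, fluo] <- corrected
  out
}

transform_kind <- function(markers) {
  ifelse(normalize_marker(markers) %in% c("FSC", "SSC"), "linear", "asinh")
}

apply_transform <- function(x, kind, cofactor) {
  if (kind == "asinh") asinh(x / cofactor) else x
}

#' Fixed instrument-display scaling
#'
#' Builds a `scaling_ref` whose anchors are the fixed instrument display
#' range rather than data quantiles: fluorescence channels map
#' `asinh(0)..asinh(range/cofactor)` to 0..1 and scatter channels map
#' `0..range` linearly. Because the anchors do not depend on any event set,
#' every case is scaled identically — the digital analogue of gating on a
#' calibrated, fixed display. This is the default scaling used when building
#' a screening template.
#'
#' @param em an `event_matrix` (only its channel/marker map is used).
#' @param cofactor asinh cofactor for fluorescence channels.
#' @param instrument_range full-scale raw value of the digitizer.
#' @return a `scaling_ref`.
#' @export
display_scaling <- function(em, cofactor = 150, instrument_range = 262144) {
  kinds <- transform_kind(em$markers)
  chans <- lapply(seq_along(em$markers), function(i) {
    if (kinds[i] == "asinh")
      list(transform = "asinh", cofactor = cofactor, low = 0,
           high = asinh(instrument_range / cofactor), degenerate = FALSE)
    else
      list(transform = "linear", cofactor = NA_real_, low = 0,
           high = instrument_range, degenerate = FALSE)
  })
  names(chans) <- names(em$markers)
  structure(list(channels = chans, markers = em$markers,
                 mode = "display"), class = "scaling_ref")
}

#' Fit a quantile-anchored scaling reference
#'
#' Per channel, anchors are empirical quantiles of the transformed reference
#' values: `q_low` maps to 0 and `q_high` to 1. Degenerate channels (equal
#' anchors, e.g. a constant channel) are widened by a machine-epsilon-scaled
#' margin and flagged. Quantile anchors adapt to instrument gain but make the
#' scale cohort-dependent; see [display_scaling()] for the fixed alternative.
#'
#' @param reference an `event_matrix` of reference events.
#' @param q_low,q_high anchor quantiles, `0 <= q_low < q_high <= 1`.
#' @param cofactor asinh cofactor for fluorescence channels.
#' @return a `scaling_ref`.
#' @export
fit_scaling <- function(reference, q_low = 0.001, q_high = 0.999,
                        cofactor = 150) {
  if (n_events(reference) < 1) stop_rg("rg_input_error", "empty reference")
  if (!(q_low >= 0 && q_low < q_high && q_high <= 1))
    stop_rg("rg_input_error", "need 0 <= q_low < q_high <= 1")
  kinds <- transform_kind(reference$markers)
  chans <- lapply(seq_along(reference$markers), function(i) {
    x <- apply_transform(reference$values[, i], kinds[i], cofactor)
    qq <- unname(stats::quantile(x, c(q_low, q_high), names = FALSE))
    degen <- qq[2] <= qq[1]
    if (degen) {
      eps <- max(abs(qq[1]), 1) * sqrt(.Machine$double.eps)
      qq <- c(qq[1] - eps, qq[1] + eps)
    }
    list(transform = kinds[i],
         cofactor = if (kinds[i] == "asinh") cofactor else NA_real_,
         low = qq[1], high = qq[2], degenerate = degen)
  })
  names(chans) <- names(reference$markers)
  structure(list(channels = chans, markers = reference$markers,
                 mode = "quantile"), class = "scaling_ref")
}

#' Scale events to the unit interval
#'
#' Applies each channel's transform (asinh or linear), then the affine map
#' sending the channel's (low, high) anchors to (0, 1), clipping to [0,1].
#' Channels are matched by channel name, falling back to marker name.
#'
#' @param em an `event_matrix` with raw values.
#' @param ref a `scaling_ref` from [display_scaling()] or [fit_scaling()].
#' @return an `event_matrix` with values in [0,1]; `metadata$scaled = TRUE`.
#' @export
scale_to_unit <- function(em, ref) {
  out <- em
  for (i in seq_along(em$markers)) {
    ch <- names(em$markers)[i]
    sc <- ref$channels[[ch]]
    if (is.null(sc)) {
      # fall back to marker-name match (channel naming may differ per file)
      hit <- which(normalize_marker(ref$markers) ==
                   normalize_marker(em$markers[i]))
      if (!length(hit))
        stop_rg("rg_config_error", "no scaling for channel %s (marker %s)",
                ch, em$markers[i])
      sc <- ref$channels[[hit[1]]]
    }
    x <- apply_transform(em$values[, i], sc$transform, sc$cofactor)
    x <- (x - sc$low) / (sc$high - sc$low)
    out$values[, i] <- pmin(1, pmax(0, x))
  }
  out$metadata$scaled <- TRUE
  out
}

# serialize / restore scaling_ref for the template JSON
scaling_to_list <- function(ref) {
  list(mode = ref$mode,
       markers = as.list(ref$markers),
       channels = lapply(ref$channels, function(sc)
         list(transform = sc$transform,
              cofactor = if (is.na(sc$cofactor)) NULL else sc$cofactor,
              low = sc$low, high = sc$high, degenerate = sc$degenerate)))
}

scaling_from_list <- function(x) {
  chans <- lapply(x$channels, function(sc)
    list(transform = sc$transform,
         cofactor = if (is.null(sc$cofactor) || !length(sc$cofactor))
           NA_real_ else suppressWarnings(as.numeric(sc$cofactor)),
         low = as.numeric(sc$low), high = as.numeric(sc$high),
         degenerate = isTRUE(sc$degenerate)))
  structure(list(channels = chans,
                 markers = unlist(x$markers), mode = x$mode),
            class = "scaling_ref")
}
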