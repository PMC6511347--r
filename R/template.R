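# Screening-template construction: highest-density-region gates around
# merged reference APL blasts in radar space, per tube and per morphologic
# type, plus the frozen scaling and layouts that make new cases comparable.

#' Build a highest-density-region gate from projected reference blasts
#'
#' Estimates the 2D density of the reference points with a Gaussian kernel
#' (bandwidth by Scott's rule, per axis), takes the smallest highest-density
#' region containing at least `containment` of the points, and polygonizes
#' its outer contour at `n_vertices` vertices. Achieved containment is then
#' verified by a point-in-polygon recount; if below target the polygon is
#' dilated outward from its centroid by the minimal factor restoring it.
#' A disconnected HDR falls back to the convex hull of the union (flagged in
#' provenance). The gate stores a `grid_n` x `grid_n` reference density grid
#' (smoothed histogram of the in-gate reference points over the polygon's
#' bounding box, normalized to sum 1) used by the pattern-similarity score.
#'
#' @param points n x 2 matrix of projected reference blasts (n >= 500).
#' @param containment target containment fraction in (0.5, 1).
#' @param type gate type tag ("hypergranular" or "microgranular").
#' @param tube_id tube the gate belongs to.
#' @param n_vertices vertices of the polygonized contour.
#' @param grid_n resolution of the stored reference density grid.
#' @return a `gate_region`.
#' @export
build_gate <- function(points, containment = 0.95, type = "hypergranular",
                       tube_id = NA_integer_, n_vertices = 128, grid_n = 64) {
  points <- as.matrix(points)
  if (nrow(points) < 500)
    stop_rg("rg_input_error", "build_gate needs >= 500 points, got %d",
            nrow(points))
  if (!(containment > 0.5 && containment < 1))
    stop_rg("rg_input_error", "containment must lie in (0.5, 1)")
  x <- points[, 1]; y <- points[, 2]
  n <- length(x)
  sdx <- stats::sd(x); sdy <- stats::sd(y)
  disconnected <- FALSE

  if (sdx < 1e-12 && sdy < 1e-12) {
    # degenerate cloud: minimal square around the (single) location
    eps <- max(abs(c(x[1], y[1])), 1) * 1e-6
    verts <- rbind(c(x[1] - eps, y[1] - eps), c(x[1] + eps, y[1] - eps),
                   c(x[1] + eps, y[1] + eps), c(x[1] - eps, y[1] + eps))
    achieved <- 1.0
  } else {
    # Scott's rule sd per axis; kde2d's h is 4x the kernel sd
    hx <- max(sdx, 1e-9) * n^(-1 / 6)
    hy <- max(sdy, 1e-9) * n^(-1 / 6)
    lims <- c(range(x) + c(-4, 4) * hx, range(y) + c(-4, 4) * hy)
    kde <- MASS::kde2d(x, y, h = 4 * c(hx, hy), n = 151, lims = lims)
    dens_at <- bilinear_interp(kde, x, y)
    # density threshold: highest level keeping >= containment of the points
    srt <- sort(dens_at, decreasing = TRUE)
    level <- srt[ceiling(containment * n)]
    cl <- grDevices::contourLines(kde$x, kde$y, kde$z, levels = level * (1 - 1e-9))
    if (!length(cl)) {
      cl <- list(list(x = range(x)[c(1, 2, 2, 1)], y = range(y)[c(1, 1, 2, 2)]))
    }
    if (length(cl) > 1) {
      # multiple rings: nested islands keep the outer ring, disjoint rings
      # collapse to the convex hull of the union
      areas <- vapply(cl, function(cc) abs(polygon_area(cbind(cc$x, cc$y))), 0)
      outer <- cl[[which.max(areas)]]
      ov <- cbind(outer$x, outer$y)
      nested <- all(vapply(cl[-which.max(areas)], function(cc)
        all(points_in_polygon(cc$x, cc$y, ov)), TRUE))
      if (nested) {
        verts <- ov
      } else {
        pts <- do.call(rbind, lapply(cl, function(cc) cbind(cc$x, cc$y)))
        verts <- pts[grDevices::chull(pts), , drop = FALSE]
        disconnected <- TRUE
      }
    } else {
      verts <- cbind(cl[[1]]$x, cl[[1]]$y)
    }
    verts <- resample_polygon(verts, n_vertices)
    achieved <- mean(points_in_polygon(x, y, verts))
  }

  # dilate about the centroid until the recount reaches the target
  dilation <- 1.0
  if (achieved < containment) {
    ctr <- colMeans(verts)
    repeat {
      dilation <- dilation * 1.01
      vv <- sweep(sweep(verts, 2, ctr) * dilation, 2, ctr, `+`)
      achieved <- mean(points_in_polygon(x, y, vv))
      if (achieved >= containment || dilation > 10) { verts <- vv; break }
    }
  }

  gate_region(type = type, tube_id = tube_id, vertices = verts,
              density = density_grid(points, verts, grid_n),
              containment = achieved,
              provenance = list(n_points = n, dilation = dilation,
                                disconnected = disconnected))
}

#' Construct a gate region
#'
#' @param type "hypergranular" or "microgranular".
#' @param tube_id tube number.
#' @param vertices closed polygon vertices (matrix, radar coordinates).
#' @param density list with `grid` (matrix summing to 1), `xlim`, `ylim`.
#' @param containment achieved containment on the reference, in [0.95, 1].
#' @param provenance free-form list (reference size, dilation, flags).
#' @return a `gate_region`.
#' @export
gate_region <- function(type, tube_id, vertices, density, containment,
                        provenance = list()) {
  if (!type %in% c("hypergranular", "microgranular"))
    stop_rg("rg_template_error", "unknown gate type '%s'", type)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3)
    stop_rg("rg_geometry_error", "gate polygon needs >= 3 vertices")
  if (containment < 0.95 - 1e-9 || containment > 1 + 1e-9)
    stop_rg("rg_template_error",
            "achieved containment %.4f outside [0.95, 1]", containment)
  if (abs(sum(density$grid) - 1) > 1e-9)
    stop_rg("rg_template_error", "density grid must sum to 1")
  structure(list(type = type, tube_id = as.integer(tube_id),
                 vertices = vertices, density = density,
                 containment = containment, provenance = provenance),
            class = "gate_region")
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# resample a closed polygon to m vertices, equally spaced by arc length
resample_polygon <- function(v, m) {
  v <- rbind(v, v[1, ])
  seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  keep <- c(TRUE, seg > 0)  # drop zero-length segments (duplicate points)
  v <- v[keep, , drop = FALSE]
  seg <- seg[seg > 0]
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(v[rep(1, m), , drop = FALSE])
  tq <- seq(0, total, length.out = m + 1)[seq_len(m)]
  xi <- stats::approx(s, v[, 1], xout = tq)$y
  yi <- stats::approx(s, v[, 2], xout = tq)$y
  cbind(xi, yi)
}

bilinear_interp <- function(kde, px, py) {
  gx <- kde$x; gy <- kde$y; z <- kde$z
  ix <- findInterval(px, gx, rightmost.closed = TRUE)
  iy <- findInterval(py, gy, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1), length(gx) - 1)
  iy <- pmin(pmax(iy, 1), length(gy) - 1)
  fx <- (px - gx[ix]) / (gx[ix + 1] - gx[ix])
  fy <- (py - gy[iy]) / (gy[iy + 1] - gy[iy])
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  z[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
    z[cbind(ix + 1, iy)] * fx * (1 - fy) +
    z[cbind(ix, iy + 1)] * (1 - fx) * fy +
    z[cbind(ix + 1, iy + 1)] * fx * fy
}

# smoothed, normalized 2D histogram of the in-gate points over the polygon's
# bounding box; the light 3x3 Gaussian blur stabilizes the pattern score at
# moderate event counts
density_grid <- function(points, verts, grid_n) {
  xlim <- range(verts[, 1]); ylim <- range(verts[, 2])
  inside <- points_in_polygon(points[, 1], points[, 2], verts)
  h <- hist2d(points[inside, 1], points[inside, 2], xlim, ylim, grid_n)
  g <- blur3(h)
  s <- sum(g)
  if (s <= 0) { g <- matrix(1 / grid_n^2, grid_n, grid_n) } else g <- g / s
  list(grid = g, xlim = xlim, ylim = ylim, n = grid_n)
}

hist2d <- function(x, y, xlim, ylim, n) {
  if (!length(x)) return(matrix(0, n, n))
  ix <- pmin(pmax(ceiling((x - xlim[1]) / diff(xlim) * n), 1), n)
  iy <- pmin(pmax(ceiling((y - ylim[1]) / diff(ylim) * n), 1), n)
  m <- matrix(0, n, n)
  tab <- table(factor(ix, levels = 1:n), factor(iy, levels = 1:n))
  m[] <- as.numeric(tab)
  m
}

# 3x3 binomial blur with edge renormalization
blur3 <- function(m) {
  k <- c(0.25, 0.5, 0.25)
  n <- nrow(m)
  pad <- rbind(0, cbind(0, m, 0), 0)
  out <- matrix(0, n, n)
  for (di in -1:1) for (dj in -1:1) {
    w <- k[di + 2] * k[dj + 2]
    out <- out + w * pad[(2 + di):(n + 1 + di), (2 + dj):(n + 1 + dj)]
  }
  out
}

# --------------------------------------------------------------------------

#' Build a screening template from reference APL cases
#'
#' For each of the four tubes: gates blasts in every reference case (unless
#' pre-gated), merges the hypergranular cases and the microgranular cases
#' separately, scales with the frozen scaling reference, projects with the
#' tube layout, and builds one hypergranular and one microgranular
#' highest-density-region gate. The result — layouts, scaling, gates,
#' cut-off — is the trained screening instrument.
#'
#' @param ref_cases list of reference cases; each a list with `case_id`,
#'   `type` ("hypergranular"/"microgranular") and `tubes` (named list
#'   "1".."4" of `event_matrix` objects).
#' @param panel a `panel_config`.
#' @param layouts per-tube `radar_layout` list, or `"default"` for the
#'   shipped orderings, or `"optimize"` to run [optimize_layout()] per tube
#'   on the pooled reference blasts labelled by morphologic type.
#' @param containment gate containment level on the merged reference. The
#'   default 0.99 draws the gate generously around the expected blast
#'   positions so that individual same-type cases clear the case-level 95\%
#'   screening cut-off (see `cutoff`); it must stay >= 0.95.
#' @param cutoff case-level screening cut-off in percent (default 95).
#' @param scaling `"display"` (fixed instrument anchors; default) or
#'   `"quantile"` (anchors fit on the merged reference via [fit_scaling()]).
#' @param blast_gate CD45/SSC gate used when cases are not pre-gated.
#' @param pre_gated set TRUE when `tubes` already hold pure blasts.
#' @param grid_n stored density-grid resolution.
#' @param seed seed recorded in provenance and used for any subsampling.
#' @return a `cohort_template`.
#' @export
build_template <- function(ref_cases, panel = default_panel(),
                           layouts = "default", containment = 0.99,
                           cutoff = 95, scaling = c("display", "quantile"),
                           blast_gate = default_blast_gate(),
                           pre_gated = FALSE, grid_n = 64, seed = 1L) {
  scaling <- match.arg(scaling)
  if (containment < 0.95)
    stop_rg("rg_template_error", "gate containment must be >= 0.95")
  types <- vapply(ref_cases, `[[`, "", "type")
  if (!any(types == "hypergranular"))
    stop_rg("rg_input_error", "no hypergranular reference case")
  if (!any(types == "microgranular"))
    stop_rg("rg_input_error", "no microgranular reference case")
  tube_ids <- as.character(1:4)
  for (rc in ref_cases) for (tid in tube_ids)
    if (is.null(rc$tubes[[tid]]))
      stop_rg("rg_input_error", "case %s is missing tube %s", rc$case_id, tid)

  # blasts per case per tube
  blasts <- lapply(ref_cases, function(rc) {
    lapply(rc$tubes[tube_ids], function(em) {
      b <- if (pre_gated) em else gate_blasts(em, blast_gate)
      if (isTRUE(b$metadata$zero_blast))
        stop_rg("rg_input_error", "case %s has no blasts", rc$case_id)
      b
    })
  })

  if (identical(layouts, "default")) layouts <- default_layouts()

  scalings <- list(); gates_h <- list(); gates_m <- list()
  opt_layouts <- list()
  for (tid in tube_ids) {
    merged_all <- merge_cases(stats::setNames(
      lapply(seq_along(blasts), function(i) blasts[[i]][[tid]]),
      vapply(ref_cases, `[[`, "", "case_id")))
    sref <- if (scaling == "display") display_scaling(merged_all)
            else fit_scaling(merged_all)
    scalings[[tid]] <- sref
    scaled_all <- scale_to_unit(merged_all, sref)
    if (identical(layouts, "optimize")) {
      cand <- unname(merged_all$markers[!normalize_marker(merged_all$markers)
                                        %in% "FSC"])
      lay <- optimize_layout(scaled_all, cand,
                             labels = rep(types, vapply(
                               seq_along(blasts),
                               function(i) n_events(blasts[[i]][[tid]]), 0L)),
                             tube_id = as.integer(tid), seed = seed)
      opt_layouts[[tid]] <- lay
    } else opt_layouts[[tid]] <- layouts[[tid]]

    for (ty in c("hypergranular", "microgranular")) {
      sel <- which(types == ty)
      merged <- merge_cases(stats::setNames(
        lapply(sel, function(i) blasts[[i]][[tid]]),
        vapply(ref_cases[sel], `[[`, "", "case_id")))
      P <- project_radar(scale_to_unit(merged, sref), opt_layouts[[tid]])
      g <- build_gate(P, containment = containment, type = ty,
                      tube_id = as.integer(tid), grid_n = grid_n)
      g$provenance$n_cases <- length(sel)
      g$provenance$case_ids <- vapply(ref_cases[sel], `[[`, "", "case_id")
      if (ty == "hypergranular") gates_h[[tid]] <- g else gates_m[[tid]] <- g
    }
  }

  structure(list(
    schema_version = 1L,
    panel = panel,
    layouts = opt_layouts,
    scaling = scalings,
    gates = list(hypergranular = gates_h, microgranular = gates_m),
    blast_gate = blast_gate,
    cutoff = cutoff,
    provenance = list(
      case_ids = vapply(ref_cases, `[[`, "", "case_id"),
      types = types, seed = seed,
      containment = containment,
      build_date = "1970-01-01")  # fixed for byte-identical rebuilds
  ), class = "cohort_template")
}

#' @export
print.cohort_template <- function(x, ...) {
  cat(sprintf("cohort_template: %d reference cases (%d hyper, %d micro), cutoff %.1f%%\n",
              length(x$provenance$case_ids),
              sum(x$provenance$types == "hypergranular"),
              sum(x$provenance$types == "microgranular"), x$cutoff))
  for (tid in names(x$gates$hypergranular))
    cat(sprintf("  tube %s: K=%d [%s]; containment H=%.3f M=%.3f\n", tid,
                length(x$layouts[[tid]]$channels),
                paste(x$layouts[[tid]]$channels, collapse = ","),
                x$gates$hypergranular[[tid]]$containment,
                x$gates$microgranular[[tid]]$containment))
  invisible(x)
}

gate_to_list <- function(g) {
  list(type = g$type, tube_id = g$tube_id,
       vertices = unname(apply(g$vertices, 1, as.numeric, simplify = FALSE)),
       density = list(grid = unname(apply(g$density$grid, 1, as.numeric,
                                          simplify = FALSE)),
                      xlim = as.numeric(g$density$xlim),
                      ylim = as.numeric(g$density$ylim),
                      n = g$density$n),
       containment = g$containment,
       provenance = g$provenance)
}

gate_from_list <- function(x) {
  grid <- do.call(rbind, lapply(x$density$grid, unlist))
  g <- grid / sum(grid)
  gate_region(type = x$type, tube_id = x$tube_id,
              vertices = do.call(rbind, lapply(x$vertices, unlist)),
              density = list(grid = g,
                             xlim = unlist(x$density$xlim),
                             ylim = unlist(x$density$ylim),
                             n = x$density$n),
              containment = as.numeric(x$containment),
              provenance = x$provenance)
}

#' Save a screening template as JSON
#'
#' @param template a `cohort_template`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_template <- function(template, path) {
  x <- list(
    schema_version = template$schema_version,
    panel = list(tubes = lapply(template$panel$tubes, function(tb)
      list(tube_id = tb$tube_id, markers = tb$markers)),
      detectors = template$panel$detectors),
    layouts = lapply(template$layouts, function(l)
      list(tube_id = l$tube_id, channels = l$channels)),
    scaling = lapply(template$scaling, scaling_to_list),
    gates = lapply(template$gates, function(gg) lapply(gg, gate_to_list)),
    blast_gate = list(name = template$blast_gate$name,
                      channels = template$blast_gate$channels,
                      vertices = unname(apply(template$blast_gate$vertices, 1,
                                              as.numeric, simplify = FALSE))),
    cutoff = template$cutoff,
    provenance = template$provenance)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load a screening template from JSON
#'
#' Validates the schema on load: all four tubes present, cut-off in (0,100),
#' polygons and density grids well-formed.
#'
#' @param path JSON path written by [save_template()].
#' @return a `cohort_template`.
#' @export
load_template <- function(path) {
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e)
                  stop_rg("rg_template_error", "unreadable template: %s",
                          conditionMessage(e)))
  need <- c("schema_version", "panel", "layouts", "scaling", "gates", "cutoff")
  for (f in need) if (is.null(x[[f]]))
    stop_rg("rg_template_error", "template field missing: %s", f)
  cutoff <- as.numeric(x$cutoff)
  if (!(cutoff > 0 && cutoff < 100))
    stop_rg("rg_template_error", "cutoff: must lie in (0,100), got %s", cutoff)
  tube_ids <- as.character(1:4)
  if (!all(tube_ids %in% names(x$layouts)))
    stop_rg("rg_template_error", "layouts: all four tubes required")
  panel <- panel_config(lapply(x$panel$tubes, function(tb)
    list(tube_id = as.integer(tb$tube_id), markers = unlist(tb$markers))),
    detectors = unlist(x$panel$detectors))
  layouts <- lapply(x$layouts, function(l)
    radar_layout(as.integer(l$tube_id), unlist(l$channels)))
  scalings <- lapply(x$scaling, scaling_from_list)
  gates <- lapply(x$gates, function(gg) lapply(gg, gate_from_list))
  for (ty in c("hypergranular", "microgranular"))
    if (!all(tube_ids %in% names(gates[[ty]])))
      stop_rg("rg_template_error", "gates.%s: all four tubes required", ty)
  bg <- polygon_gate(x$blast_gate$name, unlist(x$blast_gate$channels),
                     do.call(rbind, lapply(x$blast_gate$vertices, unlist)))
  structure(list(
    schema_version = x$schema_version,
    panel = panel, layouts = layouts, scaling = scalings, gates = gates,
    blast_gate = bg, cutoff = cutoff, provenance = x$provenance),
    class = "cohort_template")
}
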