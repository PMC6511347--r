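# Seeded synthetic cytometry cohort generator.
#
# Emulates 8-color, four-tube AML acquisitions for three diagnostic groups:
# hypergranular APL, microgranular APL, and NPM1-type CD34-negative non-APL
# AML (the immunophenotypic mimic). Blast marker positivity follows the
# published antigen-expression frequencies per group; side scatter encodes
# the hyper-/microgranular distinction; lymphocyte, monocyte and granulocyte
# background populations sit at their canonical CD45/SSC positions.
#
# Intensity model: every (population, marker) value is log-normal in raw
# units. Case-level marker status is Bernoulli per case (shared across
# tubes); hard 0%/100% table cells are fixed constraints. A positive blast
# population expresses the marker in a per-case fraction of events (high for
# lineage antigens, partial for dim aberrancy/LAIP antigens), and every
# (case, marker) pair carries a multiplicative log-normal case effect
# representing inter-patient intensity variation.

# intensity levels (raw fluorescence units, medians)
RG_LEVELS <- list(neg = 50, dim = 300, mod = 1000, pos = 3000, bright = 8000)
RG_EVENT_SDLOG <- 0.47     # within-population spread, CV ~ 50%
RG_CASE_SDLOG <- 0.15      # inter-patient intensity variation

#' Default phenotype specifications for the three simulated groups
#'
#' Encodes, per group, the case-level positivity probability of every panel
#' marker (probability 0/1 cells act as hard constraints), the intensity
#' class of a positive ("dim" aberrancy/LAIP markers vs "lineage" antigens,
#' with bright myeloid antigens in the CD33-bright groups), the SSC level
#' (high for hypergranular, medium for microgranular, low-medium for the
#' non-APL mimics), and the bone-marrow blast-fraction range per group.
#'
#' @return named list of three `phenotype_spec` objects: `hypergranular`,
#'   `microgranular`, `non_apl`.
#' @export
default_phenotypes <- function() {
  # marker, P(positive | group) for hyper / micro / non-APL, positive class
  tab <- read.table(text = "
marker     hyper micro non  class level
CD117      1     1     1    lineage pos
CD34       0     1     0    lineage pos
HLA-DR     0     0     0.58 lineage pos
CD33       1     1     1    lineage bright
CD13       1     1     1    lineage bright
cyMPO      1     1     0.83 lineage bright
CD14       0     0     0.42 laip    mod
CD11b      0     0     0.42 laip    mod
CD64       0.5   0.5   0.42 laip    dim
CD4        0     0     0.42 laip    dim
CD15       0     0     0.42 laip    mod
CD123      0     1     0.75 laip    mod
CD56       0.17  0     0.25 laip    dim
CD38       1     1     1    lineage pos
CD7        0     0.5   0.25 laip    dim
CD2        0.17  1     0    laip    dim
cyFXIII-A  1     1     0.75 lineage pos
CD71       1     1     1    laip    mod
CD300e     0     0     0.3  laip    dim
CD10       0     0     0    laip    dim
CD16       0     0     0    laip    dim
", header = TRUE, stringsAsFactors = FALSE)
  mk_spec <- function(group, pcol, ssc_meanlog, ssc_sdlog, blast_range,
                      bright_myeloid) {
    markers <- data.frame(marker = tab$marker, prob = tab[[pcol]],
                          class = tab$class, level = tab$level,
                          stringsAsFactors = FALSE)
    if (!bright_myeloid) {
      markers$level[markers$marker %in% c("CD33", "CD13", "cyMPO")] <- "pos"
      # non-APL mimics are selected to be CD33 bright
      markers$level[markers$marker == "CD33"] <- "bright"
    }
    structure(list(
      group = group,
      markers = markers,
      cd45 = c(meanlog = log(1200), sdlog = 0.30),
      ssc = c(meanlog = ssc_meanlog, sdlog = ssc_sdlog),
      fsc = c(meanlog = log(60000), sdlog = 0.20),
      blast_fraction_range = blast_range,
      background_mix = c(lymphocyte = 0.45, monocyte = 0.15,
                         granulocyte = 0.40)),
      class = "phenotype_spec")
  }
  list(
    hypergranular = mk_spec("hypergranular", "hyper",
                            log(85000), 0.25, c(0.266, 0.875), TRUE),
    microgranular = mk_spec("microgranular", "micro",
                            log(40000), 0.25, c(0.266, 0.875), TRUE),
    non_apl = mk_spec("non_apl", "non",
                      log(22000), 0.35, c(0.207, 0.829), FALSE)
  )
}

# background population profiles: per population, CD45/SSC/FSC log-normal
# parameters and event-level marker expression (prob, median level)
background_profiles <- function() {
  prof <- function(cd45, cd45sd, ssc, sscsd, fsc, markers) {
    list(cd45 = c(log(cd45), cd45sd), ssc = c(log(ssc), sscsd),
         fsc = c(log(fsc), 0.2), markers = markers)
  }
  mk <- function(...) {
    m <- list(...)
    data.frame(marker = names(m),
               prob = vapply(m, `[[`, 0, 1),
               level = vapply(m, `[[`, 0, 2), stringsAsFactors = FALSE)
  }
  list(
    lymphocyte = prof(9000, 0.20, 10000, 0.25, 40000,
      mk("CD7" = c(0.75, 1500), "CD2" = c(0.75, 1500), "CD4" = c(0.45, 1500),
         "CD38" = c(0.80, 600), "CD56" = c(0.10, 300), "CD10" = c(0.05, 300),
         "HLA-DR" = c(0.15, 1500))),
    monocyte = prof(8000, 0.20, 30000, 0.25, 55000,
      mk("CD14" = c(0.95, 3000), "CD11b" = c(0.95, 2000), "CD13" = c(0.90, 2000),
         "CD33" = c(0.95, 6000), "CD64" = c(0.90, 2000), "CD4" = c(0.90, 600),
         "HLA-DR" = c(0.95, 3000), "CD300e" = c(0.85, 1000),
         "CD38" = c(0.80, 600), "cyMPO" = c(0.60, 500),
         "cyFXIII-A" = c(0.70, 1000), "CD15" = c(0.30, 600))),
    granulocyte = prof(6000, 0.15, 80000, 0.22, 65000,
      mk("CD13" = c(0.90, 1500), "CD33" = c(0.90, 1200), "CD11b" = c(0.95, 2500),
         "CD15" = c(0.95, 3000), "CD16" = c(0.85, 2500), "CD64" = c(0.30, 400),
         "cyMPO" = c(0.95, 4000), "CD10" = c(0.40, 600), "CD38" = c(0.30, 400)))
  )
}

level_meanlog <- function(level) log(RG_LEVELS[[level]])

# draw raw intensities for one marker within one population
draw_marker <- function(n, pos_idx, pos_meanlog, case_factor) {
  x <- stats::rlnorm(n, meanlog = log(RG_LEVELS$neg), sdlog = RG_EVENT_SDLOG)
  if (length(pos_idx))
    x[pos_idx] <- stats::rlnorm(length(pos_idx),
                                meanlog = pos_meanlog + log(case_factor),
                                sdlog = RG_EVENT_SDLOG)
  x
}

#' Simulate one synthetic case
#'
#' Draws the case-level marker statuses once (shared across tubes, so e.g. a
#' CD34-negative case is CD34-negative in every tube carrying CD34), the
#' blast fraction uniformly from the group's bone-marrow range, and then per
#' tube the event-level raw intensities for blasts and background
#' populations. Event counts per population follow an exact largest-remainder
#' allocation of `n_events`. Truth population labels are attached to every
#' event.
#'
#' @param spec a `phenotype_spec` (see [default_phenotypes()]).
#' @param panel a `panel_config`.
#' @param n_events events per tube (>= 1000; the study acquisitions hold
#'   100,000).
#' @param seed integer seed; the same (spec, panel, n_events, seed) is
#'   reproduced bit for bit.
#' @param case_id case identifier.
#' @return a `synthetic_case`: list with `case_id`, `group`, `seed`,
#'   `blast_fraction`, `statuses` (named 0/1), `pos_fractions`, `tubes`
#'   (named list of labelled `event_matrix`).
#' @export
simulate_case <- function(spec, panel = default_panel(), n_events = 100000,
                          seed = 1L, case_id = NULL) {
  if (n_events < 1000)
    stop_rg("rg_input_error", "n_events must be >= 1000")
  for (m in spec$markers$marker) {
    found <- any(vapply(panel$tubes, function(tb)
      any(marker_eq(tb$markers, m)), TRUE))
    if (!found)
      stop_rg("rg_config_error", "phenotype marker %s not in panel", m)
  }
  if (is.null(case_id)) case_id <- sprintf("%s_s%d", spec$group, seed)
  set.seed(seed)

  mk <- spec$markers
  statuses <- stats::setNames(stats::rbinom(nrow(mk), 1, mk$prob), mk$marker)
  # per-case fraction of blast events expressing a positive marker
  pos_frac <- stats::setNames(ifelse(
    mk$class == "lineage",
    stats::runif(nrow(mk), 0.85, 0.95),
    stats::runif(nrow(mk), 0.35, 0.65)), mk$marker)
  # inter-patient intensity effect, one factor per marker
  case_factor <- stats::setNames(
    stats::rlnorm(nrow(mk), 0, RG_CASE_SDLOG), mk$marker)
  cd45_factor <- stats::rlnorm(1, 0, 0.10)
  ssc_factor <- stats::rlnorm(1, 0, 0.12)
  blast_fraction <- stats::runif(1, spec$blast_fraction_range[1],
                                 spec$blast_fraction_range[2])

  counts <- allocate_counts(n_events,
                            c(blast = blast_fraction,
                              (1 - blast_fraction) * spec$background_mix))
  names(counts) <- c("blast", names(spec$background_mix))
  pop_labels <- rep(names(counts), counts)
  bg <- background_profiles()

  tubes <- list()
  for (tb in panel$tubes) {
    chmap <- panel_channels(panel, tb$tube_id)
    values <- matrix(0, n_events, length(chmap),
                     dimnames = list(NULL, names(chmap)))
    row0 <- 0L
    for (pop in names(counts)) {
      n <- counts[[pop]]
      if (n == 0L) next
      idx <- row0 + seq_len(n)
      if (pop == "blast") {
        fsc <- stats::rlnorm(n, spec$fsc[1], spec$fsc[2])
        ssc <- stats::rlnorm(n, spec$ssc[1] + log(ssc_factor), spec$ssc[2])
        cd45 <- stats::rlnorm(n, spec$cd45[1] + log(cd45_factor),
                              spec$cd45[2])
      } else {
        pr <- bg[[pop]]
        fsc <- stats::rlnorm(n, pr$fsc[1], pr$fsc[2])
        ssc <- stats::rlnorm(n, pr$ssc[1], pr$ssc[2])
        cd45 <- stats::rlnorm(n, pr$cd45[1], pr$cd45[2])
      }
      values[idx, "FSC-A"] <- pmin(fsc, 262143)
      values[idx, "SSC-A"] <- pmin(ssc, 262143)
      for (ci in seq_along(chmap)) {
        ch <- names(chmap)[ci]
        marker <- chmap[[ci]]
        if (marker %in% c("FSC", "SSC")) next
        if (normalize_marker(marker) == "CD45") {
          values[idx, ch] <- pmin(cd45, 262143)
          next
        }
        if (pop == "blast") {
          mrow <- which(marker_eq(mk$marker, marker))[1]
          m <- mk$marker[mrow]
          frac <- if (statuses[[m]] == 1) pos_frac[[m]] else 0.02
          npos <- round(n * frac)
          pos_idx <- if (npos > 0) sample.int(n, npos) else integer(0)
          lvl <- if (statuses[[m]] == 1) level_meanlog(mk$level[mrow])
                 else level_meanlog("dim")
          x <- draw_marker(n, pos_idx, lvl, case_factor[[m]])
        } else {
          pr <- bg[[pop]]$markers
          brow <- which(marker_eq(pr$marker, marker))
          if (length(brow)) {
            npos <- stats::rbinom(1, n, pr$prob[brow[1]])
            pos_idx <- if (npos > 0) sample.int(n, npos) else integer(0)
            x <- draw_marker(n, pos_idx, log(pr$level[brow[1]]), 1)
          } else {
            x <- draw_marker(n, integer(0), 0, 1)
          }
        }
        values[idx, ch] <- pmin(x, 262143)
      }
      row0 <- row0 + n
    }
    tubes[[as.character(tb$tube_id)]] <- event_matrix(
      values, chmap,
      labels = data.frame(case_id = rep(case_id, n_events),
                          population = pop_labels,
                          stringsAsFactors = FALSE),
      metadata = list(group = spec$group, seed = seed),
      tube_id = tb$tube_id)
  }
  structure(list(case_id = case_id, group = spec$group, seed = seed,
                 blast_fraction = blast_fraction,
                 statuses = statuses, pos_fractions = pos_frac,
                 tubes = tubes),
            class = "synthetic_case")
}

#' Simulate a seeded cohort
#'
#' Per-case seeds are derived deterministically from the master seed, so the
#' whole cohort is reproducible from one integer. The default design mirrors
#' an 8 APL (6 hypergranular + 2 microgranular) vs 12 non-APL study.
#'
#' @param n_hyper,n_micro,n_non group sizes (>= 0).
#' @param panel a `panel_config`.
#' @param n_events events per tube per case.
#' @param seed master seed.
#' @param phenotypes phenotype specs (see [default_phenotypes()]).
#' @return list with `cases` (list of `synthetic_case`) and `manifest`
#'   (data.frame: case_id, group, seed, blast_fraction, one status column per
#'   marker).
#' @export
simulate_cohort <- function(n_hyper = 6, n_micro = 2, n_non = 12,
                            panel = default_panel(), n_events = 100000,
                            seed = 42L, phenotypes = default_phenotypes()) {
  groups <- c(rep("hypergranular", n_hyper), rep("microgranular", n_micro),
              rep("non_apl", n_non))
  cases <- vector("list", length(groups))
  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    cseed <- derive_seed(seed, i)
    sc <- simulate_case(phenotypes[[groups[i]]], panel, n_events,
                        seed = cseed,
                        case_id = sprintf("%s_%02d", groups[i], i))
    cases[[i]] <- sc
    st <- as.list(sc$statuses)
    names(st) <- paste0("status_", gsub("[^A-Za-z0-9]", "", names(st)))
    rows[[i]] <- cbind(data.frame(case_id = sc$case_id, group = sc$group,
                                  seed = cseed,
                                  blast_fraction = sc$blast_fraction,
                                  n_events = n_events,
                                  stringsAsFactors = FALSE),
                       as.data.frame(st))
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(0), group = character(0))
  list(cases = cases, manifest = manifest)
}

#' Write a synthetic case to FCS files
#'
#' One FCS 3.1 file per tube (`<case_id>_tube<k>.fcs`, marker names in $PnS)
#' plus one truth-label sidecar CSV (`<case_id>_truth.csv`) holding the
#' per-event population label shared by all four tubes.
#'
#' @param case a `synthetic_case`.
#' @param directory output directory (created if needed).
#' @return character vector of written file paths.
#' @export
write_case_fcs <- function(case, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  paths <- character(0)
  for (tid in names(case$tubes)) {
    p <- file.path(directory, sprintf("%s_tube%s.fcs", case$case_id, tid))
    write_fcs(case$tubes[[tid]], p)
    paths <- c(paths, p)
  }
  tp <- file.path(directory, sprintf("%s_truth.csv", case$case_id))
  utils::write.csv(case$tubes[[1]]$labels, tp, row.names = FALSE)
  c(paths, tp)
}
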