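# FCS 3.0/3.1 list-mode input/output, panel configuration and case merging.
#
# No FCS-capable package is assumed: the reader handles FCS 3.0/3.1 with
# datatype F (float32), D (float64) or I (uniform 16/32-bit integers), list
# mode, little- or big-endian; the writer emits FCS 3.1, datatype F.

#' Four-tube AML panel definition
#'
#' Builds the default eight-color, four-tube AML screening panel. Each tube
#' carries FSC and SSC plus eight fluorescence detectors
#' (FITC, PE, PerCP-Cy5.5/PC5.5, PC7, APC, APC-AF750, PB, PO) whose marker
#' assignment per tube is:
#' \enumerate{
#'   \item CD14, CD11b, HLA-DR, CD13, CD300e, CD64, CD4, CD45
#'   \item CD15, CD123, CD34, CD13, CD10, CD16, HLA-DR, CD45
#'   \item CD71, CD117, CD33, CD56, CD34, CD38, CD7, CD45
#'   \item cyFXIII-A, cyMPO, CD33, CD2, CD34, CD117, HLA-DR, CD45
#' }
#' CD45 (PO) and SSC are present in every tube, anchoring the blast gate.
#'
#' @return a `panel_config` object.
#' @export
default_panel <- function() {
  tubes <- list(
    list(tube_id = 1L, markers = c("CD14", "CD11b", "HLA-DR", "CD13",
                                   "CD300e", "CD64", "CD4", "CD45")),
    list(tube_id = 2L, markers = c("CD15", "CD123", "CD34", "CD13",
                                   "CD10", "CD16", "HLA-DR", "CD45")),
    list(tube_id = 3L, markers = c("CD71", "CD117", "CD33", "CD56",
                                   "CD34", "CD38", "CD7", "CD45")),
    list(tube_id = 4L, markers = c("cyFXIII-A", "cyMPO", "CD33", "CD2",
                                   "CD34", "CD117", "HLA-DR", "CD45"))
  )
  panel_config(tubes)
}

#' Construct and validate a panel configuration
#'
#' @param tubes list of tube specifications, each a list with `tube_id`
#'   (integer) and `markers` (character vector of fluorescence markers ordered
#'   by detector position).
#' @param detectors detector (fluorochrome) names, one per fluorescence
#'   channel; scatter channels FSC-A/SSC-A are implicit and always first.
#' @return a `panel_config` object.
#' @export
panel_config <- function(tubes,
                         detectors = c("FITC-A", "PE-A", "PerCP-Cy5.5-A",
                                       "PC7-A", "APC-A", "APC-AF750-A",
                                       "PB-A", "PO-A")) {
  if (!length(tubes)) stop_rg("rg_config_error", "panel needs at least one tube")
  for (tb in tubes) {
    if (is.null(tb$tube_id) || is.null(tb$markers))
      stop_rg("rg_config_error", "each tube needs tube_id and markers")
    if (length(tb$markers) != length(detectors))
      stop_rg("rg_config_error", "tube %s: %d markers for %d detectors",
              tb$tube_id, length(tb$markers), length(detectors))
    nm <- normalize_marker(tb$markers)
    if (anyDuplicated(nm))
      stop_rg("rg_config_error", "tube %s: duplicated marker %s",
              tb$tube_id, tb$markers[duplicated(nm)][1])
    if (!"CD45" %in% nm)
      stop_rg("rg_config_error", "tube %s: CD45 missing", tb$tube_id)
  }
  structure(list(tubes = tubes, detectors = detectors,
                 scatter = c("FSC-A", "SSC-A")),
            class = "panel_config")
}

panel_tube <- function(panel, tube_id) {
  for (tb in panel$tubes) if (tb$tube_id == tube_id) return(tb)
  stop_rg("rg_config_error", "tube %s not in panel", tube_id)
}

# channel names and channel->marker map for one tube
panel_channels <- function(panel, tube_id) {
  tb <- panel_tube(panel, tube_id)
  ch <- c(panel$scatter, panel$detectors)
  mk <- c("FSC", "SSC", tb$markers)
  names(mk) <- ch
  mk
}

#' Read a panel configuration from JSON
#'
#' The JSON document holds `tubes`, an array of objects with `tube_id` and
#' `markers` (ordered marker list), and optionally `detectors`.
#'
#' @param path JSON file path.
#' @return a `panel_config`.
#' @export
read_panel_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tubes <- lapply(seq_len(nrow(x$tubes)), function(i) {
    list(tube_id = as.integer(x$tubes$tube_id[i]),
         markers = unlist(x$tubes$markers[i]))
  })
  if (!is.null(x$detectors)) panel_config(tubes, detectors = x$detectors)
  else panel_config(tubes)
}

#' Construct an event matrix
#'
#' The central in-memory container: an events-by-channels numeric matrix of
#' raw fluorescence/scatter values plus a channel-to-marker map and optional
#' per-event labels (case id, population).
#'
#' @param values numeric matrix, events in rows, channels in columns (column
#'   names are channel names).
#' @param markers named character vector mapping channel name to marker name.
#' @param labels optional data.frame with one row per event (e.g. columns
#'   `case_id`, `population`).
#' @param metadata list of acquisition keywords (e.g. spillover matrix).
#' @param tube_id optional tube number.
#' @return an `event_matrix` object.
#' @export
event_matrix <- function(values, markers, labels = NULL, metadata = list(),
                         tube_id = NA_integer_) {
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop_rg("rg_input_error", "event matrix needs >= 1 event")
  if (is.null(colnames(values))) colnames(values) <- names(markers)
  if (!all(is.finite(values)))
    stop_rg("rg_input_error", "event values must be finite")
  if (anyDuplicated(colnames(values)))
    stop_rg("rg_input_error", "channel names must be unique")
  if (!setequal(names(markers), colnames(values)))
    stop_rg("rg_config_error", "marker map does not cover the channels")
  markers <- markers[colnames(values)]
  if (!is.null(labels)) {
    labels <- as.data.frame(labels, stringsAsFactors = FALSE)
    if (nrow(labels) != nrow(values))
      stop_rg("rg_input_error", "labels must have one row per event")
  }
  structure(list(values = values, markers = markers, labels = labels,
                 metadata = metadata, tube_id = as.integer(tube_id)),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("event_matrix: %d events x %d channels (tube %s)\n",
              nrow(x$values), ncol(x$values),
              ifelse(is.na(x$tube_id), "?", x$tube_id)))
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  if (!is.null(x$labels))
    cat("  labels:", paste(names(x$labels), collapse = ", "), "\n")
  invisible(x)
}

n_events <- function(em) nrow(em$values)

# channel name carrying a marker (normalized match); error if absent
marker_channel <- function(em, marker) {
  hit <- which(normalize_marker(em$markers) == normalize_marker(marker))
  if (!length(hit))
    stop_rg("rg_config_error", "marker %s not present in event matrix", marker)
  names(em$markers)[hit[1]]
}

marker_values <- function(em, marker) em$values[, marker_channel(em, marker)]

# ---------------------------------------------------------------------------
# FCS writing (FCS 3.1, list mode, float32, little-endian)

fcs_keyword_text <- function(kw, delim = "/") {
  esc <- function(s) gsub(delim, paste0(delim, delim), s, fixed = TRUE)
  paste0(delim, paste(vapply(names(kw), function(k)
    paste0(esc(k), delim, esc(as.character(kw[[k]]))), ""),
    collapse = delim), delim)
}

#' Write an event matrix as an FCS 3.1 file
#'
#' Emits list-mode FCS 3.1 with float (datatype F) storage, little-endian,
#' 32 bits per parameter. Channel names go to $PnN, marker names to $PnS.
#'
#' @param em an `event_matrix`.
#' @param path output file path.
#' @param extra_keywords named list of additional TEXT-segment keywords
#'   (e.g. `$SPILLOVER`).
#' @return `path`, invisibly.
#' @export
write_fcs <- function(em, path, extra_keywords = list()) {
  values <- em$values
  npar <- ncol(values)
  ntot <- nrow(values)
  kw <- list(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(npar), "$TOT" = as.character(ntot)
  )
  for (i in seq_len(npar)) {
    kw[[sprintf("$P%dB", i)]] <- "32"
    kw[[sprintf("$P%dE", i)]] <- "0,0"
    kw[[sprintf("$P%dR", i)]] <- "262144"
    kw[[sprintf("$P%dN", i)]] <- colnames(values)[i]
    kw[[sprintf("$P%dS", i)]] <- unname(em$markers[i])
  }
  for (k in names(extra_keywords)) kw[[k]] <- extra_keywords[[k]]

  # fix offsets: TEXT starts at byte 58 (0-based, right after the header);
  # placeholders padded to fixed width so text length is offset-independent
  text_start <- 58L
  bd <- "%BD%"; ed <- "%ED%"
  txt0 <- fcs_keyword_text(kw)
  # data begins right after TEXT; pad both offsets to 10 digits
  n_text <- nchar(txt0, type = "bytes") + 2L * (10L - 4L)
  data_start <- text_start + n_text
  data_end <- data_start + 4L * npar * ntot - 1L
  txt <- sub(bd, formatC(data_start, width = 10, flag = "0"), txt0, fixed = TRUE)
  txt <- sub(ed, formatC(data_end, width = 10, flag = "0"), txt, fixed = TRUE)
  text_end <- text_start + nchar(txt, type = "bytes") - 1L

  hdr_off <- function(x) {
    s <- as.character(x)
    if (nchar(s) > 8) s <- "0"  # exceeds header field; TEXT keywords govern
    formatC(s, width = 8, flag = " ")
  }
  header <- paste0("FCS3.1    ",
                   hdr_off(text_start), hdr_off(text_end),
                   hdr_off(if (data_end <= 99999999) data_start else 0),
                   hdr_off(if (data_end <= 99999999) data_end else 0),
                   hdr_off(0), hdr_off(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.vector(t(values)), con, size = 4L, endian = "little")
  invisible(path)
}

# ---------------------------------------------------------------------------
# FCS reading

parse_fcs_text <- function(raw_txt) {
  delim <- rawToChar(raw_txt[1])
  body <- rawToChar(raw_txt[-1])
  Encoding(body) <- "latin1"
  # split on single delimiters; doubled delimiters are escapes
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  # re-join escaped (empty) pieces: an empty part means a doubled delimiter
  out <- character(0); buf <- NULL
  i <- 1
  while (i <= length(parts)) {
    piece <- parts[i]
    if (is.null(buf)) buf <- piece else buf <- paste0(buf, delim, piece)
    if (i == length(parts) || parts[i + 1] != "" || TRUE) {
      # lookahead: if next part is empty, this value contained an escaped delim
      if (i < length(parts) && parts[i + 1] == "") { i <- i + 1 } else {
        out <- c(out, buf); buf <- NULL
      }
    }
    i <- i + 1
  }
  if (length(out) %% 2 == 1) out <- out[-length(out)]
  kw <- as.list(out[seq(2, length(out), by = 2)])
  names(kw) <- toupper(trimws(out[seq(1, length(out), by = 2)]))
  kw
}

parse_spillover <- function(s) {
  parts <- strsplit(s, ",")[[1]]
  n <- as.integer(parts[1])
  if (is.na(n) || length(parts) < 1 + n + n * n) return(NULL)
  chs <- trimws(parts[2:(1 + n)])
  vals <- as.numeric(parts[(2 + n):(1 + n + n * n)])
  matrix(vals, nrow = n, byrow = TRUE, dimnames = list(chs, chs))
}

#' Read an FCS 3.0/3.1 list-mode file
#'
#' Parses the header, delimited TEXT segment and DATA segment of an FCS 3.0
#' or 3.1 file (datatype F, D, or uniform-width 16/32-bit I; list mode).
#' If a panel is supplied, the declared parameter count must match the tube
#' layout (scatter + fluorescence detectors) and markers are mapped by panel
#' position; a $PnS keyword that contradicts the panel raises a configuration
#' error naming the channel. A $SPILLOVER (or $COMP/SPILL) keyword is parsed
#' into `metadata$spillover`. Events are never subsampled; order is preserved.
#'
#' @param path FCS file path.
#' @param panel optional `panel_config`.
#' @param tube_id tube number within the panel (required when `panel` given).
#' @return an `event_matrix`.
#' @export
read_fcs <- function(path, panel = NULL, tube_id = NULL) {
  if (!file.exists(path)) stop_rg("rg_file_error", "no such file: %s", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 58) stop_rg("rg_format_error", "truncated FCS file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 58L)
  version <- rawToChar(header[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop_rg("rg_format_error", "unsupported FCS version '%s'", version)
  off <- function(a, b) suppressWarnings(as.numeric(trimws(rawToChar(header[a:b]))))
  ts <- off(11, 18); te <- off(19, 26); ds <- off(27, 34); de <- off(35, 42)
  if (any(is.na(c(ts, te))) || te <= ts || te >= sz)
    stop_rg("rg_format_error", "corrupt FCS header offsets")
  seek(con, ts)
  kw <- parse_fcs_text(readBin(con, "raw", te - ts + 1))
  gk <- function(k) kw[[toupper(k)]]
  npar <- as.integer(gk("$PAR")); ntot <- as.integer(gk("$TOT"))
  if (is.na(npar) || is.na(ntot))
    stop_rg("rg_format_error", "missing $PAR/$TOT keywords")
  if (is.na(ds) || ds == 0) ds <- as.numeric(gk("$BEGINDATA"))
  if (is.na(de) || de == 0) de <- as.numeric(gk("$ENDDATA"))
  if (any(is.na(c(ds, de))) || de < ds || de >= sz)
    stop_rg("rg_format_error", "corrupt data segment offsets")
  dtype <- toupper(gk("$DATATYPE"))
  byteord <- gk("$BYTEORD")
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"
  seek(con, ds)
  nval <- npar * ntot
  if (identical(dtype, "F")) {
    vals <- readBin(con, "numeric", nval, size = 4L, endian = endian)
  } else if (identical(dtype, "D")) {
    vals <- readBin(con, "numeric", nval, size = 8L, endian = endian)
  } else if (identical(dtype, "I")) {
    bits <- unique(vapply(seq_len(npar),
                          function(i) as.integer(gk(sprintf("$P%dB", i))), 0L))
    if (length(bits) != 1 || !bits %in% c(16L, 32L))
      stop_rg("rg_format_error", "only uniform 16/32-bit integer data supported")
    if (bits == 16L) {
      vals <- readBin(con, "integer", nval, size = 2L, signed = FALSE,
                      endian = endian)
    } else {
      vals <- readBin(con, "integer", nval, size = 4L, endian = endian)
      vals <- ifelse(vals < 0, vals + 2^32, vals)
    }
  } else stop_rg("rg_format_error", "unsupported $DATATYPE '%s'", dtype)
  if (length(vals) < nval)
    stop_rg("rg_format_error", "data segment shorter than $TOT x $PAR")
  values <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)
  pnn <- vapply(seq_len(npar), function(i) {
    v <- gk(sprintf("$P%dN", i)); if (is.null(v)) sprintf("P%d", i) else v
  }, "")
  pns <- vapply(seq_len(npar), function(i) {
    v <- gk(sprintf("$P%dS", i)); if (is.null(v)) NA_character_ else v
  }, "")
  colnames(values) <- pnn

  if (!is.null(panel)) {
    if (is.null(tube_id))
      stop_rg("rg_config_error", "tube_id required when a panel is supplied")
    chmap <- panel_channels(panel, tube_id)
    if (npar != length(chmap))
      stop_rg("rg_config_error",
              "file declares %d parameters but tube %s expects %d",
              npar, tube_id, length(chmap))
    for (i in seq_len(npar)) {
      if (!is.na(pns[i]) && nzchar(pns[i]) &&
          !marker_eq(pns[i], chmap[[i]]) &&
          !normalize_marker(chmap[[i]]) %in% c("FSC", "SSC"))
        stop_rg("rg_config_error",
                "channel %s ($P%dS='%s') does not carry panel marker '%s'",
                pnn[i], i, pns[i], chmap[[i]])
    }
    markers <- stats::setNames(unname(chmap), pnn)
  } else {
    markers <- stats::setNames(ifelse(is.na(pns) | !nzchar(pns), pnn, pns), pnn)
    tube_id <- NA_integer_
  }

  meta <- list(keywords = kw)
  for (k in c("$SPILLOVER", "$COMP", "SPILL")) {
    if (!is.null(kw[[k]])) {
      sp <- parse_spillover(kw[[k]])
      if (!is.null(sp)) { meta$spillover <- sp; break }
    }
  }
  event_matrix(values, markers, metadata = meta, tube_id = tube_id)
}

# ---------------------------------------------------------------------------

#' Merge several cases from the same tube into one labelled event set
#'
#' Concatenates event matrices acquired with an identical marker layout,
#' preserving per-event case labels; this is the file-merging step used to
#' pool reference cases before projecting them in one radar dot-plot.
#'
#' @param cases list of `event_matrix` objects with identical channel/marker
#'   maps; each should carry a distinct `case_id` label column (a missing
#'   label is filled from the list name or position).
#' @return a single `event_matrix` with `case_id` labels.
#' @export
merge_cases <- function(cases) {
  if (!length(cases)) stop_rg("rg_input_error", "no cases to merge")
  ref <- cases[[1]]
  for (i in seq_along(cases)) {
    em <- cases[[i]]
    if (!identical(normalize_marker(unname(em$markers)),
                   normalize_marker(unname(ref$markers))))
      stop_rg("rg_merge_error",
              "case %d: marker map differs from case 1 (position %s)",
              i, paste(which(normalize_marker(unname(em$markers)) !=
                             normalize_marker(unname(ref$markers))),
                       collapse = ","))
  }
  lab_of <- function(em, i) {
    lab <- em$labels
    cid <- if (!is.null(lab) && "case_id" %in% names(lab)) lab$case_id
      else rep(if (!is.null(names(cases)) && nzchar(names(cases)[i]))
                 names(cases)[i] else sprintf("case%d", i), n_events(em))
    pop <- if (!is.null(lab) && "population" %in% names(lab)) lab$population
      else rep(NA_character_, n_events(em))
    data.frame(case_id = cid, population = pop, stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, lapply(cases, function(em) {
    v <- em$values; colnames(v) <- colnames(ref$values); v
  }))
  labels <- do.call(rbind, lapply(seq_along(cases),
                                  function(i) lab_of(cases[[i]], i)))
  event_matrix(values, ref$markers, labels = labels,
               metadata = ref$metadata, tube_id = ref$tube_id)
}
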