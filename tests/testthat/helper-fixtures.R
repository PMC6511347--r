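# Shared fixtures, built once per test run and cached.

.rg_cache <- new.env(parent = emptyenv())

rg_memo <- function(key, build) {
  if (!exists(key, envir = .rg_cache)) assign(key, build(), envir = .rg_cache)
  get(key, envir = .rg_cache)
}

# a scaled event matrix holding explicit coordinates on named axes
scaled_em <- function(values, markers = NULL) {
  values <- as.matrix(values)
  if (is.null(markers))
    markers <- stats::setNames(colnames(values), colnames(values))
  event_matrix(values, markers, metadata = list(scaled = TRUE))
}

# small raw event matrix with one fluorescence marker
raw_marker_em <- function(marker, values) {
  v <- cbind(values)
  colnames(v) <- "CH1"
  event_matrix(v, stats::setNames(marker, "CH1"))
}

# reference case list for template building: n_h hypergranular + n_m
# microgranular synthetic cases
make_ref_cases <- function(n_h, n_m, n_events, seed = 42L) {
  cohort <- simulate_cohort(n_h, n_m, 0, n_events = n_events, seed = seed)
  lapply(cohort$cases, function(sc)
    list(case_id = sc$case_id, type = sc$group, tubes = sc$tubes))
}

# small template shared across classify/cli tests (3 hyper + 1 micro, 3000
# events per tube)
tiny_template <- function() {
  rg_memo("tiny_template", function()
    build_template(make_ref_cases(3, 1, 3000, seed = 5L)))
}

# study-scale template for the acceptance suite: 6 hypergranular + 2
# microgranular reference cases, 10,000 events per tube, master seed 42
study_template <- function() {
  rg_memo("study_template", function()
    build_template(make_ref_cases(6, 2, 10000, seed = 42L)))
}

# held-out cases at study scale
heldout_cases <- function(group, seeds, n_events = 10000) {
  ph <- default_phenotypes()[[group]]
  lapply(seeds, function(s) simulate_case(ph, n_events = n_events, seed = s))
}

heldout_hyper <- function() {
  rg_memo("heldout_hyper", function()
    heldout_cases("hypergranular", 101:110))
}

heldout_micro <- function() {
  rg_memo("heldout_micro", function()
    heldout_cases("microgranular", 201:205))
}

# per-tube percentages of one case in the given gate type
type_gate_percents <- function(sc, tmpl) {
  r <- classify_case(sc$tubes, tmpl, case_id = sc$case_id)
  ty <- if (sc$group == "non_apl") "hypergranular" else sc$group
  r$tubes$percent_in_gate[r$tubes$gate == ty]
}
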