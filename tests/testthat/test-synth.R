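# Synthetic-cohort generator: determinism, allocation, phenotype fidelity.

test_that("identical spec and seed reproduce a case bit for bit", {
  ph <- default_phenotypes()$microgranular
  a <- simulate_case(ph, n_events = 2000, seed = 71)
  b <- simulate_case(ph, n_events = 2000, seed = 71)
  expect_identical(a$tubes[["2"]]$values, b$tubes[["2"]]$values)
  expect_identical(a$statuses, b$statuses)
  expect_identical(a$blast_fraction, b$blast_fraction)
  c2 <- simulate_case(ph, n_events = 2000, seed = 72)
  expect_false(identical(a$tubes[["2"]]$values, c2$tubes[["2"]]$values))
})

test_that("blast allocation is exact, not binomial", {
  sc <- simulate_case(default_phenotypes()$hypergranular,
                      n_events = 5000, seed = 73)
  expect_equal(sum(sc$tubes[["1"]]$labels$population == "blast"),
               round(sc$blast_fraction * 5000))
  # population labels are identical across tubes
  expect_identical(sc$tubes[["1"]]$labels$population,
                   sc$tubes[["4"]]$labels$population)
})

test_that("hard phenotype constraints hold in every case", {
  for (i in 1:10) {
    h <- simulate_case(default_phenotypes()$hypergranular,
                       n_events = 1000, seed = 500 + i)
    m <- simulate_case(default_phenotypes()$microgranular,
                       n_events = 1000, seed = 600 + i)
    expect_equal(unname(h$statuses[c("CD34", "HLA-DR", "CD117")]), c(0, 0, 1))
    expect_equal(unname(m$statuses[c("CD34", "CD123", "CD2", "CD117")]),
                 c(1, 1, 1, 1))
  }
})

test_that("marker status is consistent across tubes carrying the marker", {
  sc <- simulate_case(default_phenotypes()$microgranular,
                      n_events = 4000, seed = 77)
  # CD34-positive case: CD34 median of blasts clearly positive in tubes 2-4
  for (tid in c("2", "3", "4")) {
    em <- sc$tubes[[tid]]
    blast <- em$labels$population == "blast"
    cd34 <- radargate:::marker_values(em, "CD34")
    expect_gt(stats::median(cd34[blast]), 1000)
  }
})

test_that("hypergranular blasts carry high SSC; backgrounds sit canonically", {
  sc <- simulate_case(default_phenotypes()$hypergranular,
                      n_events = 5000, seed = 79)
  em <- sc$tubes[["1"]]
  pop <- em$labels$population
  ssc <- em$values[, "SSC-A"]
  cd45 <- em$values[, "PO-A"]
  expect_gt(median(ssc[pop == "blast"]), median(ssc[pop == "lymphocyte"]))
  expect_gt(median(ssc[pop == "blast"]), median(ssc[pop == "monocyte"]))
  expect_lt(median(cd45[pop == "blast"]), median(cd45[pop == "lymphocyte"]))
})

test_that("generated blasts pass the default CD45/SSC gate at >= 95%", {
  for (grp in c("hypergranular", "microgranular", "non_apl")) {
    sc <- simulate_case(default_phenotypes()[[grp]], n_events = 4000,
                        seed = 83)
    em <- sc$tubes[["1"]]
    inside <- apply_polygon_gate(em, default_blast_gate())
    blast <- em$labels$population == "blast"
    expect_gte(mean(inside[blast]), 0.95)
    # and the gated population is nearly pure blasts
    expect_gte(mean(blast[inside]), 0.98)
  }
})

test_that("case-level positivity frequencies match the phenotype table", {
  cohort <- simulate_cohort(0, 0, 200, n_events = 1000, seed = 11)
  mf <- cohort$manifest
  expect_equal(nrow(mf), 200)
  for (chk in list(c("status_HLADR", 0.58), c("status_CD14", 0.42),
                   c("status_CD123", 0.75), c("status_CD117", 1.0))) {
    p <- as.numeric(chk[2])
    phat <- mean(mf[[chk[1]]])
    se <- sqrt(max(p * (1 - p), 1e-9) / 200)
    expect_lt(abs(phat - p), 3 * se + 1e-9)
  }
})

test_that("cohort simulation is manifest-deterministic and handles emptiness", {
  a <- simulate_cohort(2, 1, 2, n_events = 1000, seed = 13)
  b <- simulate_cohort(2, 1, 2, n_events = 1000, seed = 13)
  expect_identical(a$manifest, b$manifest)
  expect_equal(nrow(a$manifest), 5)
  empty <- simulate_cohort(0, 0, 0, n_events = 1000, seed = 13)
  expect_equal(length(empty$cases), 0)
  expect_equal(nrow(empty$manifest), 0)
})

test_that("written FCS files carry panel markers in $PnS plus a truth sidecar", {
  sc <- simulate_case(default_phenotypes()$hypergranular,
                      n_events = 1000, seed = 87)
  d <- withr::local_tempdir()
  paths <- write_case_fcs(sc, d)
  expect_length(paths, 5)  # 4 tubes + sidecar
  em3 <- read_fcs(file.path(d, sprintf("%s_tube3.fcs", sc$case_id)))
  pns <- unname(em3$markers[3:10])
  expect_equal(normalize_marker(pns),
               normalize_marker(c("CD71", "CD117", "CD33", "CD56",
                                  "CD34", "CD38", "CD7", "CD45")))
  truth <- read.csv(file.path(d, sprintf("%s_truth.csv", sc$case_id)))
  expect_equal(nrow(truth), 1000)
  # round trip against the in-memory tube
  expect_lt(max(abs(em3$values - sc$tubes[["3"]]$values) /
                pmax(abs(sc$tubes[["3"]]$values), 1)), 1e-6)
})

test_that("a phenotype marker missing from the panel is a config error", {
  ph <- default_phenotypes()$hypergranular
  ph$markers$marker[1] <- "CD999"
  expect_error(simulate_case(ph, n_events = 1000, seed = 1),
               class = "rg_config_error")
})
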