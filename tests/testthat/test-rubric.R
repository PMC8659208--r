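# The seven-parameter rubric: lights, decision tree, ranking, reports.

train_panels <- function() read_panel_table(extdata("panels_training.csv"))
test_panels <- function() read_panel_table(extdata("panels_test.csv"))

published_labels <- function(path) {
  df <- mdtriage:::.read_delim_auto(path)
  stats::setNames(df$published_label, as.character(df$system))
}

test_that("the decision tree reproduces every published label", {
  for (f in c("panels_training.csv", "panels_test.csv")) {
    panels <- read_panel_table(extdata(f))
    labels <- published_labels(extdata(f))
    for (s in names(panels)) {
      expect_equal(predict_triage(panels[[s]])$label, unname(labels[s]),
                   label = paste0(f, " / ", s))
    }
  }
})

test_that("tier assignment follows the documented branch for edge systems", {
  panels <- train_panels()
  # coincident site/total sums with acceptable MM-GBSA -> Intermediate
  r <- predict_triage(panels[["4Z6I"]])
  expect_equal(r$label, "Intermediate")
  expect_true(any(grepl("coincident", r$rationale)))
  # dense fingerprint + strong total -> Excellent
  expect_equal(predict_triage(panels[["4UIW"]])$label, "Excellent")
  # positive site sum, weak totals -> Bad
  expect_equal(predict_triage(panels[["6V0S"]])$label, "Bad")
})

test_that("predictions are monotone in each energy argument", {
  th <- triage_thresholds()
  tier <- function(lbl) match(lbl, c("Excellent", "Good", "Intermediate",
                                     "Bad"))
  set.seed(21)
  for (i in 1:40) {
    p <- synth_panel(sample(c("Excellent", "Good", "Intermediate", "Bad"),
                            1), seed = i)
    base_tier <- tier(predict_triage(p, th)$label)
    for (field in c("mmgbsa", "site_energy", "total_energy")) {
      q <- p
      q[[field]] <- q[[field]] - runif(1, 0, 40)   # strictly better energy
      expect_lte(tier(predict_triage(q, th)$label), base_tier)
    }
  }
})

test_that("structural lights follow the published classification rules", {
  p <- train_panels()[["4UIW"]]
  th <- triage_thresholds()
  expect_equal(assign_lights(p, th)$rmsd, "good")          # 2.17 < 2.6
  p$rmsd_mean <- 2.98
  expect_equal(assign_lights(p, th)$rmsd, "intermediate")  # in (2.6, 3.0]
  p$rmsd_mean <- 4.05
  expect_equal(assign_lights(p, th)$rmsd, "bad")
  p$rg_width <- 1.15
  expect_equal(assign_lights(p, th)$rg, "bad")             # above 0.72
  p$rg_width <- 0.47
  expect_equal(assign_lights(p, th)$rg, "good")
  p$rmsf_violations <- 3L
  expect_equal(assign_lights(p, th)$rmsf, "bad")           # > 2 residues
  p$md_contacts <- 2L
  expect_equal(assign_lights(p, th)$md_contacts, "bad")    # below 3
  # energy gradient spans [0, 1] across the compared set
  panels <- train_panels()
  g <- vapply(panels, function(q)
    assign_lights(q, th, panels)$mmgbsa, numeric(1))
  expect_equal(unname(g[which.min(vapply(panels, `[[`, 0, "mmgbsa"))]), 1)
  expect_equal(unname(g[which.max(vapply(panels, `[[`, 0, "mmgbsa"))]), 0)
})

test_that("ranking orders tiers and breaks ties by MM-GBSA", {
  panels <- train_panels()
  results <- lapply(panels, predict_triage)
  ranked <- rank_triage(results)
  expect_equal(ranked$system[1], "4UIW")
  expect_setequal(ranked$system[ranked$label == "Bad"], c("4XY8", "6V0S"))
  # stable under permutation of the input
  ranked2 <- rank_triage(rev(results))
  expect_equal(ranked2$system, ranked$system)
  # tie-break: equal labels, more negative MM-GBSA first
  a <- predict_triage(synth_panel("Good", seed = 1, system = "a"))
  b <- predict_triage(synth_panel("Good", seed = 2, system = "b"))
  a$panel$mmgbsa <- -80; b$panel$mmgbsa <- -70
  expect_equal(rank_triage(list(b, a))$system, c("a", "b"))
  # a single system ranks itself
  expect_equal(nrow(rank_triage(list(a))), 1L)
})

test_that("build_panel validates mandatory fields and counts", {
  expect_error(build_panel("X", mmgbsa = NA, site_energy = -10,
                           total_energy = -20, md_contacts = 3,
                           rmsd_mean = 2, rmsf_violations = 0,
                           rg_width = 0.5), "mmgbsa")
  expect_error(build_panel("X", mmgbsa = -70, site_energy = -10,
                           total_energy = -20, md_contacts = -1,
                           rmsd_mean = 2, rmsf_violations = 0,
                           rg_width = 0.5), "non-negative")
  p <- build_panel("X", mmgbsa = -70, site_energy = -10, total_energy = -20,
                   md_contacts = 3, rmsd_mean = 2, rmsf_violations = 0,
                   rg_width = 0.5)
  expect_s3_class(p, "parameter_panel")
  expect_true(is.na(p$docking_score))
})

test_that("threshold invariants are enforced", {
  expect_error(triage_thresholds(rmsd_good = 3.1, rmsd_bad = 3.0), "rmsd")
  expect_error(triage_thresholds(mmgbsa_good = -60, mmgbsa_ok = -65),
               "mmgbsa")
  expect_error(triage_thresholds(total_strong = -20, total_ok = -30),
               "total")
})

test_that("reports render in all formats and JSON round-trips", {
  results <- lapply(train_panels(), predict_triage)
  md <- render_report(results, "markdown")
  expect_true(any(grepl("\\| 4UIW \\| Excellent \\|", md)))
  expect_equal(sum(grepl("^\\| \\d", md)), 8L)

  csv <- tempfile(fileext = ".csv")
  render_report(results, "delimited", csv)
  expect_equal(nrow(utils::read.csv(csv)), 8L)

  js <- tempfile(fileext = ".json")
  render_report(results, "json", js)
  back <- read_report_json(js)
  for (s in names(results)) {
    expect_equal(back[[s]]$label, results[[s]]$label)
    expect_equal(back[[s]]$panel$mmgbsa, results[[s]]$panel$mmgbsa)
  }
  expect_error(render_report(list(), "json"), "no results")
  expect_error(render_report(results, "xml"), "arg")
})
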