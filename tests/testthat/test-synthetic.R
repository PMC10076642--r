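# Synthetic report generator: validation, determinism, round trips,
# analytic cell expectations, and type-I control of the signal rule.

test_that("invalid configurations are rejected with the offending fields", {
  expect_error(synth_config(100), "seed")
  expect_error(synth_config(0, seed = 1), "n_reports")
  expect_error(
    synth_config(100, drugs = data.frame(active = "a", brand = "A",
                                         marginal = 1.2), seed = 1),
    "marginal")
  expect_error(
    synth_config(100, events = data.frame(pt = "X", prob = 0), seed = 1),
    "events\\$prob")
  expect_error(
    synth_config(100, planted = data.frame(active = "secukinumab",
                                           pt = "Colitis", odds_ratio = -2),
                 seed = 1),
    "odds_ratio")
  expect_error(
    synth_config(100, planted = data.frame(active = c("secukinumab",
                                                      "secukinumab"),
                                           pt = c("Colitis", "Colitis"),
                                           odds_ratio = c(2, 3)), seed = 1),
    "at most once")
  expect_error(
    synth_config(100, planted = data.frame(active = "infliximab",
                                           pt = "Colitis", odds_ratio = 2),
                 seed = 1),
    "planted\\$active")
})

test_that("the same seed yields byte-identical files", {
  cfg <- synth_config(n_reports = 500, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_reports(cfg, dir = d1)
  generate_reports(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # and a different seed does not
  cfg2 <- synth_config(n_reports = 500, seed = 8)
  d3 <- withr::local_tempdir()
  generate_reports(cfg2, dir = d3)
  expect_false(identical(readLines(file.path(d1, "DEMO.txt")),
                         readLines(file.path(d3, "DEMO.txt"))))
})

test_that("written files round-trip through ingestion field for field", {
  cfg <- synth_config(n_reports = 800, seed = 31)
  dir <- withr::local_tempdir()
  gen <- generate_reports(cfg, dir = dir)
  p <- attr(gen, "paths")
  back <- suppressMessages(read_quarter_files(p["demo"], p["drug"],
                                              p["reac"], p["outc"],
                                              p["indi"]))
  expect_equal(n_reports(back), 800L)
  norm <- function(dt, keys) {
    dt <- as.data.frame(dt)[, keys]
    dt[do.call(order, dt), , drop = FALSE]
  }
  expect_equal(norm(back$demo, names(gen$demo)), norm(gen$demo, names(gen$demo)),
               ignore_attr = TRUE)
  cols <- c("primaryid", "drug_seq", "role_cod", "drugname", "indi_pt")
  expect_equal(norm(back$drugs, cols), norm(gen$drugs, cols),
               ignore_attr = TRUE)
  expect_equal(norm(back$reactions, c("primaryid", "pt")),
               norm(gen$reactions, c("primaryid", "pt")), ignore_attr = TRUE)
  expect_equal(norm(back$outcomes, c("primaryid", "outc_cod")),
               norm(gen$outcomes, c("primaryid", "outc_cod")),
               ignore_attr = TRUE)
  # every generated report carries at least one reaction (filler PT)
  expect_true(all(back$demo$primaryid %in% back$reactions$primaryid))
})

test_that("forcing two versions per case still yields n unique cases", {
  cfg <- synth_config(n_reports = 400, versions_per_case = c(0, 1), seed = 13)
  dir <- withr::local_tempdir()
  gen <- generate_reports(cfg, dir = dir)
  expect_equal(n_reports(gen), 800L)  # two versions of each case on disk
  p <- attr(gen, "paths")
  back <- suppressMessages(read_quarter_files(p["demo"], p["drug"],
                                              p["reac"], p["outc"],
                                              p["indi"]))
  dedup <- suppressMessages(deduplicate(back))
  expect_equal(n_reports(dedup), 400L)
  expect_true(all(dedup$demo$caseversion == 2L))
})

test_that("empirical contingency cells match the analytic expectation", {
  cfg <- synth_config(
    n_reports = 100000,
    drugs = data.frame(active = "secukinumab", brand = "Cosentyx",
                       marginal = 0.2),
    events = data.frame(pt = c("Colitis", "Headache"), prob = c(0.01, 0.05)),
    planted = data.frame(active = "secukinumab", pt = "Colitis",
                         odds_ratio = 2),
    seed = 101
  )
  ex <- expected_contingency(cfg, "secukinumab", "Colitis")
  # planted occurrence probability on the odds scale
  p1 <- (2 * 0.01 / 0.99) / (1 + 2 * 0.01 / 0.99)
  expect_equal(unname(ex["a"]), 1e5 * 0.2 * p1, tolerance = 1e-12)

  rep <- generate_reports(cfg)
  tab <- build_contingency(rep, "secukinumab", il17_dictionary(), "Colitis")
  got <- c(a = tab$a, b = tab$b, c = tab$c, d = tab$d)
  tol <- 4 * sqrt(ex)  # ~binomial sd bound per cell
  expect_true(all(abs(got - ex) <= tol),
              label = paste("cells", paste(got, collapse = "/"),
                            "vs expected", paste(round(ex), collapse = "/")))
  expect_error(expected_contingency(cfg, "secukinumab", "Nausea"),
               "unknown event")
})

test_that("under theta = 1 the signal-flag rate respects the nominal level", {
  # all-background model: any flag is a false positive of the one-sided
  # 2.5% rule (plus the >=3-case gate, which only lowers the rate)
  n_rep <- 200
  flags <- 0L
  pairs <- 0L
  dict <- il17_dictionary()
  for (i in seq_len(n_rep)) {
    cfg <- synth_config(
      n_reports = 4000,
      events = data.frame(pt = c("Colitis", "Crohn's disease", "Nausea"),
                          prob = c(0.02, 0.02, 0.02)),
      seed = 5000 + i
    )
    rep <- generate_reports(cfg)
    for (act in c("secukinumab", "ixekizumab")) {
      for (pt in c("Colitis", "Crohn's disease", "Nausea")) {
        r <- compute_ror(build_contingency(rep, act, dict, pt))
        flags <- flags + as.integer(r$signal)
        pairs <- pairs + 1L
      }
    }
  }
  rate <- flags / pairs
  slack <- 3 * sqrt(0.025 * 0.975 / pairs)
  expect_lte(rate, 0.025 + slack)
})
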