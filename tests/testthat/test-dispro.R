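# Reporting odds ratio machinery: Woolf intervals, signal rule,
# contingency construction, proportions, and recovery of planted effects.

test_that("ROR and Woolf CI match independently computed values", {
  # frozen from a direct evaluation of (a*d)/(b*c) and
  # exp(log ROR +- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))
  r <- compute_ror(contingency_table(20, 80, 10, 90))
  expect_equal(r$ror, 2.25, tolerance = 1e-12)
  expect_equal(r$ci_low, 0.994295, tolerance = 1e-6)
  expect_equal(r$ci_high, 5.091548, tolerance = 1e-6)
  expect_equal(r$n_cases, 20L)

  # balanced table: ROR 1, CI symmetric about 1 on the log scale
  b <- compute_ror(contingency_table(10, 10, 10, 10))
  expect_equal(b$ror, 1)
  expect_equal(log(b$ci_low), -log(b$ci_high), tolerance = 1e-12)
})

test_that("ROR equals the unconditional logistic-regression odds ratio", {
  # independent route: saturated binomial GLM on the same 2x2
  set.seed(71)
  for (i in 1:20) {
    cells <- sample(5:400, 4)
    r <- compute_ror(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    dat <- data.frame(event = c(cells[1], cells[3]),
                      noevent = c(cells[2], cells[4]),
                      exposed = c(1, 0))
    m <- stats::glm(cbind(event, noevent) ~ exposed, family = binomial,
                    data = dat)
    expect_equal(r$ror, unname(exp(coef(m)["exposed"])), tolerance = 1e-8)
    se <- sqrt(diag(stats::vcov(m)))["exposed"]
    expect_equal(r$ci_low, unname(exp(coef(m)["exposed"] - 1.96 * se)),
                 tolerance = 1e-3)
  }
})

test_that("zero cells yield NA without continuity correction", {
  for (tab in list(contingency_table(0, 10, 5, 100),
                   contingency_table(5, 0, 5, 100),
                   contingency_table(5, 10, 0, 100),
                   contingency_table(5, 10, 5, 0))) {
    r <- compute_ror(tab)
    expect_true(is.na(r$ror) && is.na(r$ci_low) && is.na(r$ci_high))
    expect_false(r$signal)
  }
  expect_error(contingency_table(-1, 1, 1, 1), "non-negative")
})

test_that("swapping exposure rows inverts the ROR; CI contains the point", {
  set.seed(42)
  for (i in 1:50) {
    cells <- sample(1:500, 4)
    r1 <- compute_ror(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    r2 <- compute_ror(contingency_table(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(r1$ror * r2$ror, 1, tolerance = 1e-10)
    expect_true(r1$ci_low <= r1$ror && r1$ror <= r1$ci_high)
    # ROR = 1 exactly when a*d = b*c
    expect_equal(r1$ror == 1, cells[1] * cells[4] == cells[2] * cells[3])
  }
})

test_that("log-scale CI width shrinks as counts scale up", {
  widths <- sapply(c(1, 2, 5, 10), function(k) {
    r <- compute_ror(contingency_table(20 * k, 80 * k, 10 * k, 90 * k))
    log(r$ci_high) - log(r$ci_low)
  })
  expect_true(all(diff(widths) < 0))
})

test_that("the signal rule needs CI lower bound > 1 and at least 3 cases", {
  mk <- function(ci_low, n) structure(list(ci_low = ci_low, n_cases = n),
                                      class = "ror_result")
  expect_false(flag_signal(mk(0.48, 3)))    # CI crosses 1
  expect_true(flag_signal(mk(1.96, 611)))   # strong signal
  expect_false(flag_signal(mk(1.01, 2)))    # too few cases
  expect_true(flag_signal(mk(1.0000001, 3)))
  expect_false(flag_signal(mk(1, 3)))       # bound must exceed 1
  expect_false(flag_signal(mk(NA_real_, 10)))
})

test_that("proportions of reports reproduce the published arithmetic", {
  # half-up is the default display convention
  expect_equal(proportion_of_reports(611, 44688), 1.37)
  # the published SEC IBD share is truncated, not rounded
  expect_equal(proportion_of_reports(611, 44688, mode = "truncate"), 1.36)
  expect_equal(proportion_of_reports(160, 24406), 0.66)
  expect_equal(proportion_of_reports(3, 1796), 0.17)
  expect_equal(proportion_of_reports(314, 44688), 0.70)
  expect_equal(proportion_of_reports(73, 24406), 0.30)
  expect_equal(proportion_of_reports(0, 100), 0)
  expect_true(is.na(proportion_of_reports(5, 0)))
})

test_that("contingency construction matches exhaustive enumeration", {
  d <- il17_dictionary()
  groups <- il17_event_groups()
  for (seed in c(3, 17, 29)) {
    rep <- random_reports(150, seed = seed)
    for (pts in list(groups$IBD$pts, "Colitis", "Crohn's disease")) {
      got <- build_contingency(rep, "secukinumab", d, pts)
      want <- brute_contingency(rep, "secukinumab", d, pts)
      expect_equal(unlist(unclass(got))[c("a", "b", "c", "d")], want,
                   ignore_attr = TRUE)
    }
  }
})

test_that("contingency margins tie out and empty PT sets are rejected", {
  rep <- random_reports(80, seed = 5)
  d <- il17_dictionary()
  tab <- build_contingency(rep, "secukinumab", d, "Colitis")
  pairs_total <- nrow(unique(data.frame(
    primaryid = rep$reactions$primaryid,
    pt = tolower(trimws(rep$reactions$pt)))))
  expect_equal(tab$a + tab$b + tab$c + tab$d, pairs_total)
  expect_error(build_contingency(rep, "secukinumab", d, character()),
               "empty PT set")
  # no exposed reports: a = b = 0
  tab0 <- build_contingency(rep, "brodalumab", d, "Colitis")
  expect_equal(tab0$a + tab0$b, 0L)
})

test_that("group totals equal the sum of their per-PT counts", {
  # on the shipped published counts: SEC IBD 233+196+182 = 611,
  # SEC colitis column sums to 314
  counts <- faers_reference_counts()
  sec_ibd <- counts[drug == "secukinumab" & group == "IBD"]
  expect_equal(sum(sec_ibd$n_events), 611L)
  sec_col <- counts[drug == "secukinumab" & group == "colitis"]
  expect_equal(sum(sec_col$n_events), 314L)
  expect_equal(sum(counts[drug == "ixekizumab" & group == "IBD", n_events]),
               160L)

  # and structurally, on a synthetic collection
  cfg <- synth_config(n_reports = 3000, seed = 99)
  rep <- generate_reports(cfg)
  res <- run_disproportionality(rep, il17_dictionary())
  for (g in c("IBD", "colitis")) {
    for (dg in unique(res$drug)) {
      sub <- res[res$drug == dg & res$group == g, ]
      expect_equal(sub$count[sub$pt == "Total events of interest"],
                   sum(sub$count[sub$pt != "Total events of interest"]))
    }
  }
})

test_that("a planted association is the only flagged drug-group pair", {
  cfg <- synth_config(
    n_reports = 30000,
    planted = data.frame(active = "secukinumab",
                         pt = "Inflammatory bowel disease",
                         odds_ratio = 4),
    seed = 2024
  )
  rep <- generate_reports(cfg)
  res <- run_disproportionality(suppressMessages(deduplicate(rep)),
                                il17_dictionary())
  totals <- res[res$pt == "Total events of interest", ]
  flagged <- totals[totals$signal == TRUE, ]
  expect_equal(flagged$drug, "secukinumab")
  expect_equal(flagged$group, "IBD")
})

test_that("planted odds ratios are recovered across replicates with
           nominal CI coverage", {
  # 500 in-memory replicates per planted value, n = 20,000 reports each;
  # mean log-estimate within 3 Monte-Carlo SEs of the planted log value,
  # empirical 95% CI coverage within +-3% of nominal
  for (theta in c(1, 1.5, 2.13, 2.79)) {
    reps <- recovery_run(theta, n_replicates = 500, n_reports = 20000,
                         seed = round(1000 * theta), via_files = FALSE)
    mlog <- mean(log(reps$ror))
    mc_se <- sd(log(reps$ror)) / sqrt(nrow(reps))
    expect_lt(abs(mlog - log(theta)), 3 * mc_se)
    expect_lt(abs(mean(reps$covered) - 0.95), 0.03)
  }
})
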