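mk_labels <- function(ids, case_ids, smq = "cardiac failure") {
  tibble::tibble(report_id = ids, smq_name = smq, is_case = ids %in% case_ids)
}

test_that("contingency tables partition the anticancer set by exposure and case", {
  ids <- c("R1", "R2", "R3", "R4")
  lab <- mk_labels(ids, c("R1", "R3"))
  ex <- fake_exposures(ids, tki = list("nilotinib", "nilotinib", NULL, NULL))
  t <- build_table(lab, ex, "cardiac failure", "nilotinib")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))

  # a report with the index TKI and another anticancer drug counts once,
  # in the index margin (tki_set drives the split; all are anticancer)
  ex2 <- fake_exposures(ids, tki = list(c("nilotinib"), "nilotinib", NULL, NULL))
  t2 <- build_table(lab, ex2, "cardiac failure", "nilotinib")
  expect_equal(t2$a + t2$b + t2$c + t2$d, 4)

  # comparator may contain other TKIs for a single-drug analysis
  ex3 <- fake_exposures(ids, tki = list("nilotinib", "dasatinib", NULL, NULL))
  t3 <- build_table(lab, ex3, "cardiac failure", "nilotinib")
  expect_equal(c(t3$a, t3$b), c(1, 0))
  expect_equal(c(t3$c, t3$d), c(1, 2))
  # ... but not for the class analysis
  t4 <- build_table(lab, ex3, "cardiac failure", "tki_class")
  expect_equal(c(t4$a, t4$b, t4$c, t4$d), c(1, 1, 1, 1))

  # no comparator: error
  ex5 <- fake_exposures(ids, tki = list("nilotinib", "nilotinib",
                                        "nilotinib", "nilotinib"))
  expect_error(build_table(lab, ex5, "cardiac failure", "nilotinib"),
               "comparator")
})

test_that("crude ROR follows the Woolf closed form", {
  # symmetric table: ROR 1, interval symmetric about 1 on the log scale
  r <- crude_ror(list(a = 10, b = 10, c = 10, d = 10))
  expect_equal(r$ror, 1)
  expect_equal(log(r$ci_high), -log(r$ci_low), tolerance = 1e-12)

  # hand-evaluated closed form, cross-checked against the ML oracle
  r2 <- crude_ror(list(a = 10, b = 90, c = 100, d = 9900))
  expect_equal(r2$ror, 11)
  expect_equal(r2$ci_low, 5.55951492889, tolerance = 1e-9)
  expect_equal(r2$ci_high, 21.7644887274, tolerance = 1e-9)
  orc <- oracle_or(10, 90, 100, 9900)
  expect_equal(r2$ror, unname(orc["ror"]), tolerance = 1e-9)

  # zero cells in b, c or d: not computed, no continuity correction
  r3 <- crude_ror(list(a = 5, b = 0, c = 10, d = 10))
  expect_true(is.na(r3$ror))
  expect_match(r3$status, "zero cell")

  # eligibility rule
  expect_false(crude_ror(list(a = 2, b = 5, c = 5, d = 5))$eligible)
})

test_that("the published margins give a torsade class crude ROR near 9.1", {
  # index/comparator margins reconstructed from the published case and
  # report totals for torsade de pointes/QT prolongation under TKI-class
  # exposure
  ref <- tki_cv_reference_counts()
  a <- unname(ref$smq_of_tki_cases["torsade de pointes/QT prolongation"])
  c_ <- unname(ref$smq_of_other_anticancer_cases["torsade de pointes/QT prolongation"])
  n_tki <- ref$n_tki_cases + ref$n_tki_noncases
  n_comp <- ref$n_anticancer_retained - n_tki
  r <- crude_ror(list(a = a, b = n_tki - a, c = c_, d = n_comp - c_))
  expect_equal(round_half_up(r$ror, 1), 9.1)
})

test_that("crude ROR obeys swap-reciprocity and monotonicity", {
  set.seed(71)
  for (k in 1:25) {
    t <- as.list(setNames(sample(3:400, 4, TRUE), c("a", "b", "c", "d")))
    r <- crude_ror(t)
    swapped <- crude_ror(list(a = t$c, b = t$d, c = t$a, d = t$b))
    expect_equal(swapped$ror, 1 / r$ror, tolerance = 1e-12)
    bigger <- crude_ror(list(a = t$a + 5, b = t$b, c = t$c, d = t$d))
    expect_gt(bigger$ror, r$ror)
  }
})

test_that("adjustment changes nothing when covariates are independent of exposure and outcome", {
  # balanced factorial design: covariate distribution identical across the
  # four exposure-outcome margins, so the exposure coefficient must equal
  # the crude log-odds ratio
  cells <- expand.grid(exposed = c(TRUE, FALSE), case = c(TRUE, FALSE),
                       age = c(40, 70), sex = c("female", "male"),
                       stringsAsFactors = FALSE)
  base <- c(TT = 12, TF = 40, FT = 25, FF = 160)
  cells$n <- base[paste0(ifelse(cells$exposed, "T", "F"),
                         ifelse(cells$case, "T", "F"))] *
    ifelse(cells$age == 40, 1, 2) * ifelse(cells$sex == "female", 1, 3)
  rows <- cells[rep(seq_len(nrow(cells)), cells$n), ]
  ids <- sprintf("R%05d", seq_len(nrow(rows)))
  reports <- fake_reports(nrow(rows), report_id = ids,
                          age_years = rows$age, sex = rows$sex)
  st <- fake_store(reports)
  lab <- mk_labels(ids, ids[rows$case])
  ex <- fake_exposures(ids, tki = lapply(rows$exposed, function(e)
    if (e) "nilotinib" else NULL))
  cr <- crude_ror(build_table(lab, ex, "cardiac failure", "nilotinib"))
  ad <- adjusted_ror(st, lab, ex, "cardiac failure", "nilotinib")
  expect_equal(ad$adj_ror, cr$ror, tolerance = 1e-6)
  expect_equal(ad$adj_ci_low, cr$ci_low, tolerance = 1e-6)
  expect_equal(ad$adj_ci_high, cr$ci_high, tolerance = 1e-6)
})

test_that("a null exposure effect gives an adjusted interval containing 1", {
  set.seed(42)
  n <- 4000
  ids <- sprintf("R%05d", seq_len(n))
  exposed <- runif(n) < 0.3
  case <- runif(n) < 0.1  # independent of exposure
  reports <- fake_reports(n, report_id = ids,
                          age_years = sample(c(30, 60, 80), n, TRUE),
                          sex = sample(c("female", "male"), n, TRUE))
  lab <- mk_labels(ids, ids[case])
  ex <- fake_exposures(ids, tki = lapply(exposed, function(e)
    if (e) "imatinib" else NULL))
  ad <- adjusted_ror(fake_store(reports), lab, ex, "cardiac failure", "imatinib")
  expect_lt(ad$adj_ci_low, 1)
  expect_gt(ad$adj_ci_high, 1)
})

test_that("separation and small case counts yield diagnostics, not estimates", {
  ids <- sprintf("R%02d", 1:40)
  case <- c(rep(TRUE, 10), rep(FALSE, 30))
  exposed <- case  # perfect separation
  reports <- fake_reports(40, report_id = ids)
  lab <- mk_labels(ids, ids[case])
  ex <- fake_exposures(ids, tki = lapply(exposed, function(e)
    if (e) "ponatinib" else NULL))
  ad <- adjusted_ror(fake_store(reports), lab, ex, "cardiac failure", "ponatinib")
  expect_true(is.na(ad$adj_ror))
  expect_match(ad$status, "not computed")

  ad2 <- adjusted_ror(fake_store(reports), mk_labels(ids, ids[1:2]),
                      ex, "cardiac failure", "ponatinib")
  expect_match(ad2$status, "fewer than 3")
})

test_that("the full screen emits eligible pairs and lists the rest", {
  cfg <- scenario_config(
    n_reports = 12000, seed = 31,
    drug_menu = default_drug_menu(tki_share = 0.5),
    true_or = c("nilotinib|torsade de pointes/QT prolongation" = 8),
    nonserious_rate = 0.05, dup_rate = 0.02, followup_rate = 0.02,
    aberrant_rate = 0.01)
  g <- generate_faers(cfg)
  pl <- run_pipeline(g, cfg)
  scr <- screen_all(pl$store, pl$exposures,
                    smq_catalogue(cfg$smq_menu), labels = pl$labels)
  # 5 drugs x 8 queries plus 8 class rows, partitioned by eligibility
  expect_equal(nrow(scr$results) + nrow(scr$ineligible), 48)
  expect_true(all(scr$results$a >= 3))
  if (nrow(scr$ineligible)) expect_true(all(scr$ineligible$n_cases < 3))
  # SDR flag definition
  ok <- !is.na(scr$results$adj_ci_low)
  expect_equal(scr$results$sdr[ok], scr$results$adj_ci_low[ok] > 1)
  # the planted signal is found
  hit <- scr$results[scr$results$drug == "nilotinib" &
                       scr$results$smq_name ==
                       "torsade de pointes/QT prolongation", ]
  expect_true(hit$sdr)
})
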