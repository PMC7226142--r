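test_that("generation is deterministic under a fixed seed", {
  cfg <- scenario_config(n_reports = 600, seed = 77)
  g1 <- generate_faers(cfg)
  g2 <- generate_faers(cfg)
  for (nm in c("demo", "drug", "reac", "outc", "indi", "ther"))
    expect_identical(g1$tables[[nm]], g2$tables[[nm]])
  expect_identical(g1$truth$counts, g2$truth$counts)

  g3 <- generate_faers(scenario_config(n_reports = 600, seed = 78))
  expect_false(identical(g1$tables$demo, g3$tables$demo))
})

test_that("with no clones or date swaps the funnel removes exactly the nonserious reports", {
  cfg <- scenario_config(n_reports = 1200, seed = 5, dup_rate = 0,
                         followup_rate = 0, aberrant_rate = 0,
                         nonserious_rate = 0.2)
  g <- generate_faers(cfg)
  pl <- run_pipeline(g, cfg)
  expect_equal(pl$funnel$n_nonserious_removed,
               sum(!g$truth$report_flags$serious))
  expect_equal(pl$funnel$n_duplicates_removed, 0)
  expect_equal(pl$funnel$n_aberrant_removed, 0)
})

test_that("ground-truth contingency counts equal the pipeline's tables exactly", {
  for (seed in c(9, 33)) {
    cfg <- scenario_config(
      n_reports = 4000, seed = seed,
      true_or = c("dasatinib|cardiac failure" = 4))
    g <- generate_faers(cfg)
    pl <- run_pipeline(g, cfg)
    # retained sets agree report by report
    expect_setequal(pl$store$reports$report_id, g$truth$retained_ids)
    # exposure flags equal ground truth exactly
    m <- dplyr::inner_join(pl$exposures, g$truth$exposure, by = "report_id")
    expect_equal(nrow(m), nrow(g$truth$exposure))
    expect_equal(m$n_tki > 0, m$is_tki)
    one_tki <- m[m$is_tki, ]
    expect_true(all(mapply(function(s, d) identical(s, d),
                           one_tki$tki_set, as.list(one_tki$drug_inn))))
    # all 48 drug/class x query tables match
    for (k in seq_len(nrow(g$truth$counts))) {
      r <- g$truth$counts[k, ]
      t <- build_table(pl$labels, pl$exposures, r$smq_name, r$drug)
      expect_equal(c(t$a, t$b, t$c, t$d), c(r$a, r$b, r$c, r$d),
                   label = paste(r$drug, r$smq_name, "seed", seed))
    }
  }
})

test_that("name-mapping coverage tracks the designed misspelling rate", {
  # without the rescue, misspelled names stay unresolved, so expected
  # coverage is 1 - misspell_rate
  cfg <- scenario_config(n_reports = 6000, seed = 19, misspell_rate = 0.10)
  g <- generate_faers(cfg)
  st <- resolve_drugs(assemble_reports(g$tables), archive_from_config(cfg),
                      fuzzy = FALSE)
  cov <- mapping_coverage(st)
  expect_lt(abs(cov$coverage - 0.9), 0.02)
  # the rescue recovers them all
  st2 <- resolve_drugs(assemble_reports(g$tables), archive_from_config(cfg),
                       fuzzy = TRUE)
  expect_equal(mapping_coverage(st2)$coverage, 1.0)
})

test_that("the published-margin preset reproduces the study's expected shares", {
  cfg <- paper_margin_preset(n_reports = 100000, seed = 14)

  # design expectations implied by the configuration: per-drug case
  # probability from the planted odds ratios and baselines, then the
  # case-mix across TKIs
  menu <- cfg$drug_menu[cfg$drug_menu$is_tki, ]
  smqs <- names(cfg$smq_baseline)
  p_any <- vapply(menu$inn, function(d) {
    or <- unname(cfg$true_or[paste(d, smqs, sep = "|")])
    or[is.na(or)] <- 1
    p <- stats::plogis(stats::qlogis(unname(cfg$smq_baseline)) + log(or))
    1 - prod(1 - p)
  }, numeric(1))
  exp_share <- 100 * menu$share * p_any / sum(menu$share * p_any)
  names(exp_share) <- menu$inn
  expect_lt(abs(exp_share[["nilotinib"]] - 59.0), 2)
  expect_lt(abs(exp_share[["dasatinib"]] - 21.2), 2)
  # expected male share of TKI cases is the configured marginal
  expect_equal(100 * cfg$sex_probs[2], 52.9)

  # realized shares at n = 100,000: marginals with large denominators sit
  # within 2 points of the design; shares estimated on the few hundred TKI
  # cases are checked against three binomial standard errors
  g <- generate_faers(cfg)
  flags <- g$truth$report_flags
  any_cv <- g$truth$cases |>
    dplyr::group_by(.data$i) |>
    dplyr::summarise(any_cv = any(.data$is_case), .groups = "drop")
  m <- tibble::tibble(i = seq_len(cfg$n_reports), tki = flags$is_tki,
                      drug = flags$drug_inn,
                      retained = !is.na(flags$retained_as)) |>
    dplyr::inner_join(any_cv, by = "i")
  m <- m[m$retained, ]
  expect_lt(abs(100 * mean(m$tki[m$any_cv]) - 6.1), 2)
  expect_lt(abs(100 * mean(g$tables$demo$sex == "M") - 52.9), 2)

  tk <- m[m$any_cv & m$tki, ]
  shares <- 100 * table(tk$drug) / nrow(tk)
  band <- function(p) 300 * sqrt(p / 100 * (1 - p / 100) / nrow(tk))
  expect_lt(abs(shares[["nilotinib"]] - exp_share[["nilotinib"]]),
            band(exp_share[["nilotinib"]]))
  expect_lt(abs(shares[["dasatinib"]] - exp_share[["dasatinib"]]),
            band(exp_share[["dasatinib"]]))
})

test_that("scenario validation rejects impossible configurations", {
  expect_error(scenario_config(dup_rate = 1.2), "rates")
  expect_error(scenario_config(true_or = c("imatinib|hypertension" = -1)),
               "positive")
  expect_error(scenario_config(sex_probs = c(0.9, 0.3, 0.3)), "sum to 1")
  bad_base <- replace(default_smq_baseline(), "hypertension", 0)
  expect_error(scenario_config(smq_baseline = bad_base), "strictly")
})
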