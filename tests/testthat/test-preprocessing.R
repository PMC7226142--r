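test_that("seriousness filter retains exactly the serious reports", {
  reports <- fake_reports(10, serious = c(rep(TRUE, 7), rep(FALSE, 3)))
  st <- fake_store(reports)
  out <- filter_serious(st)
  expect_equal(nrow(out$store$reports), 7)
  expect_equal(out$n_removed, 3)
  expect_true(all(out$store$reports$serious))

  # all serious: identity
  st2 <- fake_store(fake_reports(5))
  out2 <- filter_serious(st2)
  expect_equal(out2$n_removed, 0)
  expect_identical(out2$store$reports, st2$reports)
})

test_that("deduplication keeps the last follow-up version of a case", {
  reports <- fake_reports(3, report_id = c("R1", "R2", "R3"),
                          case_id = "CASE", version_seq = c(1L, 2L, 3L))
  out <- deduplicate(fake_store(reports))
  expect_equal(out$store$reports$report_id, "R3")
  expect_equal(out$n_removed_versions, 2)
  expect_equal(out$n_removed_key, 0)
})

test_that("distinct cases identical on the five-field key collapse to one report", {
  mk <- function(ids, country = "US", onset = as.Date("2015-04-01")) {
    reports <- fake_reports(length(ids), report_id = ids,
                            case_id = paste0("C", ids),
                            country = country)
    events <- fake_events(rep(ids, each = 1), rep("dizziness rotatory", length(ids)),
                          onset_date = onset, onset_precision = "day")
    fake_store(reports, events = events)
  }
  out <- deduplicate(mk(c("R2", "R1")))
  expect_equal(out$store$reports$report_id, "R1")  # smallest id kept
  expect_equal(out$n_removed_key, 1)

  # differing only in country: both retained
  out2 <- deduplicate(mk(c("R1", "R2"), country = c("US", "FR")))
  expect_equal(out2$n_removed, 0)

  # missing onset dates compare equal only to missing
  st3 <- mk(c("R1", "R2"))
  st3$events$onset_date[1] <- NA
  st3$events$onset_precision[1] <- "missing"
  expect_equal(deduplicate(st3)$n_removed, 0)
})

test_that("aberrant exclusion needs full-precision evidence and strict inequality", {
  mk <- function(start, start_prec = "day", onset = as.Date("2018-05-01"),
                 onset_prec = "day", role = "primary suspect") {
    reports <- fake_reports(1, report_id = "R1")
    drugs <- fake_drugs("R1", "gleevec", role = role,
                        start_date = start, start_precision = start_prec)
    events <- fake_events("R1", "term x", onset_date = onset,
                          onset_precision = onset_prec)
    fake_store(reports, drugs, events)
  }
  # start after event: removed
  expect_equal(remove_aberrant(mk(as.Date("2018-06-01")))$n_removed, 1)
  # start equal to event date: retained ("after" is strict)
  expect_equal(remove_aberrant(mk(as.Date("2018-05-01")))$n_removed, 0)
  # missing or partial start: retained
  expect_equal(remove_aberrant(mk(as.Date(NA), start_prec = "missing"))$n_removed, 0)
  expect_equal(remove_aberrant(mk(as.Date("2018-06-01"),
                                  start_prec = "month"))$n_removed, 0)
  # partial onset: retained
  expect_equal(remove_aberrant(mk(as.Date("2018-06-01"),
                                  onset_prec = "month"))$n_removed, 0)
  # concomitant drugs do not make a report aberrant
  expect_equal(remove_aberrant(mk(as.Date("2018-06-01"),
                                  role = "concomitant"))$n_removed, 0)
  # one suspect drug started before the event rescues the report
  st <- mk(as.Date("2018-06-01"))
  st$drugs <- dplyr::bind_rows(
    st$drugs,
    fake_drugs("R1", "TASIGNA", start_date = as.Date("2018-01-01"),
               start_precision = "day"))
  expect_equal(remove_aberrant(st)$n_removed, 0)
})

test_that("the funnel is order-fixed, additive, and idempotent", {
  g <- generate_faers(scenario_config(n_reports = 1500, seed = 21))
  st <- resolve_drugs(assemble_reports(g$tables), test_archive(), fuzzy = TRUE)
  pp <- preprocess_reports(st)
  fr <- pp$funnel
  expect_equal(fr$n_retained,
               fr$n_input - fr$n_nonserious_removed -
                 fr$n_duplicates_removed - fr$n_aberrant_removed)
  expect_equal(fr$n_retained, nrow(pp$store$reports))
  # each stage is idempotent: a second pass removes nothing
  pp2 <- preprocess_reports(pp$store)
  expect_equal(pp2$funnel$n_nonserious_removed, 0)
  expect_equal(pp2$funnel$n_duplicates_removed, 0)
  expect_equal(pp2$funnel$n_aberrant_removed, 0)
})

test_that("funnel bookkeeping rejects impossible counts", {
  expect_error(funnel_report(10, 8, 8, 0), "nonnegative")
  fr <- funnel_report(10, 2, 3, 1)
  expect_equal(fr$n_retained, 4)
})
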