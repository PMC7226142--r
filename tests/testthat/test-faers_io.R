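test_that("partial dates parse with explicit precision and reject impossible values", {
  res <- parse_partial_date(c("20180415", "201804", "2018", "", NA))
  expect_equal(res$date[1], as.Date("2018-04-15"))
  expect_equal(res$precision, c("day", "month", "year", "missing", "missing"))
  expect_equal(res$date[2], as.Date("2018-04-01"))  # anchored, month precision

  expect_warning(bad <- parse_partial_date(c("20181341", "20180230", "abc", "123")),
                 "could not be parsed")
  expect_true(all(bad$precision == "missing"))
  expect_true(all(is.na(bad$date)))
})

test_that("table sets read from $-delimited files, dropping keyless and orphan rows", {
  dir <- withr::local_tempdir()
  hdr <- faers_dialect()
  write1 <- function(nm, rows) {
    writeLines(c(paste(hdr[[nm]], collapse = "$"), rows),
               file.path(dir, paste0(nm, ".txt")))
  }
  write1("demo", c("1$C1$1$64$YR$F$MD$US$2015",
                   "2$C2$1$$$M$CN$FR$2016",
                   "3$C3$1$30$YR$$$JP$2017"))
  write1("drug", c("1$1$PS$GLEEVEC", "1$2$C$aspirin", "9$1$PS$orphan row"))
  write1("reac", c("1$nausea simplex$20150401", "$headache$", "2$pyrexia intermittent$"))
  write1("outc", "1$HO")
  write1("indi", "1$1$chronic myeloid leukemia")
  write1("ther", "1$1$20150101$")
  paths <- setNames(file.path(dir, paste0(names(hdr), ".txt")), names(hdr))

  ts <- read_table_set(paths)
  expect_s3_class(ts, "raw_table_set")
  expect_equal(nrow(ts$demo), 3)
  lr <- ts$load_report
  expect_equal(lr$n_dropped_no_key[lr$table == "reac"], 1)
  expect_equal(lr$n_dropped_orphan[lr$table == "drug"], 1)
  expect_equal(nrow(ts$drug), 2)

  # unknown column layout names the offending file
  writeLines(c("foo$bar", "1$2"), file.path(dir, "demo.txt"))
  expect_error(read_table_set(paths), "demo.txt")
})

test_that("writer/reader round-trip is lossless for complete records", {
  g <- generate_faers(scenario_config(n_reports = 150, seed = 3,
                                      missing_date_rate = 0))
  dir <- withr::local_tempdir()
  paths <- write_table_set(g$tables, dir)
  back <- read_table_set(paths, source_quarter = "synthetic")
  for (nm in c("demo", "drug", "reac", "outc", "indi", "ther")) {
    expect_identical(as.data.frame(back[[nm]]),
                     as.data.frame(g$tables[[nm]]), label = nm)
  }
})

test_that("assembly groups drug/event lines under one report and derives fields", {
  dir <- withr::local_tempdir()
  hdr <- faers_dialect()
  write1 <- function(nm, rows) {
    writeLines(c(paste(hdr[[nm]], collapse = "$"), rows),
               file.path(dir, paste0(nm, ".txt")))
  }
  write1("demo", c("1$C1$1$65$YR$F$MD$US$2015", "2$C2$2$$$X$$$2016"))
  write1("drug", c("1$1$PS$TASIGNA", "1$2$C$warfarin"))
  write1("reac", c("1$term a$20150401", "1$term b$", "1$term c$201501"))
  write1("outc", c("1$HO", "1$DE"))
  write1("indi", "1$1$cml")
  write1("ther", "1$1$20150101$20150601")
  paths <- setNames(file.path(dir, paste0(names(hdr), ".txt")), names(hdr))
  st <- assemble_reports(read_table_set(paths))

  expect_equal(nrow(st$reports), 2)
  r1 <- st$reports[st$reports$report_id == "1", ]
  expect_equal(sum(st$drugs$report_id == "1"), 2)
  expect_equal(sum(st$events$report_id == "1"), 3)
  expect_equal(as.character(r1$age_class), "51-75")  # age 65
  expect_true(r1$serious)
  expect_setequal(r1$outcomes[[1]], c("hospitalization", "death"))

  r2 <- st$reports[st$reports$report_id == "2", ]
  expect_equal(as.character(r2$age_class), "unknown")  # missing age
  expect_equal(r2$sex, "unknown")
  expect_false(r2$serious)
  expect_equal(r2$outcomes[[1]], character(0))
})

test_that("age-class mapping is total, deterministic and matches the bin labels", {
  ages <- c(seq(0, 150, by = 0.5), NA)
  cls <- age_class_of(ages)
  expect_false(anyNA(cls))
  expect_setequal(levels(cls), c("<=25", "26-50", "51-75", ">=76", "unknown"))
  # inclusive boundaries as printed
  expect_equal(as.character(age_class_of(c(25, 26, 50, 51, 75, 76, NA))),
               c("<=25", "26-50", "26-50", "51-75", "51-75", ">=76", "unknown"))
  expect_identical(age_class_of(ages), age_class_of(ages))
})

test_that("report count after assembly equals distinct report identifiers", {
  for (seed in c(2, 17)) {
    g <- generate_faers(scenario_config(n_reports = 400, seed = seed))
    st <- assemble_reports(g$tables)
    expect_equal(nrow(st$reports), length(unique(g$tables$demo$primaryid)))
    # every child line belongs to an assembled report
    expect_true(all(st$drugs$report_id %in% st$reports$report_id))
    expect_true(all(st$events$report_id %in% st$reports$report_id))
  }
})

test_that("conflicting demographic lines keep the first and are logged", {
  dir <- withr::local_tempdir()
  hdr <- faers_dialect()
  write1 <- function(nm, rows) {
    writeLines(c(paste(hdr[[nm]], collapse = "$"), rows),
               file.path(dir, paste0(nm, ".txt")))
  }
  write1("demo", c("1$C1$1$40$YR$F$MD$US$2015", "1$C1$1$70$YR$M$MD$US$2015"))
  for (nm in setdiff(names(hdr), "demo")) write1(nm, character(0))
  paths <- setNames(file.path(dir, paste0(names(hdr), ".txt")), names(hdr))
  expect_message(st <- assemble_reports(read_table_set(paths)), "duplicated")
  expect_equal(nrow(st$reports), 1)
  expect_equal(st$reports$age_years, 40)
})
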