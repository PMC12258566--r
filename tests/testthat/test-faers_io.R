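test_that("parser reads well-formed rows into typed records", {
  df <- parse_faers_table(c("primaryid$caseid$fda_dt$sex", "100$1$20220101$F"),
                          "DEMO")
  expect_equal(nrow(df), 1L)
  expect_equal(df$primaryid, "100")
  expect_equal(df$caseid, "1")
  expect_equal(df$sex, "F")
  expect_equal(df$received_year, 2022L)
  expect_equal(attr(df, "skipped"), 0L)
})

test_that("empty fields become NA, never sentinel values", {
  df <- parse_faers_table(c("primaryid$caseid$age$sex", "100$1$$F"), "DEMO")
  expect_true(is.na(df$age))
  expect_true(is.na(df$age_years))
  expect_true(is.na(df$wt))         # absent column
})

test_that("malformed rows are skipped with a warning, not fatal", {
  txt <- c("primaryid$caseid$fda_dt$sex",
           "100$1$20220101$F",
           "101$2$2022$0101$M$extra",   # wrong delimiter count
           "102$3$20220301$M")
  expect_warning(df <- parse_faers_table(txt, "DEMO"), "skipped 1")
  expect_equal(nrow(df), 2L)
  expect_equal(attr(df, "skipped"), 1L)
})

test_that("header matching is case-insensitive and unknown columns are ignored", {
  df <- parse_faers_table(
    c("PRIMARYID$CASEID$MYSTERY$SEX", "100$1$zzz$f"), "DEMO")
  expect_equal(df$sex, "F")
  expect_false("mystery" %in% names(df))
})

test_that("drug records normalize role codes to the closed set", {
  df <- parse_faers_table(
    c("primaryid$drug_seq$role_cod$drugname",
      "100$1$ps$ADUHELM", "100$2$XX$ASPIRIN"), "DRUG")
  expect_equal(df$role_cod, c("PS", NA))
})

test_that("age units convert to years", {
  expect_equal(age_in_years(c(8, 24, 730.5), c("DEC", "MON", "DY")), c(80, 2, 2))
  expect_equal(age_in_years(70, NA), 70)       # missing unit = years
  expect_true(is.na(age_in_years(-5, "YR")))   # negative age absent
})

test_that("partial dates keep their precision and drop out of day arithmetic", {
  expect_equal(faers_date_prec(c("20220101", "202201", "2022", "bad", NA)),
               c(8L, 6L, 4L, NA, NA))
  expect_equal(faers_date_num("202203") > faers_date_num("20220101"), TRUE)
  expect_true(is.na(faers_date_day("202203")))
  expect_equal(faers_date_day("20220315"), as.Date("2022-03-15"))
})

test_that("deduplication keeps the latest report per case with primaryid tie-break", {
  one <- parse_faers_table(demo_lines()[1:2], "DEMO")
  expect_equal(deduplicate_cases(one), one, ignore_attr = TRUE)

  demo <- parse_faers_table(c(
    "primaryid$caseid$fda_dt",
    "100$7$20220101",
    "105$7$20220301",   # later fda_dt wins
    "200$8$20220601",
    "201$8$20220601"    # same date: larger primaryid wins
  ), "DEMO")
  out <- deduplicate_cases(demo)
  expect_equal(out$primaryid, c("105", "201"))
  expect_equal(out$caseid, c("7", "8"))
})

test_that("deduplication is idempotent and order-invariant", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    demo <- data.frame(
      primaryid = as.character(sample(1000:9999, n)),
      caseid = as.character(sample(1:12, n, replace = TRUE)),
      caseversion = 1L,
      fda_dt = format(as.Date("2022-01-01") + sample(0:400, n, TRUE), "%Y%m%d"),
      stringsAsFactors = FALSE
    )
    once <- deduplicate_cases(demo)
    expect_equal(deduplicate_cases(once), once)
    shuffled <- demo[sample(n), , drop = FALSE]
    expect_equal(deduplicate_cases(shuffled), once, ignore_attr = TRUE)
    expect_equal(anyDuplicated(once$caseid), 0L)
  }
})

test_that("target selection matches substrings case-insensitively in name or ingredient", {
  drugs <- data.frame(
    primaryid = c("1", "2", "3", "4", "5"),
    drug_seq = 1L,
    role_cod = c("PS", "PS", "C", "PS", "SS"),
    drugname = c("ADUHELM", "aducanumab-avwa", "ADUHELM", "ASPIRIN", "ADUHELM"),
    prod_ai = c(NA, NA, NA, "ADUCANUMAB", NA),
    stringsAsFactors = FALSE
  )
  expect_equal(select_target_reports(drugs), c("1", "2", "4"))
  expect_equal(select_target_reports(drugs, roles = c("PS", "SS")),
               c("1", "2", "4", "5"))
  expect_equal(select_target_reports(drugs, patterns = "ASPIRIN"), "4")
})

test_that("selection is monotone in the pattern set", {
  set.seed(5)
  names_pool <- c("ADUHELM", "ADUCANUMAB-AVWA", "LEQEMBI", "ASPIRIN",
                  "DONEPEZIL HCL", "MEMANTINE")
  drugs <- data.frame(
    primaryid = as.character(1:60), drug_seq = 1L,
    role_cod = sample(c("PS", "SS", "C", "I"), 60, TRUE),
    drugname = sample(names_pool, 60, TRUE), prod_ai = NA_character_,
    stringsAsFactors = FALSE
  )
  base <- select_target_reports(drugs, patterns = "ADU")
  for (extra in c("LEQEMBI", "ASPIRIN", "MEM")) {
    bigger <- select_target_reports(drugs, patterns = c("ADU", extra))
    expect_true(all(base %in% bigger))
  }
})

test_that("case-set assembly restricts, drops orphans and tolerates empty selections", {
  demo <- parse_faers_table(demo_lines(), "DEMO")
  drugs <- data.frame(primaryid = c("1001", "1011"), drug_seq = 1L,
                      role_cod = "PS", drugname = "ADUHELM",
                      prod_ai = NA_character_, stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = c("1001", "9999"), pt = c("Headache", "Nausea"),
                     stringsAsFactors = FALSE)
  outc <- data.frame(primaryid = "1001", outc_cod = "HO", stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = "1001", drug_seq = 1L, start_dt = "20220101",
                     end_dt = NA_character_, stringsAsFactors = FALSE)

  expect_message(
    cs <- assemble_case_set(demo, drugs, reac, outc, ther,
                            c("1001", "1011", "9999")),
    "1 orphan")
  expect_equal(attr(cs, "n_orphans"), 1L)
  expect_equal(nrow(cs$reactions), 1L)
  expect_setequal(cs$report_ids, c("1001", "1011"))

  all_cs <- assemble_case_set(demo, drugs, reac[1, ], outc, ther)
  expect_equal(nrow(all_cs$demo), nrow(demo))

  none <- assemble_case_set(demo, drugs, reac[1, ], outc, ther, character())
  expect_equal(length(none$report_ids), 0L)
  expect_equal(nrow(none$drugs), 0L)
})

test_that("writer and parser round-trip generated tables field by field", {
  cfg <- synthetic_config(n_reports = 150, seed = 31, duplicate_rate = 0.1)
  g <- generate_reports(cfg)
  dir <- withr::local_tempdir()
  paths <- write_faers_tables(g$tables, dir, "23Q4")
  for (kind in names(paths)) {
    back <- parse_faers_table(paths[[kind]], kind)
    orig <- g$tables[[kind]]
    shared <- intersect(names(orig), names(back))
    expect_equal(back[shared], orig[shared], ignore_attr = TRUE,
                 info = kind)
  }
})
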