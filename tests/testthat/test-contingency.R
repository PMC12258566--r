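test_that("PT->SOC map normalizes keys, defaults to UNMAPPED, rejects conflicts", {
  map <- pt_soc_map(c("Cerebral Microhaemorrhage ", "Nausea"),
                    c("Nervous system disorders", "Gastrointestinal disorders"))
  expect_equal(lookup_soc(map, "cerebral  microhaemorrhage"),
               "Nervous system disorders")
  expect_equal(lookup_soc(map, "xyzzy"), "UNMAPPED")
  expect_error(pt_soc_map(c("Headache", "headache"), c("SOC A", "SOC B")),
               "conflicting")
  # identical duplicate rows are fine
  expect_silent(pt_soc_map(c("Headache", "HEADACHE"), c("SOC A", "SOC A")))
})

test_that("map files load with or without a header row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pt,soc", "Headache,Nervous system disorders"), f)
  expect_equal(lookup_soc(read_pt_soc_map(f), "Headache"),
               "Nervous system disorders")
  writeLines(c("Headache,Nervous system disorders"), f)
  expect_equal(lookup_soc(read_pt_soc_map(f), "Headache"),
               "Nervous system disorders")
})

test_that("counting unit is the unique (report, PT) pair", {
  target <- small_case_set(1, pts = list(c("Headache", "headache ")))
  bg <- background_case_set(list("Nausea"))
  counts <- count_pairs(target, bg, example_map(), level = "PT")
  expect_equal(counts$n_target[counts$event == "headache"], 1L)
  expect_equal(attr(counts, "N_target"), 1L)
})

test_that("SOC aggregation counts once per distinct PT, so SOC totals can exceed report counts", {
  target <- small_case_set(1, pts = list(c("Brain oedema", "Seizure")))
  bg <- background_case_set(list("Nausea"))
  counts <- count_pairs(target, bg, example_map(), level = "SOC")
  expect_equal(counts$n_target[counts$event == "Nervous system disorders"], 2L)
})

test_that("pair counts are permutation-invariant and consistent with totals", {
  target <- small_case_set(4)
  bg <- background_case_set(list(c("Headache", "Nausea"), "Fatigue",
                                 c("Seizure", "Headache"), "Nausea"))
  for (level in c("PT", "SOC")) {
    counts <- count_pairs(target, bg, example_map(), level = level)
    expect_equal(sum(counts$n_target), attr(counts, "N_target"))
    expect_equal(sum(counts$n_background), attr(counts, "N_background"))
    # shuffle reaction rows: identical result
    t2 <- target
    t2$reactions <- t2$reactions[rev(seq_len(nrow(t2$reactions))), , drop = FALSE]
    expect_equal(count_pairs(t2, bg, example_map(), level = level), counts)
  }
})

test_that("overlapping target/background id sets are fatal", {
  target <- small_case_set(2)
  expect_error(count_pairs(target, target, example_map()), "overlap")
})

test_that("empty target gives all-zero target counts", {
  demo0 <- small_case_set(1)$demo[0, ]
  empty <- assemble_case_set(
    demo0,
    data.frame(primaryid = character(), drug_seq = integer(),
               role_cod = character(), drugname = character(),
               prod_ai = character()),
    data.frame(primaryid = character(), pt = character()),
    data.frame(primaryid = character(), outc_cod = character()),
    data.frame(primaryid = character(), drug_seq = integer(),
               start_dt = character(), end_dt = character()),
    character())
  bg <- background_case_set(list("Nausea", "Headache"))
  counts <- count_pairs(empty, bg, example_map())
  expect_true(all(counts$n_target == 0L))
  expect_equal(attr(counts, "N_target"), 0L)
})

test_that("2x2 construction follows a, N_target - a, c, N_background - c", {
  counts <- structure(
    data.frame(event = "headache", n_target = 3L, n_background = 30L),
    N_target = 10L, N_background = 990L,
    class = c("faers_pair_counts", "data.frame"))
  tab <- build_table(counts, "headache")
  expect_equal(unclass(tab), c(a = 3, b = 7, c = 30, d = 960))
  absent <- build_table(counts, "no such event")
  expect_equal(unclass(absent), c(a = 0, b = 10, c = 0, d = 990))
})

test_that("table cells always sum to N_target + N_background", {
  target <- small_case_set(4)
  bg <- background_case_set(list(c("Headache", "Nausea"), "Fatigue",
                                 c("Seizure", "Headache"), "Nausea"))
  counts <- count_pairs(target, bg, example_map())
  for (ev in counts$event) {
    expect_equal(sum(build_table(counts, ev)),
                 attr(counts, "N_target") + attr(counts, "N_background"))
  }
})

test_that("invalid cells are rejected", {
  expect_error(contingency_2x2(-1, 2, 3, 4), "non-negative")
  counts <- structure(
    data.frame(event = "x", n_target = 5L, n_background = 0L),
    N_target = 3L, N_background = 10L,
    class = c("faers_pair_counts", "data.frame"))
  expect_error(build_table(counts, "x"), "negative derived cell")
})
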