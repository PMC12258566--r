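# Shared in-code fixtures: everything is built programmatically.

# minimal DEMO table as raw FAERS-dialect lines
demo_lines <- function() {
  c(
    "primaryid$caseid$caseversion$fda_dt$event_dt$age$age_cod$sex$wt$occp_cod$reporter_country",
    "1001$100$1$20220101$20211220$77$YR$F$62$MD$US",
    "1011$101$1$20220215$$8$DEC$M$$CN$US",
    "1021$102$1$20220301$202202$$$F$55$PH$JP"
  )
}

# a small hand-built case set: n target reports all carrying the target
# drug as primary suspect
small_case_set <- function(n = 4,
                           pts = list(c("Headache"), c("Headache", "Seizure"),
                                      c("Brain oedema"), c("Nausea")),
                           drug = "ADUCANUMAB") {
  ids <- as.character(seq_len(n) + 1000)
  demo <- data.frame(
    primaryid = ids, caseid = as.character(seq_len(n)), caseversion = 1L,
    fda_dt = "20220601", event_dt = "20220501",
    age = 80, age_cod = "YR", sex = rep(c("F", "M"), length.out = n),
    wt = 70, occp_cod = "MD", reporter_country = "US",
    stringsAsFactors = FALSE
  )
  demo$age_years <- faersignal::age_in_years(demo$age, demo$age_cod)
  demo$received_year <- faersignal::faers_date_year(demo$fda_dt)
  drugs <- data.frame(primaryid = ids, drug_seq = 1L, role_cod = "PS",
                      drugname = drug, prod_ai = drug, stringsAsFactors = FALSE)
  reac <- data.frame(
    primaryid = rep(ids, lengths(pts[seq_len(n)])),
    pt = unlist(pts[seq_len(n)]), stringsAsFactors = FALSE)
  outc <- data.frame(primaryid = ids[1], outc_cod = "HO", stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = ids, drug_seq = 1L, start_dt = "20220401",
                     end_dt = NA_character_, stringsAsFactors = FALSE)
  assemble_case_set(demo, drugs, reac, outc, ther, ids)
}

# background case set with given (report, PT) structure
background_case_set <- function(pts, offset = 5000) {
  n <- length(pts)
  ids <- as.character(seq_len(n) + offset)
  demo <- data.frame(
    primaryid = ids, caseid = ids, caseversion = 1L,
    fda_dt = "20220601", event_dt = NA_character_, age = NA_real_,
    age_cod = NA_character_, sex = "F", wt = NA_real_,
    occp_cod = NA_character_, reporter_country = "US",
    stringsAsFactors = FALSE
  )
  demo$age_years <- NA_real_
  demo$received_year <- 2022L
  drugs <- data.frame(primaryid = ids, drug_seq = 1L, role_cod = "PS",
                      drugname = "OTHERDRUG", prod_ai = "OTHERDRUG",
                      stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = rep(ids, lengths(pts)), pt = unlist(pts),
                     stringsAsFactors = FALSE)
  empty_outc <- data.frame(primaryid = character(), outc_cod = character(),
                           stringsAsFactors = FALSE)
  empty_ther <- data.frame(primaryid = character(), drug_seq = integer(),
                           start_dt = character(), end_dt = character(),
                           stringsAsFactors = FALSE)
  assemble_case_set(demo, drugs, reac, empty_outc, empty_ther, ids)
}

example_map <- function() {
  pt_soc_map(
    c("Headache", "Seizure", "Brain oedema", "Cerebral microhaemorrhage",
      "Nausea", "Fatigue"),
    c("Nervous system disorders", "Nervous system disorders",
      "Nervous system disorders", "Nervous system disorders",
      "Gastrointestinal disorders",
      "General disorders and administration site conditions")
  )
}

# random 2x2 tables with all cells >= min_cell
random_tables <- function(n, min_cell = 1, max_cell = 60, seed = 42) {
  set.seed(seed)
  replicate(n, sample(min_cell:max_cell, 4, replace = TRUE), simplify = FALSE)
}
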