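# Report characteristics, outcome distribution and time-to-onset.

.tto_breaks <- c(0, 7, 28, 60, Inf)
.tto_labels <- c("<7", "7~28", "28~60", ">=60")

#' Time-to-onset bucket for a number of days
#'
#' Half-open buckets `[0,7)`, `[7,28)`, `[28,60)`, `[60, Inf)`; `NA`
#' days (or negative ones upstream) map to `"Unknown"`.
#'
#' @param days integer days.
#' @return character bucket labels.
#' @export
tto_bucket <- function(days) {
  out <- as.character(cut(days, .tto_breaks, labels = .tto_labels, right = FALSE))
  out[is.na(out)] <- "Unknown"
  out
}

#' Time to onset per report
#'
#' Days from the earliest therapy start of a target drug to the event
#' date, in whole days. The computation needs day-level precision on
#' both dates; a partial or missing date, or a negative difference,
#' yields `"Unknown"`. Reports with no therapy record for a target
#' drug are outside the time-to-onset universe and are omitted from
#' the result (this defines the tabulation denominator in
#' [summarize_characteristics()]).
#'
#' @param case_set a [case_set][assemble_case_set].
#' @param patterns,roles target-drug matching as in
#'   [select_target_reports()]; therapy records are linked to drug
#'   records via (`primaryid`, `drug_seq`).
#' @return data.frame with columns `primaryid`, `days` (integer or
#'   `NA`) and `bucket`.
#' @export
compute_tto <- function(case_set, patterns = c("ADUCANUMAB", "ADUHELM"),
                        roles = "PS") {
  drugs <- case_set$drugs
  ther <- case_set$therapies
  demo <- case_set$demo
  pat <- toupper(trimws(patterns))
  name <- toupper(ifelse(is.na(drugs$drugname), "", drugs$drugname))
  ai <- toupper(ifelse(is.na(drugs$prod_ai), "", drugs$prod_ai))
  hit <- rep(FALSE, nrow(drugs))
  for (p in pat) hit <- hit | grepl(p, name, fixed = TRUE) | grepl(p, ai, fixed = TRUE)
  hit <- hit & !is.na(drugs$role_cod) & drugs$role_cod %in% toupper(roles)
  key <- paste(drugs$primaryid, drugs$drug_seq)[hit]

  tk <- ther[paste(ther$primaryid, ther$drug_seq) %in% key, , drop = FALSE]
  if (nrow(tk) == 0L) {
    return(data.frame(primaryid = character(), days = integer(),
                      bucket = character(), stringsAsFactors = FALSE))
  }
  tk$start <- as.numeric(faers_date_day(tk$start_dt))
  dt <- as.data.table(tk)[, .(start = suppressWarnings(min(start, na.rm = TRUE))),
                          by = primaryid]
  dt[!is.finite(start), start := NA_real_]
  ev <- demo[match(dt$primaryid, demo$primaryid), "event_dt"]
  event <- as.numeric(faers_date_day(ev))
  days <- as.integer(event - dt$start)
  days[!is.na(days) & days < 0] <- NA_integer_
  out <- data.frame(primaryid = dt$primaryid, days = days,
                    bucket = tto_bucket(days), stringsAsFactors = FALSE)
  out[order(out$primaryid), , drop = FALSE]
}

.occp_labels <- c(CN = "Consumer", MD = "Physician", PH = "Pharmacist",
                  HP = "Other", LW = "Other", OT = "Other")
.outcome_labels <- c(DE = "Death", LT = "Life threatening", HO = "Hospitalization",
                     DS = "Disability", CA = "Congenital anomaly",
                     RI = "Required intervention", OT = "Other serious")

.bin_label <- function(x, breaks, labels) {
  out <- as.character(cut(x, breaks, labels = labels, right = FALSE))
  out[is.na(out)] <- "Unknown"
  out
}

#' Summarize report characteristics
#'
#' Tabulates, with counts and percentages: year received, sex, age and
#' weight bins, reporter occupation, reporter country, outcome codes
#' and time-to-onset buckets.
#'
#' Denominators follow spontaneous-report conventions:
#' * demographic variables (year, sex, age, weight, reporter, country)
#'   use the reports with known sex as the universe — reports of
#'   unknown sex are excluded from the characteristics table entirely
#'   (both counts are recorded in the attributes);
#' * outcomes are counted at the outcome-record level (a report with
#'   several outcomes contributes once per outcome), so the
#'   denominator is the number of outcome records;
#' * time-to-onset uses the reports in the TTO universe (those with a
#'   target-drug therapy record, see [compute_tto()]), including the
#'   `"Unknown"` bucket.
#'
#' Age bins are half-open left-closed: `[45,65)`, `[65,75)`, `>=75`;
#' weight `<60`, `[60,80)`, `>=80` kg. Percentages are
#' `100 * count / denominator` rounded half-up to 2 decimals (see
#' [pct()]); rounding is presentation-only.
#'
#' @param case_set a deduplicated [case_set][assemble_case_set].
#' @param patterns,roles passed to [compute_tto()].
#' @param top_countries number of individual countries to list before
#'   rolling the rest into `"Other"` (default 1).
#' @return a `data.frame` with columns `variable`, `category`, `count`,
#'   `percent`, plus attributes `n_selected` (all reports),
#'   `n_known_sex` (demographic denominator), `n_outcome_records` and
#'   `n_tto`.
#' @export
summarize_characteristics <- function(case_set,
                                      patterns = c("ADUCANUMAB", "ADUHELM"),
                                      roles = "PS", top_countries = 1) {
  demo <- case_set$demo
  n_selected <- nrow(demo)
  known <- demo[!is.na(demo$sex) & demo$sex %in% c("F", "M"), , drop = FALSE]
  n_known <- nrow(known)

  tab_block <- function(variable, categories, denom) {
    categories <- categories[!is.na(categories)]
    if (length(categories) == 0L || denom == 0) {
      return(data.frame(variable = character(), category = character(),
                        count = integer(), percent = numeric(),
                        stringsAsFactors = FALSE))
    }
    tt <- table(categories)
    data.frame(variable = variable, category = names(tt),
               count = as.integer(tt), percent = pct(as.integer(tt), denom),
               stringsAsFactors = FALSE)
  }
  order_block <- function(blk, order) {
    got <- intersect(order, blk$category)
    rest <- setdiff(blk$category, order)
    blk[match(c(got, sort(rest)), blk$category), , drop = FALSE]
  }

  year <- tab_block("Year", as.character(known$received_year), n_known)
  sex <- tab_block("Sex", c(Female = "Female", Male = "Male")[
    match(known$sex, c("F", "M"))], n_known)
  sex <- order_block(sex, c("Female", "Male"))
  age <- tab_block("Age", .bin_label(known$age_years, c(0, 45, 65, 75, Inf),
                                     c("<45", "45~65", "65~75", ">=75")), n_known)
  age <- order_block(age, c("<45", "45~65", "65~75", ">=75", "Unknown"))
  wt <- tab_block("Weight (kg)", .bin_label(known$wt, c(0, 60, 80, Inf),
                                            c("<60", "60~80", ">=80")), n_known)
  wt <- order_block(wt, c("<60", "60~80", ">=80", "Unknown"))

  occ <- .occp_labels[known$occp_cod]
  occ[is.na(occ)] <- "Unknown"
  rep_blk <- order_block(tab_block("Reporter", occ, n_known),
                         c("Consumer", "Physician", "Pharmacist", "Other", "Unknown"))

  country <- ifelse(is.na(known$reporter_country), "Unknown",
                    trimws(known$reporter_country))
  main <- names(sort(table(country[country != "Unknown"]), decreasing = TRUE))
  main <- main[seq_len(min(top_countries, length(main)))]
  country[!(country %in% main)] <- "Other"
  ctry <- order_block(tab_block("Reported countries", country, n_known),
                      c(main, "Other"))

  outc <- case_set$outcomes
  outc <- outc[outc$primaryid %in% known$primaryid, , drop = FALSE]
  oc <- .outcome_labels[outc$outc_cod]
  oc[is.na(oc)] <- "Other serious"
  n_outc <- length(oc)
  outcomes <- tab_block("Outcomes", oc, n_outc)
  outcomes <- outcomes[order(-outcomes$count, outcomes$category), , drop = FALSE]

  tto <- compute_tto(case_set, patterns = patterns, roles = roles)
  tto <- tto[tto$primaryid %in% known$primaryid, , drop = FALSE]
  n_tto <- nrow(tto)
  tto_blk <- order_block(tab_block("TTO", tto$bucket, n_tto),
                         c(.tto_labels, "Unknown"))

  out <- rbind(year, sex, age, wt, rep_blk, ctry, outcomes, tto_blk)
  rownames(out) <- NULL
  structure(out, n_selected = n_selected, n_known_sex = n_known,
            n_outcome_records = n_outc, n_tto = n_tto,
            class = c("faers_characteristics", "data.frame"))
}

#' @export
print.faers_characteristics <- function(x, ...) {
  cat(sprintf("Report characteristics: %d reports (%d with known sex)\n",
              attr(x, "n_selected"), attr(x, "n_known_sex")))
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}
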