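# Reading, cleaning and joining FAERS quarterly ASCII tables.
#
# The quarterly extracts are "$"-delimited text with a header row; field
# names drifted across the years (primaryid vs primary_id, gndr_cod vs
# sex, ...), so parsing matches header names case-insensitively against
# an alias table and ignores anything it does not recognise.

.faers_schemas <- list(
  DEMO = list(
    primaryid        = c("primaryid", "primary_id", "isr"),
    caseid           = c("caseid", "case_id", "case"),
    caseversion      = c("caseversion", "case_version"),
    fda_dt           = c("fda_dt", "fda_date"),
    event_dt         = c("event_dt", "event_date"),
    age              = c("age", "age_value"),
    age_cod          = c("age_cod", "age_unit"),
    sex              = c("sex", "gndr_cod"),
    wt               = c("wt", "weight", "weight_kg"),
    occp_cod         = c("occp_cod", "reporter_occupation", "occp"),
    reporter_country = c("reporter_country", "occr_country", "country")
  ),
  DRUG = list(
    primaryid = c("primaryid", "primary_id", "isr"),
    drug_seq  = c("drug_seq", "dsg_drug_seq", "drugseq"),
    role_cod  = c("role_cod", "role_code", "role"),
    drugname  = c("drugname", "drug_name"),
    prod_ai   = c("prod_ai", "active_ingredient", "ai")
  ),
  REAC = list(
    primaryid = c("primaryid", "primary_id", "isr"),
    pt        = c("pt", "pt_name", "preferred_term")
  ),
  OUTC = list(
    primaryid = c("primaryid", "primary_id", "isr"),
    outc_cod  = c("outc_cod", "outc_code", "outcome_code")
  ),
  THER = list(
    primaryid = c("primaryid", "primary_id", "isr"),
    drug_seq  = c("dsg_drug_seq", "drug_seq", "drugseq"),
    start_dt  = c("start_dt", "start_date"),
    end_dt    = c("end_dt", "end_date")
  )
)

.role_codes <- c("PS", "SS", "C", "I")
.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Parse a FAERS quarterly ASCII table
#'
#' Reads one `$`-delimited FAERS table (with header row) into a typed
#' `data.frame` with canonical lower-case column names. Unknown columns
#' are ignored; header names are matched case-insensitively against the
#' historical aliases for each field. Empty fields become `NA`, never
#' sentinel numbers. Rows whose delimiter count does not match the
#' header are skipped with a warning; the number skipped is attached as
#' attribute `"skipped"` (real FAERS quarters contain stray
#' delimiters, so a malformed row is not fatal).
#'
#' @param input path to a file, or a character vector of lines (length
#'   > 1, or containing newlines).
#' @param table table kind: `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"` or
#'   `"THER"`.
#' @return A `data.frame` with the canonical columns for the table kind
#'   (e.g. DEMO: `primaryid`, `caseid`, `caseversion`, `fda_dt`,
#'   `event_dt`, `age`, `age_cod`, `sex`, `wt`, `occp_cod`,
#'   `reporter_country`, plus derived `age_years` and `received_year`),
#'   with attribute `skipped` = number of malformed rows dropped.
#' @examples
#' txt <- c("primaryid$caseid$fda_dt$sex", "100$1$20220101$F")
#' parse_faers_table(txt, "DEMO")
#' @export
parse_faers_table <- function(input, table = c("DEMO", "DRUG", "REAC", "OUTC", "THER")) {
  table <- match.arg(table)
  schema <- .faers_schemas[[table]]

  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(input), "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty input for table ", table)

  header <- tolower(trimws(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]))
  nfield <- length(header)
  body <- lines[-1L]

  parts <- strsplit(body, "$", fixed = TRUE)
  # a trailing empty field is dropped by strsplit; pad by delimiter count
  ndelim <- lengths(regmatches(body, gregexpr("$", body, fixed = TRUE)))
  good <- ndelim == (nfield - 1L)
  skipped <- sum(!good)
  if (skipped > 0L) {
    warning(sprintf("parse_faers_table(%s): skipped %d malformed row(s)", table, skipped))
  }
  parts <- parts[good]
  cells <- lapply(parts, function(p) {
    length(p) <- nfield
    p
  })
  mat <- if (length(cells)) do.call(rbind, cells) else matrix(character(), 0L, nfield)
  mat[is.na(mat)] <- ""

  out <- list()
  for (col in names(schema)) {
    idx <- match(schema[[col]], header)
    idx <- idx[!is.na(idx)][1L]
    v <- if (!is.na(idx)) trimws(mat[, idx]) else rep("", nrow(mat))
    v[v == ""] <- NA_character_
    out[[col]] <- v
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)

  # typed / normalized fields
  if (table == "DEMO") {
    out$caseversion <- suppressWarnings(as.integer(out$caseversion))
    out$age <- suppressWarnings(as.numeric(out$age))
    out$wt <- suppressWarnings(as.numeric(out$wt))
    out$wt[!is.na(out$wt) & out$wt <= 0] <- NA_real_
    out$sex <- toupper(out$sex)
    out$sex[!is.na(out$sex) & !(out$sex %in% c("F", "M"))] <- "UNK"
    out$age_cod <- toupper(out$age_cod)
    out$occp_cod <- toupper(out$occp_cod)
    out$age_years <- age_in_years(out$age, out$age_cod)
    out$received_year <- faers_date_year(out$fda_dt)
  } else if (table == "DRUG") {
    out$drug_seq <- suppressWarnings(as.integer(out$drug_seq))
    out$role_cod <- toupper(out$role_cod)
    out$role_cod[!is.na(out$role_cod) & !(out$role_cod %in% .role_codes)] <- NA_character_
  } else if (table == "OUTC") {
    out$outc_cod <- toupper(out$outc_cod)
  } else if (table == "THER") {
    out$drug_seq <- suppressWarnings(as.integer(out$drug_seq))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write a table in the FAERS ASCII dialect
#'
#' Inverse of [parse_faers_table()]: writes the canonical columns as
#' `$`-delimited text with a header row, `NA` as empty fields. Derived
#' columns (`age_years`, `received_year`) are not written.
#'
#' @param x data.frame as returned by [parse_faers_table()].
#' @param path output file path.
#' @param table table kind (see [parse_faers_table()]).
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(x, path, table = c("DEMO", "DRUG", "REAC", "OUTC", "THER")) {
  table <- match.arg(table)
  cols <- names(.faers_schemas[[table]])
  m <- sapply(cols, function(col) {
    v <- if (col %in% names(x)) as.character(x[[col]]) else rep(NA_character_, nrow(x))
    ifelse(is.na(v), "", v)
  })
  if (nrow(x) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, cols))
  lines <- c(paste(cols, collapse = "$"),
             if (nrow(x)) apply(m, 1L, paste, collapse = "$"))
  writeLines(lines, path)
  invisible(path)
}

#' Deduplicate demographic records to one per case
#'
#' FAERS cases are revised across quarters: the same `caseid` recurs
#' with new `primaryid`s. Following standard FAERS practice, the record
#' with the latest FDA receipt date is kept for each case; ties are
#' broken by the largest numeric `primaryid`. Output is sorted by
#' `caseid`, making the operation deterministic and idempotent.
#'
#' @param demo DEMO data.frame (see [parse_faers_table()]).
#' @return the deduplicated DEMO data.frame.
#' @export
deduplicate_cases <- function(demo) {
  if (nrow(demo) == 0L) return(demo)
  dt <- as.data.table(demo)
  dt[, ord := faers_date_num(fda_dt)]
  dt[is.na(ord), ord := -Inf]
  dt[, tie := suppressWarnings(as.numeric(primaryid))]
  dt[is.na(tie), tie := -Inf]
  setorder(dt, caseid, -ord, -tie)
  out <- dt[, .SD[1L], by = caseid]
  out[, c("ord", "tie") := NULL]
  setcolorder(out, names(demo))
  setorder(out, caseid)
  as.data.frame(out)
}

#' Select reports naming a target drug in a suspect role
#'
#' A report is selected iff it has at least one drug record whose role
#' code is in `roles` and whose verbatim product name *or* active
#' ingredient contains any of `patterns` as a case-insensitive
#' substring (FAERS free-text names carry salt/suffix variants such as
#' `"ADUCANUMAB-AVWA"`).
#'
#' @param drugs DRUG data.frame.
#' @param patterns character vector of name fragments; default the
#'   aducanumab product strings.
#' @param roles role codes to accept; default `"PS"` (primary suspect).
#' @return sorted character vector of selected `primaryid`s.
#' @export
select_target_reports <- function(drugs,
                                  patterns = c("ADUCANUMAB", "ADUHELM"),
                                  roles = "PS") {
  stopifnot(length(patterns) >= 1L)
  roles <- toupper(roles)
  pat <- toupper(trimws(patterns))
  name <- toupper(trimws(ifelse(is.na(drugs$drugname), "", drugs$drugname)))
  ai <- toupper(trimws(ifelse(is.na(drugs$prod_ai), "", drugs$prod_ai)))
  hit <- rep(FALSE, nrow(drugs))
  for (p in pat) {
    hit <- hit | grepl(p, name, fixed = TRUE) | grepl(p, ai, fixed = TRUE)
  }
  hit <- hit & !is.na(drugs$role_cod) & drugs$role_cod %in% roles
  sort(unique(drugs$primaryid[hit]))
}

#' Assemble a joined, restricted case set
#'
#' Restricts the five FAERS tables to a set of report identifiers and
#' bundles them. Child records whose `primaryid` has no demographic
#' parent are orphans: they are dropped and counted (attribute
#' `n_orphans` and a message).
#'
#' @param demo deduplicated DEMO data.frame.
#' @param drugs,reactions,outcomes,therapies the other four tables.
#' @param report_ids character vector of `primaryid`s to keep; defaults
#'   to all ids in `demo`.
#' @return a `faers_case_set`: a list with elements `demo`, `drugs`,
#'   `reactions`, `outcomes`, `therapies` and `report_ids`.
#' @export
assemble_case_set <- function(demo, drugs, reactions, outcomes, therapies,
                              report_ids = demo$primaryid) {
  report_ids <- as.character(report_ids)
  keep_demo <- demo[demo$primaryid %in% report_ids, , drop = FALSE]
  present <- unique(keep_demo$primaryid)

  restrict <- function(x) x[x$primaryid %in% report_ids, , drop = FALSE]
  orphans <- 0L
  adopt <- function(x) {
    x <- restrict(x)
    orphan <- !(x$primaryid %in% present)
    orphans <<- orphans + sum(orphan)
    x[!orphan, , drop = FALSE]
  }
  cs <- structure(list(
    demo = keep_demo,
    drugs = adopt(drugs),
    reactions = adopt(reactions),
    outcomes = adopt(outcomes),
    therapies = adopt(therapies),
    report_ids = present
  ), class = "faers_case_set")
  attr(cs, "n_orphans") <- orphans
  if (orphans > 0L) message("assemble_case_set: dropped ", orphans, " orphan child record(s)")
  cs
}

#' @export
print.faers_case_set <- function(x, ...) {
  cat("FAERS case set:", length(x$report_ids), "reports\n")
  cat(sprintf("  drug records: %d | reactions: %d | outcomes: %d | therapies: %d\n",
              nrow(x$drugs), nrow(x$reactions), nrow(x$outcomes), nrow(x$therapies)))
  invisible(x)
}
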