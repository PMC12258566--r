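# End-to-end orchestration: raw (or synthetic) tables -> three result
# CSVs and a run manifest.

#' Run configuration for the full analysis
#'
#' @param input either a directory containing FAERS quarterly files
#'   (`DEMO*.txt`, `DRUG*.txt`, ...; several quarters are concatenated),
#'   a named list of the five tables, or a [synthetic_config()] (the
#'   tables are then generated in-memory).
#' @param quarters optional inclusive quarter window, e.g.
#'   `c("2021Q3", "2023Q4")`: reports whose FDA receipt date falls
#'   outside it are dropped before deduplication.
#' @param patterns,roles target-drug selection (see
#'   [select_target_reports()]).
#' @param pt_soc_map a [pt_soc_map], a path to one, or NULL (all PTs
#'   report under the `"UNMAPPED"` SOC, with a logged count).
#' @param min_count minimum case count for a PT row to be written to
#'   the report (default 3); flags are columns, never row filters, so
#'   sub-threshold statistics above the count floor remain inspectable.
#' @param top_n number of PT rows written (default 30), sorted by
#'   descending case count, ties alphabetical.
#' @param out_dir output directory, or NULL to skip writing.
#' @param seed RNG seed (used by the MGPS start jitter — none — and
#'   forwarded to a [synthetic_config()] input when it has none; kept
#'   in the manifest for reproducibility).
#' @return a `faers_run_config` list.
#' @export
run_config <- function(input, quarters = NULL,
                       patterns = c("ADUCANUMAB", "ADUHELM"), roles = "PS",
                       pt_soc_map = NULL, min_count = 3, top_n = 30,
                       out_dir = NULL, seed = 1) {
  stopifnot(min_count >= 1)
  if (!is.null(quarters)) {
    stopifnot(length(quarters) == 2L)
    if (.quarter_key(quarters[1L]) > .quarter_key(quarters[2L])) {
      stop("quarter range is not well-ordered: ", quarters[1L], " > ", quarters[2L])
    }
  }
  structure(list(input = input, quarters = quarters, patterns = patterns,
                 roles = roles, pt_soc_map = pt_soc_map,
                 min_count = min_count, top_n = top_n, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "faers_run_config")
}

.quarter_key <- function(q) {
  q <- toupper(gsub("[^0-9Q]", "", q))
  m <- regmatches(q, regexec("^([0-9]{4})Q([1-4])$", q))[[1L]]
  if (length(m) != 3L) stop("bad quarter string: ", q, " (expected e.g. 2023Q4)")
  as.integer(m[2L]) * 4L + as.integer(m[3L])
}

.quarter_of_date <- function(fda_dt) {
  y <- faers_date_year(fda_dt)
  p <- faers_date_prec(fda_dt)
  mth <- rep(NA_integer_, length(fda_dt))
  ok <- !is.na(p) & p >= 6L
  mth[ok] <- as.integer(substr(trimws(as.character(fda_dt[ok])), 5L, 6L))
  ifelse(is.na(y) | is.na(mth), NA_integer_, y * 4L + (mth - 1L) %/% 3L + 1L)
}

.read_input_tables <- function(input) {
  kinds <- c("DEMO", "DRUG", "REAC", "OUTC", "THER")
  if (inherits(input, "synthetic_config")) {
    return(list(tables = generate_reports(input)$tables,
                skipped = setNames(rep(0L, 5L), kinds)))
  }
  if (is.list(input) && all(kinds %in% names(input))) {
    return(list(tables = input[kinds], skipped = setNames(rep(0L, 5L), kinds)))
  }
  if (is.character(input) && length(input) == 1L && dir.exists(input)) {
    tables <- list()
    skipped <- setNames(integer(5L), kinds)
    for (kind in kinds) {
      files <- sort(list.files(input, pattern = paste0("^", kind, ".*\\.(txt|TXT)$"),
                               full.names = TRUE))
      if (!length(files)) stop("no ", kind, " file found in ", input)
      parts <- lapply(files, parse_faers_table, table = kind)
      skipped[kind] <- sum(vapply(parts, function(p) attr(p, "skipped"), integer(1L)))
      tables[[kind]] <- do.call(rbind, parts)
    }
    return(list(tables = tables, skipped = skipped))
  }
  stop("input must be a directory, a named list of tables, or a synthetic_config")
}

#' Run the full disproportionality analysis
#'
#' Executes parse -> quarter filter -> deduplicate -> target selection
#' -> case-set assembly -> PT and SOC pair counting -> the four
#' disproportionality algorithms with signal criteria -> descriptive
#' characteristics, and (when `out_dir` is set) writes
#' `characteristics.csv`, `soc_signals.csv`, `pt_signals.csv` and
#' `manifest.json`. Statistics are written rounded half-up to 2
#' decimals; full precision is retained in the returned objects.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with `characteristics`, `soc_signals`,
#'   `pt_signals` (full, unfiltered), `case_set`, `manifest`, and
#'   `paths` of any files written.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "faers_run_config"))
  set.seed(config$seed)
  inp <- .read_input_tables(config$input)
  tables <- inp$tables
  parsed <- vapply(tables, nrow, integer(1L))

  demo <- tables$DEMO
  if (!is.null(config$quarters)) {
    qk <- .quarter_of_date(demo$fda_dt)
    lo <- .quarter_key(config$quarters[1L]); hi <- .quarter_key(config$quarters[2L])
    demo <- demo[!is.na(qk) & qk >= lo & qk <= hi, , drop = FALSE]
  }
  n_before <- nrow(demo)
  demo <- deduplicate_cases(demo)
  n_after <- nrow(demo)

  target_ids <- select_target_reports(tables$DRUG, config$patterns, config$roles)
  target_ids <- intersect(target_ids, demo$primaryid)
  if (!length(target_ids)) warning("no reports match the target drug selection")

  target <- assemble_case_set(demo, tables$DRUG, tables$REAC, tables$OUTC,
                              tables$THER, target_ids)
  background <- assemble_case_set(demo, tables$DRUG, tables$REAC, tables$OUTC,
                                  tables$THER, setdiff(demo$primaryid, target_ids))

  map <- config$pt_soc_map
  if (is.character(map) && !inherits(map, "pt_soc_map")) map <- read_pt_soc_map(map)
  if (is.null(map)) {
    map <- pt_soc_map(character(), character())
    message("no PT->SOC map supplied: all PTs will report under UNMAPPED")
  }
  n_unmapped <- sum(lookup_soc(map, unique(normalize_pt(target$reactions$pt))) == "UNMAPPED")
  if (n_unmapped > 0L) message(n_unmapped, " target PT(s) not in the PT->SOC map (UNMAPPED)")

  empty_stats <- data.frame(
    event = character(), a = numeric(), ror = numeric(), ror_ci_low = numeric(),
    ror_ci_high = numeric(), prr = numeric(), prr_ci_low = numeric(),
    prr_ci_high = numeric(), chisq = numeric(), ic = numeric(), ic_sd = numeric(),
    ic_minus_2sd = numeric(), ebgm = numeric(), ebgm05 = numeric(),
    ebgm05_source = character(), ror_signal = logical(), prr_signal = logical(),
    bcpnn_signal = logical(), mgps_signal = logical(), stringsAsFactors = FALSE)
  if (length(target_ids)) {
    pt_counts <- count_pairs(target, background, map, level = "PT")
    soc_counts <- count_pairs(target, background, map, level = "SOC")
    pt_stats <- signal_stats(pt_counts, min_count = config$min_count)
    soc_stats <- signal_stats(soc_counts, min_count = config$min_count)
    characteristics <- summarize_characteristics(target, config$patterns, config$roles)
  } else {
    pt_stats <- soc_stats <- empty_stats
    characteristics <- summarize_characteristics(target, config$patterns, config$roles)
  }

  # report layout: PT table by descending case count, ties alphabetical
  pt_report <- pt_stats[order(-pt_stats$a, pt_stats$event), , drop = FALSE]
  pt_report <- pt_report[pt_report$a >= config$min_count, , drop = FALSE]
  pt_report <- utils::head(pt_report, config$top_n)
  soc_report <- soc_stats[order(-soc_stats$a, soc_stats$event), , drop = FALSE]

  manifest <- list(
    package = as.character(utils::packageVersion("faersignal")),
    seed = config$seed,
    quarters = config$quarters, patterns = config$patterns, roles = config$roles,
    min_count = config$min_count, top_n = config$top_n,
    rows_parsed = as.list(parsed), rows_skipped = as.list(inp$skipped),
    demo_in_window = n_before, demo_deduplicated = n_after,
    n_target_reports = length(target_ids),
    n_known_sex = attr(characteristics, "n_known_sex"),
    n_orphans_target = attr(target, "n_orphans")
  )

  paths <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    rounded <- function(df) {
      num <- vapply(df, is.numeric, logical(1L))
      df[num] <- lapply(df[num], round_half_up, digits = 2)
      df
    }
    paths["characteristics"] <- file.path(config$out_dir, "characteristics.csv")
    utils::write.csv(as.data.frame(characteristics), paths["characteristics"],
                     row.names = FALSE)
    paths["soc_signals"] <- file.path(config$out_dir, "soc_signals.csv")
    utils::write.csv(rounded(soc_report), paths["soc_signals"], row.names = FALSE)
    paths["pt_signals"] <- file.path(config$out_dir, "pt_signals.csv")
    utils::write.csv(rounded(pt_report), paths["pt_signals"], row.names = FALSE)
    paths["manifest"] <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
  }

  invisible(list(characteristics = characteristics, soc_signals = soc_stats,
                 pt_signals = pt_stats, pt_report = pt_report,
                 soc_report = soc_report, case_set = target,
                 manifest = manifest, paths = paths))
}
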