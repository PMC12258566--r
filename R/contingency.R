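# Report-PT pair counting and 2x2 contingency tables.

#' Normalize a MedDRA Preferred Term string
#'
#' Trims, collapses internal whitespace and case-folds so that lookups
#' and counts are insensitive to formatting. MedDRA version differences
#' are the caller's responsibility.
#'
#' @param x character vector of PT (or SOC) strings.
#' @return normalized character vector.
#' @export
normalize_pt <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

#' PT to SOC mapping
#'
#' MedDRA is licensed and cannot be bundled; the primary-SOC mapping is
#' supplied by the user as a two-column table (PT, SOC). Keys are
#' normalized with [normalize_pt()]. A PT mapped to two different SOCs
#' is a fatal error; looking up an unmapped PT yields the reserved SOC
#' `"UNMAPPED"`.
#'
#' @param pt,soc character vectors of equal length.
#' @return a `pt_soc_map`: named character vector (names = normalized
#'   PT, values = SOC).
#' @export
pt_soc_map <- function(pt, soc) {
  key <- normalize_pt(pt)
  soc <- trimws(as.character(soc))
  tab <- unique(data.frame(key = key, soc = soc, stringsAsFactors = FALSE))
  dup <- unique(tab$key[duplicated(tab$key)])
  if (length(dup)) {
    stop("conflicting SOC mappings for PT(s): ", paste(dup, collapse = ", "))
  }
  structure(setNames(tab$soc, tab$key), class = "pt_soc_map")
}

#' Load a PT to SOC map from delimited text
#'
#' @param path a CSV/TSV file (two columns: PT, SOC; header optional —
#'   a first row whose second field looks like a known SOC-style string
#'   is treated as data, a row `pt,soc` style header is skipped).
#' @param sep field separator, `","` by default.
#' @return a [pt_soc_map].
#' @export
read_pt_soc_map <- function(path, sep = ",") {
  df <- utils::read.csv(path, sep = sep, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    if (nrow(df) == 0L) return(pt_soc_map(character(), character()))
    stop("PT->SOC map must have two columns")
  }
  first <- normalize_pt(unlist(df[1L, 1:2]))
  if (all(first %in% c("pt", "soc", "preferred term", "preferred_term",
                       "system organ class", "system_organ_class"))) {
    df <- df[-1L, , drop = FALSE]
  }
  pt_soc_map(df[[1L]], df[[2L]])
}

#' Look up the SOC for PTs
#'
#' @param map a [pt_soc_map].
#' @param pt character vector of PTs (any formatting).
#' @return character vector of SOC names, `"UNMAPPED"` where absent.
#' @export
lookup_soc <- function(map, pt) {
  out <- unname(map[normalize_pt(pt)])
  out[is.na(out)] <- "UNMAPPED"
  out
}

#' Count report-event pairs for target versus background
#'
#' The counting unit is the unique (report, PT) pair: a PT listed twice
#' on one report counts once. At SOC level each *distinct PT* a report
#' carries contributes once, so one report can add more than 1 to a SOC
#' count — the convention under which a drug's SOC-level "case
#' reports" can exceed its number of reports.
#'
#' @param target,background [case_set][assemble_case_set]s with
#'   disjoint report-id sets (background = all other deduplicated
#'   reports, the case/non-case design).
#' @param map a [pt_soc_map]; required for `level = "SOC"`.
#' @param level `"PT"` or `"SOC"`.
#' @return a `faers_pair_counts` data.frame with columns `event`,
#'   `n_target`, `n_background`, sorted by event; attributes
#'   `N_target`, `N_background` (total pair counts) and `level`.
#' @export
count_pairs <- function(target, background, map = NULL, level = c("PT", "SOC")) {
  level <- match.arg(toupper(level[[1L]]), c("PT", "SOC"))
  if (length(intersect(target$report_ids, background$report_ids))) {
    stop("target and background report-id sets overlap")
  }
  if (level == "SOC" && is.null(map)) stop("a pt_soc_map is required at SOC level")

  pairs_of <- function(cs) {
    r <- cs$reactions
    if (nrow(r) == 0L) {
      return(data.table(primaryid = character(), event = character()))
    }
    dt <- data.table(primaryid = r$primaryid, pt_norm = normalize_pt(r$pt))
    dt <- dt[!is.na(pt_norm) & nzchar(pt_norm)]
    dt <- unique(dt)                    # unique (report, PT) pairs
    if (level == "SOC") dt[, event := lookup_soc(map, pt_norm)] else dt[, event := pt_norm]
    dt[, .(primaryid, event)]
  }
  tp <- pairs_of(target)
  bp <- pairs_of(background)
  # at SOC level a report counts once per distinct PT, i.e. pairs are
  # NOT re-uniqued after aggregation
  ct <- tp[, .(n_target = .N), by = event]
  cb <- bp[, .(n_background = .N), by = event]
  out <- merge(ct, cb, by = "event", all = TRUE)
  out[is.na(n_target), n_target := 0L]
  out[is.na(n_background), n_background := 0L]
  setorder(out, event)
  out <- as.data.frame(out)
  structure(out,
            N_target = nrow(tp), N_background = nrow(bp),
            level = level, class = c("faers_pair_counts", "data.frame"))
}

#' Construct a 2x2 contingency table
#'
#' Cells follow the usual disproportionality layout: `a` = target
#' reports with the event, `b` = target reports with other events,
#' `c` = background reports with the event, `d` = background with other
#' events. Derived margins `n = a+b+c+d`, `Cx = a+b`, `Cy = a+c`,
#' `Cxy = a`.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return a `contingency_2x2` (named numeric vector with elements
#'   `a`, `b`, `c`, `d`).
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c), d = as.numeric(d))
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("contingency cells must be non-negative numbers, got (",
         paste(cells, collapse = ", "), ")")
  }
  structure(cells, class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("2x2 table  a=%g b=%g c=%g d=%g  (n=%g, Cx=%g, Cy=%g)\n",
              x["a"], x["b"], x["c"], x["d"],
              sum(x), x["a"] + x["b"], x["a"] + x["c"]))
  invisible(x)
}

#' Build the 2x2 table for one event from pair counts
#'
#' `a = n_target(event)`, `b = N_target - a`, `c = n_background(event)`,
#' `d = N_background - c`. An event absent from the counts yields
#' `a = 0` (and `c = 0`).
#'
#' @param counts a [count_pairs()] result.
#' @param event event key (PT or SOC, any formatting).
#' @return a [contingency_2x2].
#' @export
build_table <- function(counts, event) {
  key <- normalize_pt(event)
  row <- match(key, normalize_pt(counts$event))
  a <- if (is.na(row)) 0 else counts$n_target[row]
  c_ <- if (is.na(row)) 0 else counts$n_background[row]
  b <- attr(counts, "N_target") - a
  d <- attr(counts, "N_background") - c_
  if (b < 0 || d < 0) stop("corrupt pair counts: negative derived cell for '", event, "'")
  contingency_2x2(a, b, c_, d)
}

# coerce (table | length-4 vector) to named cells
.as_cells <- function(t) {
  if (inherits(t, "contingency_2x2")) return(unclass(t))
  t <- as.numeric(t)
  if (length(t) != 4L || any(is.na(t)) || any(t < 0)) {
    stop("expected a contingency_2x2 or 4 non-negative counts (a, b, c, d)")
  }
  c(a = t[1L], b = t[2L], c = t[3L], d = t[4L])
}
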