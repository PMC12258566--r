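# Synthetic FAERS-format report generator with analytic ground truth.

.default_drug_catalog <- function() {
  data.frame(
    name = c("ADUCANUMAB", "DONEPEZIL", "MEMANTINE", "ASPIRIN",
             "LISINOPRIL", "ATORVASTATIN"),
    p = c(0.02, 0.30, 0.25, 0.40, 0.35, 0.45),
    role_ps = c(1.00, 0.30, 0.30, 0.15, 0.20, 0.20),
    role_ss = c(0.00, 0.20, 0.20, 0.20, 0.25, 0.25),
    role_c  = c(0.00, 0.40, 0.40, 0.55, 0.45, 0.45),
    role_i  = c(0.00, 0.10, 0.10, 0.10, 0.10, 0.10),
    stringsAsFactors = FALSE
  )
}

.default_event_catalog <- function() {
  nerv <- "Nervous system disorders"
  psy <- "Psychiatric disorders"
  gi <- "Gastrointestinal disorders"
  gen <- "General disorders and administration site conditions"
  inf <- "Infections and infestations"
  card <- "Cardiac disorders"
  inj <- "Injury, poisoning and procedural complications"
  data.frame(
    pt = c("Amyloid related imaging abnormality-oedema/effusion",
           "Amyloid related imaging abnormality-microhaemorrhages and haemosiderin deposits",
           "Cerebral microhaemorrhage", "Brain oedema", "Headache", "Dizziness",
           "Seizure", "Memory impairment", "Somnolence",
           "Confusional state", "Disorientation", "Anxiety", "Insomnia",
           "Nausea", "Diarrhoea", "Vomiting",
           "Fatigue", "Drug ineffective", "Pyrexia", "Gait disturbance",
           "Urinary tract infection", "Pneumonia",
           "Atrial fibrillation", "Cardiac failure",
           "Fall", "Head injury"),
    soc = c(nerv, nerv, nerv, nerv, nerv, nerv, nerv, nerv, nerv,
            psy, psy, psy, psy,
            gi, gi, gi,
            gen, gen, gen, gen,
            inf, inf,
            card, card,
            inj, inj),
    p = c(0.005, 0.004, 0.003, 0.003, 0.120, 0.090,
          0.020, 0.030, 0.025,
          0.040, 0.020, 0.050, 0.060,
          0.110, 0.080, 0.070,
          0.130, 0.100, 0.060, 0.025,
          0.050, 0.035,
          0.030, 0.020,
          0.060, 0.015),
    stringsAsFactors = FALSE
  )
}

.default_demographics <- function() {
  list(
    sex = c(F = 0.508, M = 0.448, UNK = 0.044),
    year = c("2021" = 0.0394, "2022" = 0.5174, "2023" = 0.4432),
    age = c("45~65" = 0.0603, "65~75" = 0.2367, ">=75" = 0.3318,
            Unknown = 0.3712),
    weight = c("<60" = 0.0812, "60~80" = 0.1717, ">=80" = 0.0974,
               Unknown = 0.6497),
    reporter = c(CN = 0.4316, MD = 0.3248, PH = 0.2367, Unknown = 0.0070),
    country = c(US = 0.9258, JP = 0.025, DE = 0.020, GB = 0.0292),
    outcome_rate = 252 / 431,
    outcome = c(OT = 0.5040, HO = 0.3690, DE = 0.0873, LT = 0.0278,
                DS = 0.0079, RI = 0.0040)
  )
}

.default_tto_model <- function() {
  list(p_therapy = 263 / 431, p_missing = 71 / 263,
       bucket_probs = c("<7" = 14, "7~28" = 8, "28~60" = 14, ">=60" = 156) / 192,
       max_days = 365)
}

#' Configuration for the synthetic report generator
#'
#' Defines a spontaneous-report database with known ground truth: drug
#' and event marginal reporting probabilities, demographic category
#' distributions, an outcome- and therapy-date model, a duplicate
#' rate, and injected drug-event signals. A signal is a multiplicative
#' relative reporting rate: for reports carrying the drug, the PT's
#' inclusion probability is multiplied by `rr` (clamped to 1) — the
#' simplest mechanism for which ROR and PRR both estimate `rr` in the
#' rare-event limit, keeping recovery tests analytic.
#'
#' Default demographic distributions mirror the published aducanumab
#' report-characteristics proportions, so synthetic descriptive output
#' resembles a real drug-safety profile; drug and event marginals are
#' set so a default-sized run yields a few hundred target reports.
#'
#' @param n_reports number of unique cases to generate.
#' @param drug_catalog data.frame with columns `name`, `p` (marginal
#'   inclusion probability) and role-code probabilities `role_ps`,
#'   `role_ss`, `role_c`, `role_i` (each row summing to 1).
#' @param event_catalog data.frame with columns `pt`, `soc`, `p`.
#' @param injected_signals data.frame with columns `drug`, `pt`, `rr`
#'   (relative reporting rate > 0), or NULL for a global null.
#' @param demographics list of category probability vectors (`sex`,
#'   `year`, `age`, `weight`, `reporter`, `country`), plus
#'   `outcome_rate` (mean outcome records per report) and `outcome`
#'   (code probabilities).
#' @param tto_model list with `p_therapy` (probability a target report
#'   carries a therapy record), `p_missing` (therapy start missing),
#'   `bucket_probs` (onset-delay bucket mixture) and `max_days`.
#' @param duplicate_rate fraction of cases additionally emitted as a
#'   later-dated revision (same `caseid`, incremented version).
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical output files.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_reports = 20000,
                             drug_catalog = .default_drug_catalog(),
                             event_catalog = .default_event_catalog(),
                             injected_signals = data.frame(
                               drug = "ADUCANUMAB",
                               pt = "Amyloid related imaging abnormality-oedema/effusion",
                               rr = 20),
                             demographics = .default_demographics(),
                             tto_model = .default_tto_model(),
                             duplicate_rate = 0.1,
                             seed = 1) {
  stopifnot(is.numeric(n_reports), length(n_reports) == 1L, n_reports >= 1)
  probs_ok <- function(p) all(is.finite(p)) && all(p >= 0) && all(p <= 1)
  if (!probs_ok(drug_catalog$p)) stop("drug marginal probabilities must be in [0, 1]")
  if (!probs_ok(event_catalog$p)) stop("event marginal probabilities must be in [0, 1]")
  roles <- as.matrix(drug_catalog[, c("role_ps", "role_ss", "role_c", "role_i")])
  if (!probs_ok(roles) || any(abs(rowSums(roles) - 1) > 1e-8)) {
    stop("role-code probabilities must be in [0, 1] and sum to 1 per drug")
  }
  if (!is.null(injected_signals) && nrow(injected_signals)) {
    if (any(!is.finite(injected_signals$rr)) || any(injected_signals$rr <= 0)) {
      stop("injected relative reporting rates must be > 0")
    }
    bad <- !(injected_signals$drug %in% drug_catalog$name) |
      !(injected_signals$pt %in% event_catalog$pt)
    if (any(bad)) stop("injected signal names must appear in the catalogs")
  }
  if (duplicate_rate < 0 || duplicate_rate > 1) stop("duplicate_rate must be in [0, 1]")
  structure(list(
    n_reports = as.integer(n_reports), drug_catalog = drug_catalog,
    event_catalog = event_catalog, injected_signals = injected_signals,
    demographics = demographics, tto_model = tto_model,
    duplicate_rate = duplicate_rate, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic FAERS config: %d reports, %d drugs, %d PTs, %d injected signal(s), seed %d\n",
              x$n_reports, nrow(x$drug_catalog), nrow(x$event_catalog),
              if (is.null(x$injected_signals)) 0L else nrow(x$injected_signals),
              x$seed))
  invisible(x)
}

# sample one category per row from a named probability vector
.sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic FAERS-format report database
#'
#' Draws `n_reports` cases with demographics, one-or-more drug records
#' with role codes, one-or-more reaction PTs (per-PT Bernoulli draws;
#' injected signals multiply the PT probability for reports carrying
#' the signal drug; a report that draws no drug gets the
#' highest-marginal drug, one that draws no PT gets a single PT from
#' the marginal distribution), outcome records, and therapy dates for
#' target-drug reports. A `duplicate_rate` fraction of cases is
#' re-emitted as a later revision with the same `caseid`.
#'
#' @param config a [synthetic_config()].
#' @return list with `tables` (named list of DEMO/DRUG/REAC/OUTC/THER
#'   data.frames in the canonical [parse_faers_table()] layout) and
#'   `truth` (the [ground_truth()] data.frame).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_reports
  dem <- config$demographics
  drugs <- config$drug_catalog
  events <- config$event_catalog
  inj <- config$injected_signals

  caseid <- as.character(10000000 + seq_len(n))
  primaryid <- paste0(caseid, "1")

  sex <- .sample_cat(n, dem$sex)
  year <- as.integer(.sample_cat(n, dem$year))
  fda <- as.Date(sprintf("%d-%02d-%02d", year,
                         sample(1:12, n, replace = TRUE),
                         sample(1:28, n, replace = TRUE)))
  event_date <- fda - sample(0:60, n, replace = TRUE)

  age_bin <- .sample_cat(n, dem$age)
  age <- rep(NA_real_, n)
  age[age_bin == "45~65"] <- runif(sum(age_bin == "45~65"), 45, 65)
  age[age_bin == "65~75"] <- runif(sum(age_bin == "65~75"), 65, 75)
  age[age_bin == ">=75"] <- runif(sum(age_bin == ">=75"), 75, 95)
  age <- floor(age)

  wt_bin <- .sample_cat(n, dem$weight)
  wt <- rep(NA_real_, n)
  wt[wt_bin == "<60"] <- runif(sum(wt_bin == "<60"), 40, 60)
  wt[wt_bin == "60~80"] <- runif(sum(wt_bin == "60~80"), 60, 80)
  wt[wt_bin == ">=80"] <- runif(sum(wt_bin == ">=80"), 80, 120)
  wt <- round(wt, 1)

  occp <- .sample_cat(n, dem$reporter)
  occp[occp == "Unknown"] <- NA_character_
  country <- .sample_cat(n, dem$country)

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, caseversion = 1L,
    fda_dt = format(fda, "%Y%m%d"), event_dt = format(event_date, "%Y%m%d"),
    age = age, age_cod = ifelse(is.na(age), NA_character_, "YR"),
    sex = sex, wt = wt, occp_cod = occp, reporter_country = country,
    stringsAsFactors = FALSE
  )

  # drug records: independent inclusion per catalog drug
  K <- nrow(drugs)
  incl <- matrix(FALSE, n, K)
  for (k in seq_len(K)) incl[, k] <- runif(n) < drugs$p[k]
  none <- rowSums(incl) == 0L
  incl[none, which.max(drugs$p)] <- TRUE
  drug_rows <- list()
  for (k in seq_len(K)) {
    idx <- which(incl[, k])
    if (!length(idx)) next
    role <- sample(c("PS", "SS", "C", "I"), length(idx), replace = TRUE,
                   prob = as.numeric(drugs[k, c("role_ps", "role_ss", "role_c", "role_i")]))
    drug_rows[[k]] <- data.frame(primaryid = primaryid[idx], kk = k,
                                 role_cod = role, drugname = drugs$name[k],
                                 prod_ai = drugs$name[k], stringsAsFactors = FALSE)
  }
  drug_tab <- as.data.table(do.call(rbind, drug_rows))
  setorder(drug_tab, primaryid, kk)
  drug_tab[, drug_seq := seq_len(.N), by = primaryid]
  drug <- as.data.frame(drug_tab[, .(primaryid, drug_seq, role_cod, drugname, prod_ai)])

  # reaction records: per-PT Bernoulli with injected multiplicative RR
  Ev <- nrow(events)
  reac_rows <- list()
  got_any <- rep(FALSE, n)
  for (e in seq_len(Ev)) {
    p_vec <- rep(events$p[e], n)
    if (!is.null(inj) && nrow(inj)) {
      for (s in which(inj$pt == events$pt[e])) {
        carrier <- incl[, match(inj$drug[s], drugs$name)]
        p_vec[carrier] <- pmin(1, p_vec[carrier] * inj$rr[s])
      }
    }
    hit <- runif(n) < p_vec
    got_any <- got_any | hit
    if (any(hit)) {
      reac_rows[[e]] <- data.frame(primaryid = primaryid[hit],
                                   pt = events$pt[e], stringsAsFactors = FALSE)
    }
  }
  if (any(!got_any)) {
    forced <- sample(events$pt, sum(!got_any), replace = TRUE,
                     prob = events$p / sum(events$p))
    reac_rows[[Ev + 1L]] <- data.frame(primaryid = primaryid[!got_any],
                                       pt = forced, stringsAsFactors = FALSE)
  }
  reac <- do.call(rbind, reac_rows)
  reac <- reac[order(reac$primaryid, reac$pt), , drop = FALSE]

  # outcome records
  n_out <- rpois(n, dem$outcome_rate)
  oidx <- rep(seq_len(n), n_out)
  outc <- data.frame(primaryid = primaryid[oidx],
                     outc_cod = .sample_cat(length(oidx), dem$outcome),
                     stringsAsFactors = FALSE)
  outc <- unique(outc[order(outc$primaryid, outc$outc_cod), , drop = FALSE])

  # therapy records for target-drug reports (first catalog drug is the
  # conventional target; therapies attach to its drug_seq)
  tm <- config$tto_model
  target_name <- drugs$name[1L]
  tgt <- drug[drug$drugname == target_name, c("primaryid", "drug_seq")]
  tgt <- tgt[!duplicated(tgt$primaryid), , drop = FALSE]
  has_ther <- runif(nrow(tgt)) < tm$p_therapy
  tgt <- tgt[has_ther, , drop = FALSE]
  if (nrow(tgt)) {
    bucket <- .sample_cat(nrow(tgt), tm$bucket_probs)
    delay <- integer(nrow(tgt))
    delay[bucket == "<7"] <- sample(0:6, sum(bucket == "<7"), replace = TRUE)
    delay[bucket == "7~28"] <- sample(7:27, sum(bucket == "7~28"), replace = TRUE)
    delay[bucket == "28~60"] <- sample(28:59, sum(bucket == "28~60"), replace = TRUE)
    delay[bucket == ">=60"] <- sample(60:tm$max_days, sum(bucket == ">=60"), replace = TRUE)
    ev_dt <- faers_date_day(demo$event_dt[match(tgt$primaryid, demo$primaryid)])
    start <- format(ev_dt - delay, "%Y%m%d")
    start[runif(nrow(tgt)) < tm$p_missing] <- NA_character_
    ther <- data.frame(primaryid = tgt$primaryid, drug_seq = tgt$drug_seq,
                       start_dt = start, end_dt = NA_character_,
                       stringsAsFactors = FALSE)
  } else {
    ther <- data.frame(primaryid = character(), drug_seq = integer(),
                       start_dt = character(), end_dt = character(),
                       stringsAsFactors = FALSE)
  }

  # duplicate revisions: same caseid, version 2, later fda date
  dup <- which(runif(n) < config$duplicate_rate)
  if (length(dup)) {
    dup_id <- paste0(caseid[dup], "2")
    demo2 <- demo[dup, , drop = FALSE]
    demo2$primaryid <- dup_id
    demo2$caseversion <- 2L
    demo2$fda_dt <- format(faers_date_day(demo2$fda_dt) + 30, "%Y%m%d")
    demo <- rbind(demo, demo2)
    clone <- function(x) {
      x2 <- x[x$primaryid %in% primaryid[dup], , drop = FALSE]
      x2$primaryid <- dup_id[match(x2$primaryid, primaryid[dup])]
      rbind(x, x2)
    }
    drug <- clone(drug); reac <- clone(reac); outc <- clone(outc); ther <- clone(ther)
  }

  ord <- function(x) x[do.call(order, unname(as.list(x))), , drop = FALSE]
  demo$age_years <- age_in_years(demo$age, demo$age_cod)
  demo$received_year <- faers_date_year(demo$fda_dt)
  tables <- list(DEMO = ord(demo), DRUG = ord(drug), REAC = ord(reac),
                 OUTC = ord(outc), THER = ord(ther))
  tables <- lapply(tables, function(x) { rownames(x) <- NULL; x })
  list(tables = tables, truth = ground_truth(config))
}

#' Expected 2x2 cells under a synthetic configuration
#'
#' Closed-form expectations of the contingency cells for one
#' (drug, PT) pair, with the pipeline's default selection rule
#' (role PS). Neglects the two rare forcing corrections (no-drug and
#' no-PT reports) and signal leakage through non-PS carriers, all of
#' which are second-order for the default catalogs.
#'
#' @param config a [synthetic_config()].
#' @param drug,pt catalog names (fatal if unknown).
#' @return named numeric `c(Ea, Eb, Ec, Ed)`.
#' @export
expected_table <- function(config, drug, pt) {
  drugs <- config$drug_catalog
  events <- config$event_catalog
  kd <- match(drug, drugs$name)
  ke <- match(pt, events$pt)
  if (is.na(kd)) stop("unknown drug: ", drug)
  if (is.na(ke)) stop("unknown pt: ", pt)
  inj <- config$injected_signals
  rr_for <- function(d, e) {
    if (is.null(inj) || !nrow(inj)) return(1)
    hit <- inj$drug == d & inj$pt == e
    if (any(hit)) inj$rr[which(hit)[1L]] else 1
  }
  n <- config$n_reports
  p_sel <- drugs$p[kd] * drugs$role_ps[kd]
  p_t <- vapply(seq_len(nrow(events)),
                function(e) min(1, events$p[e] * rr_for(drug, events$pt[e])),
                numeric(1L))
  Ea <- n * p_sel * p_t[ke]
  Eb <- n * p_sel * sum(p_t) - Ea
  Ec <- n * (1 - p_sel) * events$p[ke]
  Ed <- n * (1 - p_sel) * sum(events$p) - Ec
  c(Ea = Ea, Eb = Eb, Ec = Ec, Ed = Ed)
}

#' Ground truth table for a synthetic configuration
#'
#' One row per (drug, PT) pair in the catalogs: the generating relative
#' reporting rate (1 unless injected) and the expected contingency
#' cells from [expected_table()].
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `drug`, `pt`, `rr`, `Ea`, `Eb`,
#'   `Ec`, `Ed`.
#' @export
ground_truth <- function(config) {
  grid <- expand.grid(drug = config$drug_catalog$name,
                      pt = config$event_catalog$pt,
                      stringsAsFactors = FALSE)
  inj <- config$injected_signals
  grid$rr <- 1
  if (!is.null(inj) && nrow(inj)) {
    for (s in seq_len(nrow(inj))) {
      grid$rr[grid$drug == inj$drug[s] & grid$pt == inj$pt[s]] <- inj$rr[s]
    }
  }
  cells <- t(mapply(function(d, p) expected_table(config, d, p),
                    grid$drug, grid$pt))
  cbind(grid, as.data.frame(cells, row.names = seq_len(nrow(grid))))
}

#' Write the five synthetic tables as FAERS quarterly files
#'
#' @param tables the `tables` element of [generate_reports()].
#' @param dir output directory (created if needed).
#' @param quarter quarter tag used in the conventional file names
#'   (`DEMO23Q4.txt`, ...).
#' @return named character vector of file paths.
#' @export
write_faers_tables <- function(tables, dir, quarter = "23Q4") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (kind in names(tables)) {
    path <- file.path(dir, paste0(kind, quarter, ".txt"))
    write_faers_table(tables[[kind]], path, kind)
    paths[kind] <- path
  }
  paths
}
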