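# Disproportionality statistics on a 2x2 contingency table.
#
# Conventions: a = target reports with the event, b = target with other
# events, c = background with the event, d = background with other
# events; n = a+b+c+d, Cx = a+b, Cy = a+c.

#' Reporting odds ratio with Wald 95% CI
#'
#' `ROR = ad / bc`, with the log-scale Wald interval
#' `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. No zero-cell
#' continuity correction is applied: a zero in `a` gives `ROR = 0`
#' (with undefined CI), while `b = 0` or `c = 0` makes the ratio
#' undefined — returned as `NA` with a `reason`, never an exception.
#'
#' @param t a [contingency_2x2] or numeric `c(a, b, c, d)`.
#' @param conf_z normal quantile for the interval (1.96 = 95%).
#' @return list with `ror`, `ci_low`, `ci_high`, and `reason` (`NA`
#'   unless the ratio is undefined).
#' @export
ror_stats <- function(t, conf_z = 1.96) {
  x <- .as_cells(t)
  a <- x["a"]; b <- x["b"]; c <- x["c"]; d <- x["d"]
  if (b == 0 || c == 0) {
    return(list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                reason = sprintf("undefined: %s = 0", if (b == 0) "b" else "c")))
  }
  ror <- unname((a * d) / (b * c))
  if (a == 0 || d == 0) {
    return(list(ror = ror, ci_low = NA_real_, ci_high = NA_real_,
                reason = "zero cell: CI undefined"))
  }
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror,
       ci_low = unname(exp(log(ror) - conf_z * se)),
       ci_high = unname(exp(log(ror) + conf_z * se)),
       reason = NA_character_)
}

#' Proportional reporting ratio, CI and chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with the log-scale Wald interval
#' `exp(ln PRR +/- 1.96 * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#'
#' The accompanying chi-square is, by default, the Yates
#' continuity-corrected statistic
#' `(|ad - bc| - n/2)^2 n / [(a+b)(a+c)(c+d)(b+d)]`, clamped to 0 when
#' the correction overshoots (`|ad - bc| < n/2`). `correct = FALSE`
#' gives the uncorrected Pearson statistic, which some published signal
#' tables report even when they state the corrected formula.
#'
#' @inheritParams ror_stats
#' @param correct apply the Yates continuity correction (default TRUE).
#' @return list with `prr`, `ci_low`, `ci_high`, `chisq`, `reason`.
#' @export
prr_stats <- function(t, conf_z = 1.96, correct = TRUE) {
  x <- .as_cells(t)
  a <- x["a"]; b <- x["b"]; c <- x["c"]; d <- x["d"]
  chisq <- chisq_2x2(t, correct = correct)
  if (c == 0 || (a + b) == 0) {
    return(list(prr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                chisq = chisq,
                reason = sprintf("undefined: %s", if (c == 0) "c = 0" else "a + b = 0")))
  }
  prr <- unname((a / (a + b)) / (c / (c + d)))
  if (a == 0) {
    return(list(prr = prr, ci_low = NA_real_, ci_high = NA_real_,
                chisq = chisq, reason = "zero cell: CI undefined"))
  }
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  list(prr = prr,
       ci_low = unname(exp(log(prr) - conf_z * se)),
       ci_high = unname(exp(log(prr) + conf_z * se)),
       chisq = chisq,
       reason = NA_character_)
}

#' Chi-square statistic of a 2x2 table
#'
#' @inheritParams prr_stats
#' @return the (optionally Yates-corrected, clamped at 0) chi-square.
#' @export
chisq_2x2 <- function(t, correct = TRUE) {
  x <- .as_cells(t)
  a <- x["a"]; b <- x["b"]; c <- x["c"]; d <- x["d"]
  n <- a + b + c + d
  marg <- (a + b) * (a + c) * (c + d) * (b + d)
  if (marg == 0) return(NA_real_)
  num <- abs(a * d - b * c) - (if (correct) n / 2 else 0)
  if (num < 0) return(0)
  unname(num^2 * n / marg)
}

#' BCPNN hyperparameters
#'
#' Prior pseudo-counts of the Bayesian confidence propagation neural
#' network: `alpha1 = beta1 = 1` (marginal pseudo-counts),
#' `alpha = beta = 2` (prior totals), `gamma11 = 1` (joint
#' pseudo-count). The joint prior scale `gamma` is derived per table as
#' `gamma11 (C+alpha)(C+beta) / [(Cx+alpha1)(Cy+beta1)]`, which centres
#' the prior on independence so the information component is exactly 0
#' for a perfectly independent table.
#'
#' `smoothing = FALSE` sets every pseudo-count to zero, collapsing the
#' estimator to the unsmoothed `IC = log2(a n / (Cx Cy))` — the
#' maximum-likelihood observed/expected ratio that many published FAERS
#' signal tables actually contain (the smoothed estimator is bounded
#' near `log2(a + 1)` and cannot produce the very large IC values seen
#' for rare-background events).
#'
#' @param alpha1,beta1,alpha,beta,gamma11 non-negative pseudo-counts.
#' @param smoothing logical; `FALSE` zeroes all pseudo-counts.
#' @return a `bcpnn_hyperparams` list.
#' @export
bcpnn_hyperparams <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                              gamma11 = 1, smoothing = TRUE) {
  if (!smoothing) alpha1 <- beta1 <- alpha <- beta <- gamma11 <- 0
  h <- list(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta,
            gamma11 = gamma11)
  if (any(vapply(h, function(v) !is.numeric(v) || length(v) != 1L || is.na(v) || v < 0,
                 logical(1L)))) {
    stop("BCPNN hyperparameters must be single non-negative numbers")
  }
  structure(h, class = "bcpnn_hyperparams")
}

#' BCPNN information component
#'
#' Posterior expectation and variance of the information component
#' `IC = log2 P(drug, event) / [P(drug) P(event)]` under
#' Dirichlet-multinomial priors:
#' \deqn{E(IC) = \log_2 \frac{(C_{xy}+\gamma_{11})(C+\alpha)(C+\beta)}
#'   {(C+\gamma)(C_x+\alpha_1)(C_y+\beta_1)}}
#' with \eqn{\gamma = \gamma_{11}(C+\alpha)(C+\beta) /
#' [(C_x+\alpha_1)(C_y+\beta_1)]}, and `V(IC)` the standard three-term
#' delta-method sum divided by \eqn{(\ln 2)^2}. The conservative signal
#' bound is `E(IC) - 2 sqrt(V(IC))`.
#'
#' With `bcpnn_hyperparams(smoothing = FALSE)` the expectation reduces
#' to the unsmoothed `log2(a n / (Cx Cy))` (see [bcpnn_hyperparams()]).
#'
#' @inheritParams ror_stats
#' @param hyper a [bcpnn_hyperparams].
#' @return list with `ic` (bits), `ic_sd`, `ic_minus_2sd`, and the
#'   derived `gamma`.
#' @export
bcpnn_stats <- function(t, hyper = bcpnn_hyperparams()) {
  x <- .as_cells(t)
  a <- x["a"]
  C <- sum(x); Cx <- x["a"] + x["b"]; Cy <- x["a"] + x["c"]
  a1 <- hyper$alpha1; b1 <- hyper$beta1
  al <- hyper$alpha; be <- hyper$beta; g11 <- hyper$gamma11
  den_marg <- (Cx + a1) * (Cy + b1)
  if (den_marg == 0 || C == 0) {
    return(list(ic = NA_real_, ic_sd = NA_real_, ic_minus_2sd = NA_real_,
                gamma = NA_real_))
  }
  g <- g11 * (C + al) * (C + be) / den_marg
  ic <- unname(log2(((a + g11) * (C + al) * (C + be)) / ((C + g) * den_marg)))
  v <- ((C - a + g - g11) / ((a + g11) * (1 + C + g)) +
        (C - Cx + al - a1) / ((Cx + a1) * (1 + C + al)) +
        (C - Cy + be - b1) / ((Cy + b1) * (1 + C + be))) / log(2)^2
  ic_sd <- unname(sqrt(v))
  list(ic = ic, ic_sd = ic_sd, ic_minus_2sd = ic - 2 * ic_sd, gamma = unname(g))
}

#' Information-component-based EBGM
#'
#' The shrinkage-adjusted observed/expected ratio derived from the
#' information component: `EBGM = 2^IC` and, by default,
#' `EBGM05 = 2^(IC - 1.645 sd(IC))` (a one-sided 5% bound on the same
#' scale). The full DuMouchel gamma-Poisson estimator is available
#' separately as [mgps_fit()] and is never silently mixed with this
#' one; the result carries its `estimator` label.
#'
#' @inheritParams bcpnn_stats
#' @return list with `ebgm`, `ebgm05` and `estimator = "ic"`.
#' @export
ebgm_stats <- function(t, hyper = bcpnn_hyperparams()) {
  bc <- bcpnn_stats(t, hyper)
  list(ebgm = 2^bc$ic, ebgm05 = 2^(bc$ic - 1.645 * bc$ic_sd), estimator = "ic")
}

#' Apply the standard signal criteria
#'
#' Conjunctive criteria, each requiring at least 3 target cases:
#' * `ror_signal`: `a >= 3` and `ROR >= 2` and ROR 95% CI lower bound > 1;
#' * `prr_signal`: `a >= 3` and `PRR >= 2` and `chi-square >= 4`;
#' * `bcpnn_signal`: `a >= 3` and `IC - 2SD > 0`;
#' * `mgps_signal`: `a >= 3` and `EBGM05 >= 2` (the field-standard
#'   MGPS criterion).
#'
#' `NA` statistics (undefined ratios) never satisfy a criterion.
#'
#' @param stats a data.frame with columns `a`, `ror`, `ror_ci_low`,
#'   `prr`, `chisq`, `ic_minus_2sd`, `ebgm05` (e.g. from
#'   [signal_stats()]).
#' @param min_count minimum case count (default 3).
#' @return `stats` with logical columns `ror_signal`, `prr_signal`,
#'   `bcpnn_signal`, `mgps_signal` added/replaced.
#' @export
evaluate_signals <- function(stats, min_count = 3) {
  ok <- function(x) !is.na(x) & x
  base <- stats$a >= min_count
  stats$ror_signal <- base & ok(stats$ror >= 2) & ok(stats$ror_ci_low > 1)
  stats$prr_signal <- base & ok(stats$prr >= 2) & ok(stats$chisq >= 4)
  stats$bcpnn_signal <- base & ok(stats$ic_minus_2sd > 0)
  stats$mgps_signal <- base & ok(stats$ebgm05 >= 2)
  stats
}

#' Full per-event disproportionality statistics
#'
#' Builds the 2x2 table for every event in `counts` and computes all
#' four algorithms plus the signal flags. The EBGM column is the
#' information-component estimator `2^IC`; `ebgm05` comes from the
#' DuMouchel posterior ([mgps_fit()]) when `mgps = TRUE` and the prior
#' fit succeeds, else from the IC-based bound — the `ebgm05_source`
#' column says which.
#'
#' @param counts a [count_pairs()] result.
#' @param hyper a [bcpnn_hyperparams] used for IC and `2^IC`.
#' @param mgps fit the DuMouchel gamma mixture across all events for
#'   `ebgm05` (default TRUE when there are at least `mgps_min_events`
#'   events).
#' @param mgps_min_events minimum number of events for a stable prior
#'   fit (default 50).
#' @param min_count minimum case count for the flags.
#' @param correct Yates-correct the chi-square (default TRUE).
#' @return a data.frame (one row per event) with columns `event`, `a`,
#'   `ror`, `ror_ci_low`, `ror_ci_high`, `prr`, `prr_ci_low`,
#'   `prr_ci_high`, `chisq`, `ic`, `ic_sd`, `ic_minus_2sd`, `ebgm`,
#'   `ebgm05`, `ebgm05_source` and the four `_signal` flags.
#' @export
signal_stats <- function(counts, hyper = bcpnn_hyperparams(), mgps = TRUE,
                         mgps_min_events = 50, min_count = 3, correct = TRUE) {
  events <- counts$event
  rows <- lapply(events, function(ev) {
    tab <- build_table(counts, ev)
    r <- ror_stats(tab)
    p <- prr_stats(tab, correct = correct)
    bc <- bcpnn_stats(tab, hyper)
    data.frame(
      event = ev, a = unname(tab["a"]),
      ror = r$ror, ror_ci_low = r$ci_low, ror_ci_high = r$ci_high,
      prr = p$prr, prr_ci_low = p$ci_low, prr_ci_high = p$ci_high,
      chisq = p$chisq,
      ic = bc$ic, ic_sd = bc$ic_sd, ic_minus_2sd = bc$ic_minus_2sd,
      ebgm = 2^bc$ic, ebgm05 = 2^(bc$ic - 1.645 * bc$ic_sd),
      ebgm05_source = "ic",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (isTRUE(mgps) && nrow(out) >= mgps_min_events) {
    fit <- tryCatch(mgps_fit(counts), warning = function(w) NULL,
                    error = function(e) NULL)
    if (!is.null(fit)) {
      idx <- match(out$event, fit$event)
      got <- !is.na(idx)
      out$ebgm05[got] <- fit$ebgm05[idx[got]]
      out$ebgm05_source[got] <- "mgps"
    }
  }
  evaluate_signals(out, min_count = min_count)
}
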