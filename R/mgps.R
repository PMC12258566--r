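# DuMouchel multi-item gamma-Poisson shrinker (MGPS).
#
# Observed counts a_i are modelled as Poisson(lambda_i * E_i) with
# lambda drawn from a two-component gamma mixture prior
#   lambda ~ w Gamma(a1, b1) + (1-w) Gamma(a2, b2)   (rate form),
# fitted by maximum marginal likelihood over all events of a run. The
# marginal of a is then a mixture of negative binomials, and the
# posterior of lambda a mixture of gammas, giving
#   EBGM  = exp E[ln lambda | a]   (empirical Bayes geometric mean)
#   EBGM05 = 5th percentile of the posterior.

.mgps_nll <- function(par, a, E) {
  a1 <- exp(par[1L]); b1 <- exp(par[2L])
  a2 <- exp(par[3L]); b2 <- exp(par[4L])
  w <- plogis(par[5L])
  f1 <- dnbinom(a, size = a1, prob = b1 / (b1 + E))
  f2 <- dnbinom(a, size = a2, prob = b2 / (b2 + E))
  ll <- log(w * f1 + (1 - w) * f2 + 1e-300)
  -sum(ll)
}

#' Fit the DuMouchel gamma-Poisson shrinker across events
#'
#' Fits the two-component gamma mixture prior for the relative
#' reporting rate by maximum marginal likelihood over all events'
#' (observed count `a`, expected count `E = Cx * Cy / n`) pairs, then
#' returns the empirical Bayes geometric mean `EBGM` and its 5th
#' percentile `EBGM05` per event. This is the full MGPS estimator,
#' exposed as an alternative to the information-component
#' [ebgm_stats()]; the two are never silently mixed.
#'
#' @param x either a [count_pairs()] result, a list of
#'   [contingency_2x2] tables (named by event), or a data.frame with
#'   columns `event`, `a`, `E`.
#' @param start starting values `(alpha1, beta1, alpha2, beta2, w)` for
#'   the prior fit (DuMouchel's conventional start).
#' @return a data.frame with columns `event`, `a`, `E`, `ebgm`,
#'   `ebgm05`; the fitted prior is attached as attribute `prior`
#'   (`alpha1`, `beta1`, `alpha2`, `beta2`, `w`, `convergence`).
#'   A degenerate fit (boundary parameters or failed optimisation)
#'   raises a warning and falls back to the IC-based estimator from
#'   [ebgm_stats()] with zero smoothing, labelled by attribute
#'   `estimator = "ic-fallback"`.
#' @references DuMouchel W. (1999) Bayesian data mining in large
#'   frequency tables, with an application to the FDA spontaneous
#'   reporting system. The American Statistician 53(3):177-190.
#' @export
mgps_fit <- function(x, start = c(0.2, 0.1, 2, 4, 1 / 3)) {
  df <- .as_ae_frame(x)
  a <- df$a; E <- df$E

  fallback <- function(msg) {
    warning("mgps_fit: ", msg, "; falling back to the IC-based estimator")
    ic <- log2(pmax(a, 1e-12) / pmax(E, 1e-300))
    # crude lower bound on the raw scale, labelled as fallback
    sd <- sqrt(1 / pmax(a, 0.5)) / log(2)
    out <- data.frame(event = df$event, a = a, E = E,
                      ebgm = 2^ic, ebgm05 = 2^(ic - 1.645 * sd),
                      stringsAsFactors = FALSE)
    attr(out, "estimator") <- "ic-fallback"
    out
  }
  if (nrow(df) < 2L) return(fallback("needs at least 2 events"))

  par0 <- c(log(start[1L]), log(start[2L]), log(start[3L]), log(start[4L]),
            qlogis(start[5L]))
  fit <- tryCatch(
    optim(par0, .mgps_nll, a = a, E = E, method = "L-BFGS-B",
          lower = rep(-12, 5L), upper = rep(12, 5L),
          control = list(maxit = 500)),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$value) || fit$convergence != 0) {
    return(fallback("optimisation failed"))
  }
  par <- fit$par
  a1 <- exp(par[1L]); b1 <- exp(par[2L])
  a2 <- exp(par[3L]); b2 <- exp(par[4L])
  w <- plogis(par[5L])
  # a component that carries weight must be interior; a vanished mixing
  # weight just collapses the prior to one gamma, which is fine
  at_edge <- function(p) any(abs(p) >= 12 - 1e-6)
  if ((w > 1e-3 && at_edge(par[1:2])) || (w < 1 - 1e-3 && at_edge(par[3:4]))) {
    return(fallback("degenerate fit (boundary parameters)"))
  }

  # posterior: mixture of Gamma(aj + a, bj + E) with weights Qj
  f1 <- dnbinom(a, size = a1, prob = b1 / (b1 + E))
  f2 <- dnbinom(a, size = a2, prob = b2 / (b2 + E))
  Q1 <- w * f1 / (w * f1 + (1 - w) * f2 + 1e-300)
  elog <- Q1 * (digamma(a1 + a) - log(b1 + E)) +
    (1 - Q1) * (digamma(a2 + a) - log(b2 + E))
  ebgm <- exp(elog)

  ebgm05 <- vapply(seq_along(a), function(i) {
    cdf <- function(q) {
      Q1[i] * pgamma(q, shape = a1 + a[i], rate = b1 + E[i]) +
        (1 - Q1[i]) * pgamma(q, shape = a2 + a[i], rate = b2 + E[i])
    }
    lo <- min(qgamma(0.0005, shape = a1 + a[i], rate = b1 + E[i]),
              qgamma(0.0005, shape = a2 + a[i], rate = b2 + E[i]))
    hi <- max(qgamma(0.9995, shape = a1 + a[i], rate = b1 + E[i]),
              qgamma(0.9995, shape = a2 + a[i], rate = b2 + E[i]))
    if (!is.finite(lo) || lo <= 0) lo <- 1e-12
    tryCatch(uniroot(function(q) cdf(q) - 0.05, c(lo, hi), tol = 1e-10)$root,
             error = function(e) NA_real_)
  }, numeric(1L))

  out <- data.frame(event = df$event, a = a, E = E, ebgm = ebgm,
                    ebgm05 = ebgm05, stringsAsFactors = FALSE)
  attr(out, "estimator") <- "mgps"
  attr(out, "prior") <- list(alpha1 = a1, beta1 = b1, alpha2 = a2, beta2 = b2,
                             w = w, convergence = fit$convergence)
  out
}

# normalize mgps_fit inputs to data.frame(event, a, E)
.as_ae_frame <- function(x) {
  if (inherits(x, "faers_pair_counts")) {
    Nt <- attr(x, "N_target"); Nb <- attr(x, "N_background")
    n <- Nt + Nb
    a <- x$n_target
    Cy <- x$n_target + x$n_background
    return(data.frame(event = x$event, a = a, E = Nt * Cy / n,
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("a", "E") %in% names(x)))
    ev <- if ("event" %in% names(x)) x$event else as.character(seq_len(nrow(x)))
    return(data.frame(event = ev, a = x$a, E = x$E, stringsAsFactors = FALSE))
  }
  if (is.list(x)) {
    ev <- names(x)
    if (is.null(ev)) ev <- as.character(seq_along(x))
    cells <- lapply(x, .as_cells)
    a <- vapply(cells, function(z) z["a"], numeric(1L))
    E <- vapply(cells, function(z) {
      n <- sum(z)
      (z["a"] + z["b"]) * (z["a"] + z["c"]) / n
    }, numeric(1L))
    return(data.frame(event = ev, a = unname(a), E = unname(E),
                      stringsAsFactors = FALSE))
  }
  stop("cannot interpret input to mgps_fit")
}
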