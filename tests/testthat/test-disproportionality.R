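# Hand-arithmetic oracles for the (3, 7, 30, 960) table are written as
# literal formula transcriptions, independent of the implementation path.

test_that("ROR matches hand arithmetic and is 1 on symmetric tables", {
  r <- ror_stats(c(10, 10, 10, 10))
  expect_equal(r$ror, 1)
  expect_equal(r$ci_low, exp(-1.96 * sqrt(0.4)))

  r <- ror_stats(c(3, 7, 30, 960))
  expect_equal(r$ror, 2880 / 210)
  se <- sqrt(1 / 3 + 1 / 7 + 1 / 30 + 1 / 960)
  expect_equal(r$ci_low, exp(log(2880 / 210) - 1.96 * se))
  expect_equal(r$ci_high, exp(log(2880 / 210) + 1.96 * se))
  expect_true(r$ci_low <= r$ror && r$ror <= r$ci_high)
})

test_that("undefined ROR carries a reason instead of throwing", {
  r <- ror_stats(c(3, 0, 30, 960))
  expect_true(is.na(r$ror))
  expect_match(r$reason, "b = 0")
  r <- ror_stats(c(0, 7, 30, 960))
  expect_equal(r$ror, 0)          # zero numerator is a value, CI undefined
  expect_true(is.na(r$ci_low))
})

test_that("PRR and Yates chi-square match hand arithmetic, with clamping", {
  p <- prr_stats(c(10, 90, 100, 900))
  expect_equal(p$prr, 1)
  expect_equal(p$chisq, 0)        # |ad - bc| = 0 < n/2: clamped

  p <- prr_stats(c(3, 7, 30, 960))
  expect_equal(p$prr, (3 / 10) / (30 / 990))
  expect_equal(p$chisq, (abs(3 * 960 - 7 * 30) - 500)^2 * 1000 /
                 (10 * 33 * 990 * 967))
  se <- sqrt(1 / 3 - 1 / 10 + 1 / 30 - 1 / 990)
  expect_equal(p$ci_low, exp(log(9.9) - 1.96 * se))

  expect_true(is.na(prr_stats(c(3, 7, 0, 990))$prr))
})

test_that("chi-square agrees with the stats::chisq.test oracle, both corrected and not", {
  for (cells in random_tables(100, min_cell = 1, max_cell = 80, seed = 9)) {
    m <- matrix(cells, 2, 2, byrow = TRUE)
    for (corr in c(TRUE, FALSE)) {
      ours <- chisq_2x2(cells, correct = corr)
      ref <- suppressWarnings(stats::chisq.test(m, correct = corr)$statistic)
      expect_equal(ours, unname(ref), tolerance = 1e-12)
    }
  }
})

test_that("BCPNN IC is exactly 0 at symmetric independence and matches the formula oracle", {
  expect_identical(bcpnn_stats(c(25, 25, 25, 25))$ic, 0)

  # independent transcription of the posterior-expectation formula
  g <- 1 * 1002 * 1002 / (11 * 34)
  expected_ic <- log2(4 * 1002 * 1002 / ((1000 + g) * 11 * 34))
  bc <- bcpnn_stats(c(3, 7, 30, 960))
  expect_equal(bc$ic, expected_ic, tolerance = 1e-12)
  expect_equal(bc$gamma, g)
  v <- ((1000 - 3 + g - 1) / (4 * (1001 + g)) +
          (1000 - 10 + 1) / (11 * 1003) +
          (1000 - 33 + 1) / (34 * 1003)) / log(2)^2
  expect_equal(bc$ic_sd, sqrt(v), tolerance = 1e-12)
  expect_equal(bc$ic_minus_2sd, bc$ic - 2 * bc$ic_sd)
})

test_that("zero smoothing reduces the IC to the unsmoothed log2 observed/expected", {
  h0 <- bcpnn_hyperparams(smoothing = FALSE)
  for (cells in random_tables(25, min_cell = 1, seed = 2)) {
    a <- cells[1]; n <- sum(cells)
    cx <- cells[1] + cells[2]; cy <- cells[1] + cells[3]
    expect_equal(bcpnn_stats(cells, h0)$ic, log2(a * n / (cx * cy)),
                 tolerance = 1e-12)
  }
})

test_that("the smoothed IC shrinks: 2^IC lies between 1 and the raw ratio", {
  # the +/-1 pseudo-counts can nudge a near-independent table either
  # way, so the direction is asserted where the raw ratio is away from 1
  for (cells in random_tables(60, min_cell = 2, max_cell = 200, seed = 3)) {
    a <- cells[1]; n <- sum(cells)
    raw <- a * n / ((cells[1] + cells[2]) * (cells[1] + cells[3]))
    if (abs(log2(raw)) < 0.35) next
    shrunk <- 2^bcpnn_stats(cells)$ic
    expect_true((shrunk > min(1, raw)) && (shrunk < max(1, raw)),
                info = paste(cells, collapse = ","))
  }
})

test_that("ROR, PRR and IC increase strictly in a with margins fixed", {
  for (cells in random_tables(25, min_cell = 3, max_cell = 80, seed = 4)) {
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    up <- c(a + 1, b - 1, c - 1, d + 1)   # same n, Cx, Cy
    expect_gt(ror_stats(up)$ror, ror_stats(cells)$ror)
    expect_gt(prr_stats(up)$prr, prr_stats(cells)$prr)
    expect_gt(bcpnn_stats(up)$ic, bcpnn_stats(cells)$ic)
  }
})

test_that("ROR and PRR agree in the rare-exposure regime", {
  set.seed(6)
  for (i in 1:40) {
    a <- sample(3:20, 1); c <- sample(5:50, 1)
    b <- 100 * a + sample(0:500, 1)
    d <- 100 * c + sample(0:5000, 1)
    r <- ror_stats(c(a, b, c, d))$ror
    p <- prr_stats(c(a, b, c, d))$prr
    expect_lt(abs(r - p) / p, 0.02)
  }
})

test_that("the IC-based EBGM is the composition 2^IC with a labelled estimator", {
  e <- ebgm_stats(c(25, 25, 25, 25))
  expect_equal(e$ebgm, 1)
  bc <- bcpnn_stats(c(3, 7, 30, 960))
  e <- ebgm_stats(c(3, 7, 30, 960))
  expect_equal(e$ebgm, 2^bc$ic)
  expect_equal(e$ebgm05, 2^(bc$ic - 1.645 * bc$ic_sd))
  expect_equal(e$estimator, "ic")
})

test_that("signal criteria are conjunctions gated on a >= 3", {
  stats <- data.frame(
    event = c("strong", "weak-ror", "rare"),
    a = c(559, 76, 2),
    ror = c(16.08, 1.38, 50), ror_ci_low = c(14.19, 1.09, 2),
    prr = c(7.62, 1.35, 50), chisq = c(3470.01, 7.22, 10),
    ic_minus_2sd = c(2.78, 0.1, 1), ebgm05 = c(6.86, 1.11, 10))
  out <- evaluate_signals(stats)
  expect_true(out$ror_signal[1] && out$prr_signal[1] && out$bcpnn_signal[1] &&
                out$mgps_signal[1])
  # ROR below 2 fails the criterion even with CI lower bound above 1
  expect_false(out$ror_signal[2])
  expect_true(out$bcpnn_signal[2])
  # below the minimum case count nothing is flagged
  expect_false(any(unlist(out[3, c("ror_signal", "prr_signal",
                                   "bcpnn_signal", "mgps_signal")])))
})

test_that("removing a sub-condition can only grow the flagged set", {
  set.seed(8)
  cells <- random_tables(80, min_cell = 1, max_cell = 40, seed = 8)
  stats <- do.call(rbind, lapply(seq_along(cells), function(i) {
    tb <- cells[[i]]
    r <- ror_stats(tb); p <- prr_stats(tb); bc <- bcpnn_stats(tb)
    data.frame(event = as.character(i), a = tb[1], ror = r$ror,
               ror_ci_low = r$ci_low, prr = p$prr, chisq = p$chisq,
               ic_minus_2sd = bc$ic_minus_2sd,
               ebgm05 = 2^(bc$ic - 1.645 * bc$ic_sd))
  }))
  full <- evaluate_signals(stats)
  relaxed_count <- evaluate_signals(stats, min_count = 1)
  for (flag in c("ror_signal", "prr_signal", "bcpnn_signal", "mgps_signal")) {
    expect_true(all(!full[[flag]] | relaxed_count[[flag]]))
    # each flag implies every one of its sub-conditions
    if (flag == "ror_signal") {
      expect_true(all(!full[[flag]] |
                        (full$a >= 3 & full$ror >= 2 & full$ror_ci_low > 1)))
    }
    if (flag == "prr_signal") {
      expect_true(all(!full[[flag]] |
                        (full$a >= 3 & full$prr >= 2 & full$chisq >= 4)))
    }
  }
})

test_that("NA statistics never satisfy a criterion", {
  stats <- data.frame(event = "x", a = 10, ror = NA_real_, ror_ci_low = NA_real_,
                      prr = NA_real_, chisq = NA_real_, ic_minus_2sd = NA_real_,
                      ebgm05 = NA_real_)
  out <- evaluate_signals(stats)
  expect_false(any(unlist(out[, c("ror_signal", "prr_signal",
                                  "bcpnn_signal", "mgps_signal")])))
})
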