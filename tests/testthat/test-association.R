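test_that("behaviour frequencies count code occurrences over carer turns", {
  rec <- records_from_cells(5, 5, 0, 0, behaviour = "UseName")
  f1 <- behaviour_frequencies(rec[rec$codes != "", ])
  expect_equal(f1$pct_occurrences, 100)

  # planted 543 + 1197 occurrences across two codes
  rec2 <- data.frame(conversation_id = "x", index = 1:1740, speaker = "CS",
                     codes = rep(c("AnsCont", "VblAck"), c(543, 1197)),
                     fwd_short = FALSE, fwd_medium = FALSE, fwd_long = FALSE,
                     bwd_short = FALSE, bwd_medium = FALSE, bwd_long = FALSE,
                     stringsAsFactors = FALSE)
  f2 <- behaviour_frequencies(rec2)
  expect_equal(f2$behaviour, c("VblAck", "AnsCont"))
  expect_equal(round(f2$pct_occurrences[f2$behaviour == "AnsCont"], 1), 31.2)

  expect_equal(nrow(behaviour_frequencies(rec2[0, ])), 0L)
})

test_that("eligibility uses the ceiling of the turn fraction", {
  mk <- function(k, n = 1743) {
    data.frame(conversation_id = "x", index = seq_len(n), speaker = "CS",
               codes = rep(c("GiveTime", ""), c(k, n - k)),
               fwd_short = FALSE, fwd_medium = FALSE, fwd_long = FALSE,
               bwd_short = FALSE, bwd_medium = FALSE, bwd_long = FALSE,
               stringsAsFactors = FALSE)
  }
  expect_equal(eligible_behaviours(mk(18)), "GiveTime")   # ceiling(17.43) = 18
  expect_equal(eligible_behaviours(mk(17)), character())
  expect_equal(eligible_behaviours(mk(1), min_fraction = 0), "GiveTime")
})

test_that("contingency cross-tabulates behaviour presence against engagement", {
  rec <- records_from_cells(17, 40, 166, 1520, behaviour = "AnsCont")
  tab <- contingency(rec, "AnsCont", "fwd_short")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(17, 40, 166, 1520))
  expect_equal(contingency(rec, "AnsCont", c("forward", "short"))$a, 17)

  all_eng <- records_from_cells(3, 0, 3, 0)
  t2 <- contingency(all_eng, "ActListen", "fwd_short")
  expect_equal(c(t2$b, t2$d), c(0, 0))

  expect_error(contingency(rec, "NotACode", "fwd_short"), "lookup")
  expect_error(contingency(rec, "AnsCont", "sideways_short"), "unknown")
})

test_that("closed-form odds ratios reproduce published cells and the oracle", {
  r <- odds_ratio(list(a = 17, b = 40, c = 166, d = 1520))
  expect_equal(r$odds_ratio, 3.892, tolerance = 1e-3)
  expect_equal(r$ci_low, 2.158, tolerance = 1e-3)
  expect_equal(r$ci_high, 7.018, tolerance = 1e-3)
  expect_equal(r$probability_present, 100 * 17 / 57)
  expect_lt(r$p_value, 0.001)

  expect_equal(odds_ratio(list(a = 1, b = 1, c = 1, d = 1))$odds_ratio, 1.0)
  expect_equal(odds_ratio(list(a = 166, b = 159, c = 69, d = 1349))$odds_ratio,
               20.411, tolerance = 1e-3)

  set.seed(61)
  for (i in 1:60) {
    cells <- sample(1:50, 4, replace = TRUE)
    r <- odds_ratio(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4]))
    o <- oracle_or(cells[1], cells[2], cells[3], cells[4])
    expect_equal(r$odds_ratio, o$or, tolerance = 1e-12)
    expect_equal(r$ci_low, o$lo, tolerance = 1e-12)
    expect_equal(r$ci_high, o$hi, tolerance = 1e-12)
    expect_equal(r$p_value, o$p, tolerance = 1e-12)
    expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
    # inversion and block-swap invariances
    r_sw <- odds_ratio(list(a = cells[3], b = cells[4], c = cells[1], d = cells[2]))
    expect_equal(r$odds_ratio * r_sw$odds_ratio, 1, tolerance = 1e-12)
  }

  # monotonicity in the engaged-and-present cell
  ors <- sapply(1:10, function(a) odds_ratio(list(a = a, b = 5, c = 7, d = 11))$odds_ratio)
  expect_true(all(diff(ors) > 0))
})

test_that("zero cells follow the documented degeneracy policy", {
  z <- odds_ratio(list(a = 0, b = 35, c = 183, d = 1525))
  expect_equal(c(z$odds_ratio, z$ci_low, z$ci_high), c(0, 0, 0))
  expect_true(z$separation)

  inf <- odds_ratio(list(a = 5, b = 0, c = 3, d = 7))
  expect_equal(inf$odds_ratio, Inf)
  expect_true(inf$separation)

  h <- odds_ratio(list(a = 0, b = 35, c = 183, d = 1525), correction = "haldane")
  expect_gt(h$odds_ratio, 0)
  expect_false(h$separation)
  expect_equal(h$odds_ratio, (0.5 * 1525.5) / (35.5 * 183.5), tolerance = 1e-12)
})

test_that("logistic fits agree with the closed form and flag separation", {
  rec <- records_from_cells(17, 40, 166, 1520, behaviour = "AnsCont")
  fit <- logistic_association(rec, "AnsCont", "fwd_short")
  expect_equal(fit$odds_ratio, 3.892, tolerance = 1e-3)
  expect_equal(fit$odds_ratio, odds_ratio(fit$table)$odds_ratio,
               tolerance = 1e-6)
  expect_equal(fit$method, "logistic")

  rec2 <- records_from_cells(50, 275, 133, 1285)
  expect_equal(logistic_association(rec2, "ActListen", "fwd_short")$odds_ratio,
               1.757, tolerance = 1e-3)

  # constant outcome: degenerate, falls back with a separation flag
  rec3 <- records_from_cells(0, 10, 0, 20)
  f3 <- logistic_association(rec3, "ActListen", "fwd_short")
  expect_true(f3$separation)
})

test_that("results tables cover eligible behaviours x ranges in frequency order", {
  rec <- records_from_cells(17, 40, 166, 1520, behaviour = "AnsCont")
  res <- results_table(rec, "forward")
  expect_s3_class(res, "engagement_association")
  expect_equal(nrow(res), 3L)
  expect_equal(res$range, c("short", "medium", "long"))
  expect_equal(res$or[res$range == "short"], 3.892, tolerance = 1e-3)
  expect_equal(res$odds_present[1], "17/40")
  expect_equal(res$stars[1], "***")

  # backward routing keys off the backward labels only
  resb <- results_table(rec, "backward")
  expect_true(all(resb$separation))   # backward labels all FALSE here

  # two behaviours are ordered by descending frequency
  rec2 <- rbind(records_from_cells(10, 20, 50, 100, behaviour = "VblAck"),
                records_from_cells(5, 10, 20, 40, behaviour = "GiveTime"))
  res2 <- results_table(rec2, "forward", min_fraction = 0)
  expect_equal(unique(res2$behaviour), c("VblAck", "GiveTime"))
  expect_equal(nrow(res2), 6L)

  # optional multiplicity adjustment appends a BH column
  res3 <- results_table(rec, "forward", adjust = TRUE)
  expect_true("p_adj" %in% names(res3))
  expect_true(all(res3$p_adj >= res3$p, na.rm = TRUE))
})
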