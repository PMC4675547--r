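split_codes <- function(codes) strsplit(as.character(codes), ";", fixed = TRUE)

code_present <- function(records, behaviour) {
  vapply(split_codes(records$codes), function(x) behaviour %in% x, NA)
}

outcome_column <- function(outcome) {
  if (length(outcome) == 2L) outcome <- paste(outcome, collapse = "_")
  outcome <- sub("^forward", "fwd", sub("^backward", "bwd", outcome))
  outcome <- sub("^fwd_med$", "fwd_medium", sub("^bwd_med$", "bwd_medium", outcome))
  ok <- c("fwd_short", "fwd_medium", "fwd_long",
          "bwd_short", "bwd_medium", "bwd_long")
  if (!outcome %in% ok)
    stop("unknown engagement dimension: ", outcome, call. = FALSE)
  outcome
}

#' Behaviour code frequencies over carer turns
#'
#' @param records A turn table from [build_turn_table()].
#' @return A data frame per code: `count` (turns carrying the code),
#'   `pct_occurrences` (share of all code occurrences) and `pct_turns`
#'   (share of all carer turns), sorted by descending count.
#' @export
behaviour_frequencies <- function(records) {
  empty <- data.frame(behaviour = character(), count = integer(),
                      pct_occurrences = numeric(), pct_turns = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(records)) return(empty)
  codes <- unlist(split_codes(records$codes), use.names = FALSE)
  codes <- codes[nzchar(codes)]
  if (!length(codes)) return(empty)
  tab <- sort(table(codes), decreasing = TRUE)
  data.frame(behaviour = names(tab), count = as.integer(tab),
             pct_occurrences = 100 * as.integer(tab) / sum(tab),
             pct_turns = 100 * as.integer(tab) / nrow(records),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Behaviours eligible for association analysis
#'
#' A behaviour enters the per-behaviour analyses only if it occurs on at
#' least `ceiling(min_fraction * n)` of the `n` carer turns (default 1%,
#' e.g. 18 of 1,743 turns). Rare codes give degenerate 2x2 tables.
#'
#' @param records A turn table.
#' @param min_fraction Minimum fraction of carer turns (default 0.01);
#'   0 makes every observed code eligible.
#' @return Character vector of eligible code labels, most frequent first.
#' @export
eligible_behaviours <- function(records, min_fraction = 0.01) {
  freq <- behaviour_frequencies(records)
  if (!nrow(freq)) return(character())
  thr <- ceiling(min_fraction * nrow(records))
  freq$behaviour[freq$count >= thr]
}

#' Cross-tabulate behaviour presence against an engagement label
#'
#' @param records A turn table.
#' @param behaviour A behaviour code label occurring in `records`.
#' @param outcome An engagement dimension: one of `fwd_short`, `fwd_medium`,
#'   `fwd_long`, `bwd_short`, `bwd_medium`, `bwd_long` (or
#'   `c("forward","short")` etc.).
#' @return A `contingency_table`: counts `a` (engaged & present), `b`
#'   (not engaged & present), `c` (engaged & absent), `d` (not engaged &
#'   absent), plus the behaviour and outcome identifiers.
#' @export
contingency <- function(records, behaviour, outcome) {
  outcome <- outcome_column(outcome)
  all_codes <- unique(unlist(split_codes(records$codes), use.names = FALSE))
  if (!behaviour %in% all_codes)
    stop("lookup error: behaviour '", behaviour, "' not present in records",
         call. = FALSE)
  present <- code_present(records, behaviour)
  engaged <- records[[outcome]]
  structure(list(a = sum(engaged & present), b = sum(!engaged & present),
                 c = sum(engaged & !present), d = sum(!engaged & !present),
                 behaviour = behaviour, outcome = outcome),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<2x2 table %s x %s>\n", x$behaviour, x$outcome))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2,
              dimnames = list(engaged = c("yes", "no"),
                              behaviour = c("present", "absent")))
  print(m)
  invisible(x)
}

new_association_result <- function(behaviour, outcome, or, lo, hi, p, prob,
                                   tab, method, separation = FALSE) {
  structure(list(behaviour = behaviour, outcome = outcome, odds_ratio = or,
                 ci_low = lo, ci_high = hi, p_value = p,
                 probability_present = prob, table = tab, method = method,
                 separation = separation),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  head <- if (is.na(x$behaviour)) "2x2 association" else
    paste(x$behaviour, "x", x$outcome)
  cat(sprintf("%s [%s%s]: OR %.3f (95%% CI %.3f-%.3f), p %s, P(engaged | present) %.1f%%\n",
              head, x$method,
              if (x$separation) ", separation" else "",
              x$odds_ratio, x$ci_low, x$ci_high,
              format.pval(x$p_value, digits = 3), x$probability_present))
  invisible(x)
}

#' Closed-form odds ratio with Wald interval
#'
#' For a 2x2 table of engagement against behaviour presence, computes
#' `OR = ad/(bc)`, the 95% Wald interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, a two-sided Wald test
#' p-value and the probability of engagement given the behaviour,
#' `a/(a+b)` in percent.
#'
#' Zero-cell policy (no continuity correction by default): `a = 0` yields
#' OR 0 with a degenerate (0, 0) interval; `b = 0` or `c = 0` with the other
#' cells positive yields OR `Inf` with a degenerate interval; both carry a
#' separation flag. `correction = "haldane"` instead adds 0.5 to every cell
#' of a table containing a zero.
#'
#' @param t A `contingency_table` (or a list/vector with components
#'   `a`, `b`, `c`, `d`).
#' @param conf_level Confidence level of the Wald interval.
#' @param correction `"none"` (default) or `"haldane"`.
#' @return An `association_result`.
#' @examples
#' odds_ratio(list(a = 17, b = 40, c = 166, d = 1520)) # OR 3.892 (2.158-7.018)
#' @export
odds_ratio <- function(t, conf_level = 0.95, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
  if (any(c(a, b, cc, d) < 0) || any(c(a, b, cc, d) != round(c(a, b, cc, d))))
    stop("contingency cells must be non-negative integers", call. = FALSE)
  behaviour <- if (!is.null(t[["behaviour"]])) t[["behaviour"]] else NA_character_
  outcome <- if (!is.null(t[["outcome"]])) t[["outcome"]] else NA_character_
  tab <- structure(list(a = a, b = b, c = cc, d = d, behaviour = behaviour,
                        outcome = outcome), class = "contingency_table")
  prob <- if (a + b > 0) 100 * a / (a + b) else NA_real_
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  any_zero <- any(c(a, b, cc, d) == 0)
  if (any_zero && correction == "haldane") {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    any_zero <- FALSE
  }
  if (any_zero) {
    if (a == 0) {
      return(new_association_result(behaviour, outcome, 0, 0, 0, NA_real_,
                                    prob, tab, "closed_form", separation = TRUE))
    }
    if (b == 0 || cc == 0) {
      return(new_association_result(behaviour, outcome, Inf, Inf, Inf,
                                    NA_real_, prob, tab, "closed_form",
                                    separation = TRUE))
    }
    # d == 0 only: odds ratio collapses to 0/... treat as degenerate zero
    return(new_association_result(behaviour, outcome, 0, 0, 0, NA_real_,
                                  prob, tab, "closed_form", separation = TRUE))
  }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  lo <- exp(log(or) - z * se)
  hi <- exp(log(or) + z * se)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  new_association_result(behaviour, outcome, or, lo, hi, p, prob, tab,
                         "closed_form")
}

#' Univariate logistic regression of engagement on behaviour presence
#'
#' Fits `engaged ~ present` by maximum-likelihood logistic regression and
#' reports the exponentiated coefficient with its Wald interval and p-value.
#' With a single binary predictor and all four cells positive the model is
#' saturated, so the exponentiated coefficient equals the closed-form
#' `ad/(bc)` exactly; the logistic route is retained as the fitting idiom
#' and as a numerical cross-check. Under complete separation (a zero cell)
#' the maximum-likelihood estimate is degenerate: the result falls back to
#' the closed-form cells and carries a separation flag.
#'
#' @inheritParams contingency
#' @param conf_level Confidence level of the Wald interval.
#' @return An `association_result` with `method = "logistic"` (or the
#'   closed-form fallback under separation).
#' @export
logistic_association <- function(records, behaviour, outcome,
                                 conf_level = 0.95) {
  tab <- contingency(records, behaviour, outcome)
  fit_logistic_cells(tab, conf_level = conf_level)
}

fit_logistic_cells <- function(tab, conf_level = 0.95) {
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (any(cells == 0)) {
    res <- odds_ratio(tab, conf_level = conf_level)
    res$separation <- TRUE
    return(res)
  }
  dat <- data.frame(y = c(1, 0, 1, 0), x = c(1, 1, 0, 0), w = cells)
  fit <- stats::glm(y ~ x, family = stats::binomial(), data = dat,
                    weights = w,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  est <- stats::coef(fit)[["x"]]
  se <- sqrt(stats::vcov(fit)["x", "x"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * stats::pnorm(-abs(est / se))
  prob <- 100 * tab$a / (tab$a + tab$b)
  new_association_result(tab$behaviour, tab$outcome, exp(est),
                         exp(est - z * se), exp(est + z * se), p, prob, tab,
                         "logistic")
}

#' Per-behaviour association results for one engagement direction
#'
#' For every eligible behaviour and each of the short, medium and long
#' ranges, fits the univariate association between behaviour presence and
#' the binary engagement label, ordered by behaviour frequency descending.
#' Significance stars mark p below 0.05 / 0.01 / 0.005.
#'
#' @param records A turn table from [build_turn_table()].
#' @param direction `"forward"` (partner engagement with carer content) or
#'   `"backward"` (carer engagement with partner content).
#' @param method `"logistic"` (default) or `"closed_form"`; numerically
#'   identical on all-positive tables.
#' @param min_fraction Eligibility threshold, see [eligible_behaviours()].
#' @param conf_level Confidence level for Wald intervals.
#' @param adjust Logical; append a Benjamini-Hochberg adjusted p-value
#'   column `p_adj` across all rows. Off by default: the canonical analysis
#'   runs separate per-behaviour tests without multiplicity correction.
#' @param correction Zero-cell policy for the closed-form route, see
#'   [odds_ratio()].
#' @return An object of class `engagement_association`: a data frame with
#'   one row per behaviour x range, columns `behaviour`, `range`, `p`,
#'   `or`, `ci_low`, `ci_high`, `prob_present`, `odds_present`,
#'   `odds_absent`, `stars`, `separation`, and attributes `direction`,
#'   `method`, `n_records`.
#' @export
results_table <- function(records, direction = c("forward", "backward"),
                          method = c("logistic", "closed_form"),
                          min_fraction = 0.01, conf_level = 0.95,
                          adjust = FALSE, correction = c("none", "haldane")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  correction <- match.arg(correction)
  behaviours <- eligible_behaviours(records, min_fraction = min_fraction)
  ranges <- c("short", "medium", "long")
  rows <- vector("list", length(behaviours) * length(ranges))
  k <- 0L
  for (bh in behaviours) {
    for (rg in ranges) {
      tab <- contingency(records, bh, c(direction, rg))
      res <- if (method == "logistic") {
        fit_logistic_cells(tab, conf_level = conf_level)
      } else {
        odds_ratio(tab, conf_level = conf_level, correction = correction)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        behaviour = bh, range = rg, p = res$p_value, or = res$odds_ratio,
        ci_low = res$ci_low, ci_high = res$ci_high,
        prob_present = res$probability_present,
        odds_present = sprintf("%d/%d", tab$a, tab$b),
        odds_absent = sprintf("%d/%d", tab$c, tab$d),
        separation = res$separation, stringsAsFactors = FALSE)
    }
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(behaviour = character(), range = character(), p = numeric(),
               or = numeric(), ci_low = numeric(), ci_high = numeric(),
               prob_present = numeric(), odds_present = character(),
               odds_absent = character(), separation = logical(),
               stringsAsFactors = FALSE)
  out$stars <- ifelse(is.na(out$p), "",
                ifelse(out$p < 0.005, "***",
                 ifelse(out$p < 0.01, "**",
                  ifelse(out$p < 0.05, "*", ""))))
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  structure(out, class = c("engagement_association", "data.frame"),
            direction = direction, method = method, n_records = nrow(records))
}

#' @export
print.engagement_association <- function(x, digits = 3, ...) {
  cat(sprintf("Engagement associations (%s direction, %s, %d carer turns)\n",
              attr(x, "direction"), attr(x, "method"), attr(x, "n_records")))
  d <- as.data.frame(x)
  d$p <- format.pval(d$p, digits = digits, eps = 1e-3)
  d$or <- formatC(d$or, digits = digits, format = "f")
  d$ci <- sprintf("(%s-%s)", formatC(d$ci_low, digits = digits, format = "f"),
                  formatC(d$ci_high, digits = digits, format = "f"))
  d$prob_present <- sprintf("%.0f%%", d$prob_present)
  print(d[c("behaviour", "range", "p", "or", "ci", "prob_present",
            "odds_present", "odds_absent", "stars")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.engagement_association <- function(object, alpha = 0.05, ...) {
  sig <- object[!is.na(object$p) & object$p < alpha, , drop = FALSE]
  cat(sprintf("%d of %d behaviour x range tests significant at alpha = %g (%s)\n",
              nrow(sig), nrow(object), alpha, attr(object, "direction")))
  if (nrow(sig))
    print(as.data.frame(sig)[c("behaviour", "range", "p", "or")],
          row.names = FALSE)
  invisible(sig)
}

#' @export
coef.engagement_association <- function(object, ...) {
  stats::setNames(log(object$or), paste(object$behaviour, object$range, sep = ":"))
}

#' Reference behaviour-engagement counts from a published study
#'
#' A frozen table of 2x2 cell counts (engaged/not engaged by behaviour
#' present/absent), printed odds ratios, Wald interval bounds and
#' probabilities for every behaviour x range combination in both engagement
#' directions, from a study of 20 carer--resident dyadic conversations
#' (1,743 carer turns). Rows whose printed summary statistics are
#' arithmetically inconsistent with their own printed cell counts
#' (typesetting errors in the source) are flagged via the `or_consistent`,
#' `ci_consistent` and `prob_consistent` columns.
#'
#' @return A data frame with columns `direction`, `behaviour`, `range`, `p`,
#'   `or`, `ci_low`, `ci_high`, `prob`, `a`, `b`, `c`, `d` and the three
#'   consistency flags.
#' @export
reference_association_counts <- function() {
  path <- system.file("extdata", "reference_association_counts.csv",
                      package = "convrecur")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
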