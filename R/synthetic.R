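#' Configuration for the synthetic dyadic-conversation generator
#'
#' Describes a corpus of alternating two-speaker conversations with known
#' content-sharing dynamics: every turn draws a few content terms from a
#' shared vocabulary plus filler stopwords, and term reuse by the partner is
#' injected as explicit copy events whose probability sits on the odds scale,
#' so that behaviour codes can multiply the reuse odds within a chosen range
#' (short, medium or long). The generator matches the statistical structure
#' the analysis consumes, not realistic syntax.
#'
#' Defaults emulate the corpus shape the analysis is designed for: 20
#' conversations of roughly 173 turns (about 3,460 utterances in total),
#' sparse content (about two content terms per turn from a 600-term
#' vocabulary) so that incidental cross-turn term collisions stay rare and
#' recurrence is dominated by genuine reuse.
#'
#' @param n_conversations Number of conversations.
#' @param turns_per_conversation Mean turns per conversation.
#' @param turn_jitter Uniform jitter (turns) around the mean length.
#' @param vocabulary_size Number of distinct content terms available.
#' @param terms_per_turn Mean content terms per turn (geometric lengths:
#'   many short turns, few long ones; capped at 8).
#' @param stopword_rate Expected fraction of filler stopword tokens per turn.
#' @param baseline_reuse Baseline probability that a reuse event fires in
#'   each range window for a given source turn.
#' @param behaviour_rates Named numeric vector: per-carer-turn emission
#'   probability of each behaviour code.
#' @param behaviour_effects Named list: for each code, `list(multiplier =,
#'   window =)` with `multiplier > 0` applied to the reuse odds of partner
#'   turns within `window` (`"short"`, `"medium"` or `"long"`).
#' @param channels Named character vector `c(carer = , partner = )`.
#' @param seed Master seed; a fixed seed makes corpus output byte-identical.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_conversations = 20L,
                             turns_per_conversation = 173L,
                             turn_jitter = 10L,
                             vocabulary_size = 600L,
                             terms_per_turn = 2,
                             stopword_rate = 0.4,
                             baseline_reuse = 0.15,
                             behaviour_rates = NULL,
                             behaviour_effects = NULL,
                             channels = c(carer = "CS", partner = "PWD"),
                             seed = 1L) {
  stopifnot(n_conversations >= 0, turns_per_conversation >= 2,
            turn_jitter >= 0, vocabulary_size >= 1, terms_per_turn >= 1,
            stopword_rate >= 0, stopword_rate < 1,
            baseline_reuse >= 0, baseline_reuse <= 1,
            length(channels) == 2L,
            all(c("carer", "partner") %in% names(channels)))
  if (terms_per_turn > vocabulary_size)
    stop("config error: vocabulary smaller than mean terms per turn",
         call. = FALSE)
  if (!is.null(behaviour_rates)) {
    stopifnot(is.numeric(behaviour_rates), !is.null(names(behaviour_rates)),
              all(behaviour_rates >= 0), all(behaviour_rates <= 1))
  }
  if (!is.null(behaviour_effects)) {
    stopifnot(is.list(behaviour_effects), !is.null(names(behaviour_effects)))
    for (e in behaviour_effects) {
      stopifnot(is.list(e), e$multiplier > 0,
                e$window %in% c("short", "medium", "long"))
    }
    if (!all(names(behaviour_effects) %in% names(behaviour_rates)))
      stop("every code with an injected effect needs an emission rate",
           call. = FALSE)
  }
  structure(list(
    n_conversations = as.integer(n_conversations),
    turns_per_conversation = as.integer(turns_per_conversation),
    turn_jitter = as.integer(turn_jitter),
    vocabulary_size = as.integer(vocabulary_size),
    terms_per_turn = terms_per_turn,
    stopword_rate = stopword_rate,
    baseline_reuse = baseline_reuse,
    behaviour_rates = behaviour_rates,
    behaviour_effects = behaviour_effects,
    channels = channels,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config: %d conversations x ~%d turns, vocab %d, baseline reuse %.2f, seed %d>\n",
              x$n_conversations, x$turns_per_conversation, x$vocabulary_size,
              x$baseline_reuse, x$seed))
  if (length(x$behaviour_effects)) {
    for (nm in names(x$behaviour_effects)) {
      e <- x$behaviour_effects[[nm]]
      cat(sprintf("  effect: %s x%.2f on %s window (rate %.2f)\n", nm,
                  e$multiplier, e$window, x$behaviour_rates[[nm]]))
    }
  }
  invisible(x)
}

sim_fillers <- c("yeah", "well", "you", "know", "oh", "mmm", "right", "no",
                 "um", "like")

# partner-turn lags inside each range window (alternating speakers: odd lags
# belong to the other speaker); medium excludes the short lag so that
# medium-window effects exercise the label isolation rule
window_lags <- function(window, remaining) {
  lags <- switch(window,
                 short = 1,
                 medium = c(3, 5, 7, 9),
                 long = if (remaining >= 11) seq(11, remaining, by = 2) else numeric())
  lags[lags <= remaining]
}

#' Generate one synthetic conversation with ground truth
#'
#' Turns alternate between the partner and carer channels. Content terms are
#' drawn uniformly from the configured vocabulary; reuse events copy one
#' uniformly chosen content term of the source turn into a partner turn at a
#' window-specific lag (short: next turn; medium: a partner turn 3-9 turns
#' ahead; long: a partner turn 11 or more turns ahead). Event probabilities
#' start at `baseline_reuse` and, on carer turns, are adjusted on the odds
#' scale by the multiplier of each emitted behaviour code whose effect
#' targets that window. Behaviour codes are embedded in the rendered text as
#' bracketed annotations.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Optional seed for this conversation's stream.
#' @param id Conversation identifier.
#' @return A list with `conversation` (a [conversation()] object) and
#'   `truth` (data frame of forced reuse events: `source_index`, `lag`,
#'   `window`, 0-based indices).
#' @export
generate_conversation <- function(cfg, seed = NULL, id = "sim") {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$turns_per_conversation
  if (cfg$turn_jitter > 0)
    n <- n + sample.int(2L * cfg$turn_jitter + 1L, 1L) - cfg$turn_jitter - 1L
  n <- max(n, 2L)
  carer <- unname(cfg$channels[["carer"]])
  partner <- unname(cfg$channels[["partner"]])
  speaker <- rep(c(partner, carer), length.out = n)

  k <- pmin(1L + stats::rgeom(n, 1 / max(cfg$terms_per_turn, 1)), 8L)
  k <- pmin(k, cfg$vocabulary_size)
  terms <- lapply(k, function(ki) sample.int(cfg$vocabulary_size, ki))

  rates <- cfg$behaviour_rates
  codes <- rep(list(character()), n)
  if (length(rates)) {
    is_carer <- speaker == carer
    for (t in which(is_carer)) {
      emit <- names(rates)[stats::runif(length(rates)) < rates]
      codes[[t]] <- sort(emit)
    }
  }

  effects <- cfg$behaviour_effects
  base_lo <- stats::qlogis(cfg$baseline_reuse)
  forced <- list()
  if (cfg$baseline_reuse > 0 || length(effects)) {
    for (t in seq_len(n)) {
      boost <- c(short = 0, medium = 0, long = 0)
      if (length(effects) && speaker[t] == carer && length(codes[[t]])) {
        for (nm in intersect(codes[[t]], names(effects))) {
          e <- effects[[nm]]
          boost[[e$window]] <- boost[[e$window]] + log(e$multiplier)
        }
      }
      for (w in c("short", "medium", "long")) {
        lags <- window_lags(w, n - t)
        if (!length(lags)) next
        p <- stats::plogis(base_lo + boost[[w]])
        if (p <= 0 || stats::runif(1) >= p) next
        lag <- if (length(lags) == 1L) lags else sample(lags, 1L)
        term <- if (length(terms[[t]]) == 1L) terms[[t]] else sample(terms[[t]], 1L)
        terms[[t + lag]] <- unique(c(terms[[t + lag]], term))
        forced[[length(forced) + 1L]] <-
          data.frame(source_index = t - 1L, lag = lag, window = w,
                     stringsAsFactors = FALSE)
      }
    }
  }

  words <- sprintf("w%04d", seq_len(cfg$vocabulary_size))
  sr <- cfg$stopword_rate
  raw <- character(n)
  clean <- character(n)
  for (t in seq_len(n)) {
    content <- words[terms[[t]]]
    n_fill <- if (sr > 0) stats::rpois(1, length(content) * sr / (1 - sr)) else 0L
    toks <- c(content, sample(sim_fillers, n_fill, replace = TRUE))
    toks <- if (length(toks) > 1L) sample(toks) else toks
    body <- paste(toks, collapse = " ")
    clean[t] <- paste0(body, ".")
    ann <- if (length(codes[[t]])) paste0(" [", codes[[t]], "]", collapse = "") else ""
    raw[t] <- paste0(body, ann, ".")
  }
  conv <- conversation(speaker = speaker, raw_text = raw, clean_text = clean,
                       codes = codes, notations = rep(list(character()), n),
                       channels = c(partner, carer), id = id)
  truth <- if (length(forced)) do.call(rbind, forced) else
    data.frame(source_index = integer(), lag = integer(),
               window = character(), stringsAsFactors = FALSE)
  list(conversation = conv, truth = truth)
}

#' Generate a synthetic corpus with manifest and ground truth
#'
#' Draws one seed per conversation from the master seed so that each
#' conversation has an independent, reproducible stream; a fixed master seed
#' yields byte-identical output.
#'
#' @param cfg A [synthetic_config()].
#' @return An object of class `synthetic_corpus`: list with `conversations`
#'   (list of `conversation` objects), `truth` (injected effects and the
#'   per-conversation forced reuse events) and `manifest` (config
#'   fingerprint and seeds).
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  nc <- cfg$n_conversations
  seeds <- if (nc > 0) sample.int(2147483646L, nc) else integer()
  conversations <- vector("list", nc)
  events <- vector("list", nc)
  for (i in seq_len(nc)) {
    g <- generate_conversation(cfg, seed = seeds[i], id = sprintf("sim%03d", i))
    conversations[[i]] <- g$conversation
    ev <- g$truth
    if (nrow(ev)) ev$conversation_id <- g$conversation$id
    events[[i]] <- ev
  }
  forced <- if (nc > 0) do.call(rbind, events[vapply(events, nrow, 0L) > 0]) else NULL
  scal <- cfg[c("n_conversations", "turns_per_conversation", "turn_jitter",
                "vocabulary_size", "terms_per_turn", "stopword_rate",
                "baseline_reuse", "seed")]
  manifest <- list(
    config = scal,
    behaviour_rates = as.list(cfg$behaviour_rates),
    behaviour_effects = cfg$behaviour_effects,
    fingerprint = paste(names(scal), unlist(scal), sep = "=", collapse = ";"),
    conversation_seeds = seeds
  )
  structure(list(conversations = conversations,
                 truth = list(effects = cfg$behaviour_effects, forced = forced),
                 manifest = manifest, config = cfg),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  nu <- sum(vapply(x$conversations, function(cv) nrow(cv$turns), 0L))
  cat(sprintf("<synthetic_corpus: %d conversations, %d utterances, seed %d>\n",
              length(x$conversations), nu, x$config$seed))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Emits one CSV transcript per conversation plus `truth.json` and
#' `manifest.json` (requires the jsonlite package).
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (conv in corpus$conversations)
    write_conversation(conv, file.path(dir, paste0(conv$id, ".csv")))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing truth.json/manifest.json requires the jsonlite package",
         call. = FALSE)
  jsonlite::write_json(corpus$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(corpus$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Parameter-recovery report for injected behaviour effects
#'
#' Runs the full pipeline (recurrence, engagement labels, association) over
#' a synthetic corpus and compares, per injected behaviour code, the
#' estimated odds ratio in the code's target window (forward direction,
#' carer turns) against the injected multiplier, reporting whether the Wald
#' interval covers it. A code that was never emitted is reported as
#' unevaluable.
#'
#' @param corpus A `synthetic_corpus` (or list of conversations).
#' @param truth Ground truth (taken from the corpus when omitted).
#' @param records Optional precomputed turn table, to reuse across reports.
#' @param conf_level Wald interval confidence level.
#' @param carer_channel Carer channel identifier.
#' @return A data frame of class `recovery_report`: per injected code its
#'   window, injected multiplier, estimated OR, interval, p-value, coverage
#'   indicator and evaluability.
#' @export
recovery_report <- function(corpus, truth = NULL, records = NULL,
                            conf_level = 0.95, carer_channel = "CS") {
  if (inherits(corpus, "synthetic_corpus")) {
    if (is.null(truth)) truth <- corpus$truth
    if (!is.null(corpus$config)) carer_channel <- unname(corpus$config$channels[["carer"]])
    conversations <- corpus$conversations
  } else {
    conversations <- corpus
  }
  effects <- truth$effects
  if (!length(effects))
    stop("no injected effects in ground truth to recover", call. = FALSE)
  if (is.null(records))
    records <- build_turn_table(conversations, carer_channel = carer_channel)
  all_codes <- unique(unlist(split_codes(records$codes), use.names = FALSE))
  rows <- vector("list", length(effects))
  for (i in seq_along(effects)) {
    nm <- names(effects)[i]
    e <- effects[[i]]
    if (!nm %in% all_codes) {
      rows[[i]] <- data.frame(code = nm, window = e$window,
                              multiplier = e$multiplier, or = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              p = NA_real_, covered = NA, evaluable = FALSE,
                              stringsAsFactors = FALSE)
      next
    }
    res <- odds_ratio(contingency(records, nm, c("forward", e$window)),
                      conf_level = conf_level)
    covered <- is.finite(res$ci_low) && is.finite(res$ci_high) &&
      res$ci_low <= e$multiplier && e$multiplier <= res$ci_high
    rows[[i]] <- data.frame(code = nm, window = e$window,
                            multiplier = e$multiplier, or = res$odds_ratio,
                            ci_low = res$ci_low, ci_high = res$ci_high,
                            p = res$p_value, covered = covered,
                            evaluable = !res$separation,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_report", "data.frame")
  out
}
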