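#' Build a capped per-conversation term vocabulary
#'
#' Collects all non-stopword tokens of a conversation, ranks them by
#' descending corpus frequency within that conversation (ties broken by first
#' occurrence) and truncates to `max_terms`. Vocabularies are built per
#' conversation and never pooled across conversations, so recurrence is always
#' relative to the lexical content of the dyad at hand.
#'
#' @param conv A [conversation()] object.
#' @param stopwords Character vector of excluded terms.
#' @param max_terms Maximum vocabulary size (default 200).
#' @return An object of class `term_vocabulary`: list with `terms` (ordered
#'   character vector), `max_terms`, `stopwords` and `source` (conversation
#'   id). An all-stopword conversation yields an empty vocabulary, under
#'   which every similarity is 0.
#' @export
build_vocabulary <- function(conv, stopwords = default_stopwords(),
                             max_terms = 200L) {
  stopifnot(inherits(conv, "conversation"), max_terms >= 0L)
  toks <- unlist(tokenize(conv$turns$clean_text), use.names = FALSE)
  toks <- toks[!(toks %in% stopwords)]
  terms <- character()
  if (length(toks)) {
    first <- match(unique(toks), toks)
    freq <- tabulate(match(toks, unique(toks)))
    ord <- order(-freq, first)
    terms <- unique(toks)[ord]
    if (length(terms) > max_terms) terms <- terms[seq_len(max_terms)]
  }
  structure(list(terms = terms, max_terms = as.integer(max_terms),
                 stopwords = stopwords, source = conv$id),
            class = "term_vocabulary")
}

#' @export
print.term_vocabulary <- function(x, ...) {
  cat(sprintf("<term_vocabulary: %d/%d terms for '%s'>\n", length(x$terms),
              x$max_terms, x$source))
  if (length(x$terms))
    cat(" ", paste(utils::head(x$terms, 12L), collapse = ", "),
        if (length(x$terms) > 12L) "..." else "", "\n")
  invisible(x)
}

#' Binary term-presence matrix for the turns of a conversation
#'
#' @param conv A `conversation` object.
#' @param vocab A `term_vocabulary` built for this conversation.
#' @return Integer matrix, turns x vocabulary terms, entries in \{0,1\}.
#' @export
turn_term_matrix <- function(conv, vocab) {
  stopifnot(inherits(conv, "conversation"), inherits(vocab, "term_vocabulary"))
  n <- nrow(conv$turns)
  toks <- tokenize(conv$turns$clean_text)
  if (n == 1L) toks <- list(toks)
  B <- matrix(0L, n, length(vocab$terms),
              dimnames = list(NULL, vocab$terms))
  for (i in seq_len(n)) B[i, ] <- as.integer(vocab$terms %in% toks[[i]])
  B
}

#' Similarity of two binary turn vectors
#'
#' Cosine similarity over binary term-presence vectors:
#' `shared / sqrt(m * n)` where `shared` is the number of common terms and
#' `m`, `n` the per-turn term counts. Zero when either vector is empty.
#'
#' @param a,b Binary vectors over the same vocabulary.
#' @return A number in \[0, 1\].
#' @examples
#' term_similarity(c(1, 1, 1, 1, 0, 0), c(1, 0, 0, 0, 1, 0)) # 1/sqrt(8)
#' @export
term_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop("dimension error: vectors span different vocabularies", call. = FALSE)
  a <- as.numeric(a != 0); b <- as.numeric(b != 0)
  m <- sum(a); n <- sum(b)
  if (m == 0 || n == 0) return(0)
  sum(a * b) / sqrt(m * n)
}

#' Turn-by-turn recurrence matrix of a conversation
#'
#' Computes the symmetric matrix of pairwise turn similarities
#' ([term_similarity()]) over a per-conversation vocabulary. The diagonal is
#' 1 where the turn contains at least one vocabulary term and 0 otherwise.
#'
#' @param conv A `conversation` object.
#' @param vocab A `term_vocabulary`; built from `conv` by default.
#' @return An object of class `recurrence_matrix`: list with `sim` (n x n
#'   numeric matrix in \[0,1\]), `n_turns`, `speaker` (turn to channel map),
#'   `conversation_id` and `vocabulary`.
#' @export
recurrence_matrix <- function(conv, vocab = build_vocabulary(conv)) {
  B <- turn_term_matrix(conv, vocab)
  n <- nrow(B)
  if (ncol(B) == 0L) {
    sim <- matrix(0, n, n)
  } else {
    C <- tcrossprod(B)
    cnt <- rowSums(B)
    denom <- sqrt(outer(cnt, cnt))
    sim <- ifelse(denom > 0, C / denom, 0)
  }
  structure(list(sim = sim, n_turns = n, speaker = conv$turns$speaker,
                 conversation_id = conv$id, vocabulary = vocab),
            class = "recurrence_matrix")
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  off <- x$sim; if (x$n_turns) diag(off) <- 0
  cat(sprintf("<recurrence_matrix '%s': %d turns, %d term(s), %d nonzero off-diagonal pair(s)>\n",
              x$conversation_id, x$n_turns, length(x$vocabulary$terms),
              sum(off[upper.tri(off)] > 0)))
  invisible(x)
}

#' Primitive per-turn recurrence metrics
#'
#' Derives, for every turn, the twelve windowed recurrence metrics: the cross
#' of time scale (short = adjacent turn, medium = up to 10 turns away, long =
#' all remaining turns), direction (forward, backward) and type (other =
#' turns by the conversation partner, self = turns by the same speaker).
#' Short metrics equal the single adjacent-pair similarity (0 when the
#' adjacent turn is by the non-qualifying speaker); medium and long metrics
#' are arithmetic means of the pairwise similarities over the qualifying
#' turns inside the window. Windows are counted in raw turn distance over
#' both speakers; the aggregate then restricts to the qualifying speaker.
#' Boundary turns average over however many qualifying turns exist, and a
#' turn with no qualifying turns in a window scores 0. Self-similarity
#' (the diagonal) is excluded from every aggregate.
#'
#' @param m A [recurrence_matrix()].
#' @param windows Named numeric vector giving the short/medium/long window
#'   widths in turns; `Inf` means all remaining turns.
#' @return A data frame with `index` (0-based) and twelve metric columns
#'   `other_forward_short`, ..., `self_backward_long`.
#' @export
primitive_metrics <- function(m, windows = c(short = 1, medium = 10, long = Inf)) {
  stopifnot(inherits(m, "recurrence_matrix"))
  stopifnot(all(c("short", "medium", "long") %in% names(windows)))
  n <- m$n_turns
  cols <- c("other_forward_short", "other_forward_medium", "other_forward_long",
            "other_backward_short", "other_backward_medium", "other_backward_long",
            "self_forward_short", "self_forward_medium", "self_forward_long",
            "self_backward_short", "self_backward_medium", "self_backward_long")
  out <- as.data.frame(matrix(0, n, 12L, dimnames = list(NULL, cols)))
  if (n == 0L) return(cbind(index = integer(), out))
  S <- m$sim
  diag(S) <- 0
  idx <- seq_len(n)
  D <- outer(idx, idx, function(i, j) j - i)   # signed turn distance
  other <- outer(m$speaker, m$speaker, "!=")
  win_avg <- function(qual, lo, hi) {
    mask <- qual & D >= lo & D <= hi
    cnt <- rowSums(mask)
    s <- rowSums(S * mask)
    ifelse(cnt > 0, s / cnt, 0)
  }
  for (ty in c("other", "self")) {
    qual <- if (ty == "other") other else !other
    for (w in c("short", "medium", "long")) {
      ww <- unname(windows[[w]])
      out[[paste(ty, "forward", w, sep = "_")]]  <- win_avg(qual, 1, ww)
      out[[paste(ty, "backward", w, sep = "_")]] <- win_avg(qual, -ww, -1)
    }
  }
  cbind(index = idx - 1L, out)
}

#' Analyse a single conversation end to end
#'
#' Convenience wrapper: builds the vocabulary, the recurrence matrix and the
#' primitive metrics for one conversation.
#'
#' @inheritParams build_vocabulary
#' @inheritParams primitive_metrics
#' @return An object of class `recurrence_analysis`: list with
#'   `conversation`, `vocabulary`, `matrix` and `metrics`.
#' @export
analyze_conversation <- function(conv, stopwords = default_stopwords(),
                                 max_terms = 200L,
                                 windows = c(short = 1, medium = 10, long = Inf)) {
  vocab <- build_vocabulary(conv, stopwords = stopwords, max_terms = max_terms)
  m <- recurrence_matrix(conv, vocab)
  structure(list(conversation = conv, vocabulary = vocab, matrix = m,
                 metrics = primitive_metrics(m, windows = windows)),
            class = "recurrence_analysis")
}

#' @export
print.recurrence_analysis <- function(x, ...) {
  print(x$matrix)
  pos <- colSums(x$metrics[, -1, drop = FALSE] > 0)
  cat("  turns with positive other-forward-short:",
      sum(x$metrics$other_forward_short > 0), "\n")
  invisible(x)
}

#' Export per-turn metrics with transcript metadata
#'
#' One row per turn: conversation id, index, speaker, clean text, the twelve
#' primitive metrics and the semicolon-joined behaviour codes.
#'
#' @param x A `recurrence_analysis`.
#' @param file Optional path; when given, written as CSV.
#' @return The assembled data frame (invisibly when `file` is given).
#' @export
metrics_table <- function(x, file = NULL) {
  stopifnot(inherits(x, "recurrence_analysis"))
  conv <- x$conversation
  d <- cbind(
    data.frame(conversation_id = conv$id, index = conv$turns$index,
               speaker = conv$turns$speaker, text = conv$turns$clean_text,
               stringsAsFactors = FALSE),
    x$metrics[, -1, drop = FALSE],
    behaviour_codes = vapply(conv$codes, paste, "", collapse = ";")
  )
  if (!is.null(file)) {
    utils::write.csv(d, file, row.names = FALSE)
    return(invisible(d))
  }
  d
}
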