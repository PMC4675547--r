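#' Binarise recurrence metrics into engagement labels with range isolation
#'
#' A turn's windowed recurrence always counts adjacent-turn sharing into the
#' medium and long aggregates, so a positive medium or long metric may simply
#' restate short-range engagement. The binary labels therefore apply
#' isolation rules: short is labelled whenever the short metric is positive;
#' medium only when the medium metric is positive *and* short is absent; long
#' only when the long metric is positive and both shorter ranges are absent.
#' At most one of the three labels can be `TRUE`, and any positive metric in
#' a direction yields exactly one `TRUE` label in that direction.
#'
#' @param metrics A data frame from [primitive_metrics()], or any data frame
#'   containing the three `other_<direction>_<range>` columns.
#' @param direction `"forward"` (partner engages with this speaker's content)
#'   or `"backward"` (this speaker engages with earlier partner content).
#' @param tol Positivity threshold. Similarities are exact rationals of small
#'   integers, so anything beyond representation noise counts as recurrence.
#' @return A data frame of logicals with columns `short`, `medium`, `long`.
#' @examples
#' m <- data.frame(other_forward_short = c(0.354, 0, 0),
#'                 other_forward_medium = c(0.071, 0.200, 0),
#'                 other_forward_long = c(0.004, 0.010, 0))
#' binarize_engagement(m, "forward")
#' @export
binarize_engagement <- function(metrics, direction = c("forward", "backward"),
                                tol = 1e-12) {
  direction <- match.arg(direction)
  cols <- paste("other", direction, c("short", "medium", "long"), sep = "_")
  missing_cols <- setdiff(cols, names(metrics))
  if (length(missing_cols))
    stop("metrics lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  s <- metrics[[cols[1]]]; md <- metrics[[cols[2]]]; lg <- metrics[[cols[3]]]
  if (any(c(s, md, lg) < 0))
    stop("invariant violation: negative recurrence metric", call. = FALSE)
  short <- s > tol
  medium <- md > tol & !short
  long <- lg > tol & !short & !medium
  data.frame(short = short, medium = medium, long = long)
}

#' Assemble the corpus-level carer turn table
#'
#' Runs (or accepts) per-conversation recurrence metrics and collates one
#' record per carer-channel turn across all conversations, carrying the
#' behaviour codes present on the turn and both binary label triples:
#' forward (does the partner engage with this turn's content later?) and
#' backward (does this turn engage with earlier partner content?). Partner
#' turns can be retained for diagnostics via `include_partner`, but the
#' default analysis table contains carer turns only.
#'
#' @param conversations A list of [conversation()] objects (a single
#'   conversation is accepted).
#' @param metrics Optional list of [primitive_metrics()] data frames aligned
#'   with `conversations`; computed per conversation when `NULL`. Each
#'   conversation always uses its own vocabulary.
#' @param carer_channel The channel whose turns anchor the analysis.
#' @param include_partner Logical; also emit records for the other channel.
#' @param stopwords,max_terms Vocabulary construction, see
#'   [build_vocabulary()].
#' @param tol Positivity threshold for [binarize_engagement()].
#' @return A data frame with columns `conversation_id`, `index`, `speaker`,
#'   `codes` (semicolon-joined), `fwd_short`, `fwd_medium`, `fwd_long`,
#'   `bwd_short`, `bwd_medium`, `bwd_long` (logical).
#' @export
build_turn_table <- function(conversations, metrics = NULL,
                             carer_channel = "CS", include_partner = FALSE,
                             stopwords = default_stopwords(), max_terms = 200L,
                             tol = 1e-12) {
  if (inherits(conversations, "conversation"))
    conversations <- list(conversations)
  if (!length(conversations)) {
    return(data.frame(conversation_id = character(), index = integer(),
                      speaker = character(), codes = character(),
                      fwd_short = logical(), fwd_medium = logical(),
                      fwd_long = logical(), bwd_short = logical(),
                      bwd_medium = logical(), bwd_long = logical(),
                      stringsAsFactors = FALSE))
  }
  if (!is.null(metrics)) {
    if (length(metrics) != length(conversations))
      stop("consistency error: `metrics` and `conversations` lengths differ",
           call. = FALSE)
  }
  pieces <- vector("list", length(conversations))
  for (k in seq_along(conversations)) {
    conv <- conversations[[k]]
    stopifnot(inherits(conv, "conversation"))
    pm <- if (is.null(metrics)) {
      analyze_conversation(conv, stopwords = stopwords,
                           max_terms = max_terms)$metrics
    } else {
      metrics[[k]]
    }
    if (nrow(pm) != nrow(conv$turns))
      stop("consistency error: metrics rows do not match conversation '",
           conv$id, "'", call. = FALSE)
    fwd <- binarize_engagement(pm, "forward", tol = tol)
    bwd <- binarize_engagement(pm, "backward", tol = tol)
    rec <- data.frame(
      conversation_id = conv$id,
      index = conv$turns$index,
      speaker = conv$turns$speaker,
      codes = vapply(conv$codes, paste, "", collapse = ";"),
      fwd_short = fwd$short, fwd_medium = fwd$medium, fwd_long = fwd$long,
      bwd_short = bwd$short, bwd_medium = bwd$medium, bwd_long = bwd$long,
      stringsAsFactors = FALSE
    )
    if (!include_partner)
      rec <- rec[rec$speaker == carer_channel, , drop = FALSE]
    pieces[[k]] <- rec
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write a turn table to CSV with Y/N labels
#'
#' @param records A turn table from [build_turn_table()].
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_turn_table <- function(records, file) {
  d <- records
  lab <- c("fwd_short", "fwd_medium", "fwd_long",
           "bwd_short", "bwd_medium", "bwd_long")
  for (cl in intersect(lab, names(d))) d[[cl]] <- ifelse(d[[cl]], "Y", "N")
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}
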