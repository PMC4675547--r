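#' Construct a dyadic conversation object
#'
#' A conversation is an ordered sequence of speaker turns over exactly two
#' channels (by convention the carer channel `"CS"` and the partner channel
#' `"PWD"`). Each turn carries the verbatim transcript line, the cleaned
#' spoken text (annotations removed), the set of behaviour codes found in
#' brackets, and the set of recognised parenthetical notations.
#'
#' @param speaker Character vector of channel identifiers, one per turn.
#' @param raw_text Character vector of verbatim transcript lines.
#' @param clean_text Character vector of annotation-free spoken text; if
#'   `NULL`, recomputed from `raw_text` via [extract_annotations()].
#' @param codes List of character vectors of behaviour codes per turn.
#' @param notations List of character vectors of notations per turn.
#' @param channels The two channel identifiers; defaults to the distinct
#'   values of `speaker` (which must number one or two).
#' @param id Conversation identifier string.
#' @param registry Character vector of admissible behaviour code labels.
#' @param strict Logical; passed to [extract_annotations()] when annotations
#'   are recomputed.
#' @return An object of class `conversation`: a list with elements `id`,
#'   `channels` and `turns` (a data frame with 0-based `index`, `speaker`,
#'   `raw_text`, `clean_text`) plus parallel lists `codes` and `notations`.
#' @seealso [parse_transcript()], [write_conversation()]
#' @export
conversation <- function(speaker, raw_text, clean_text = NULL, codes = NULL,
                         notations = NULL, channels = NULL, id = "conversation",
                         registry = behaviour_registry()$label, strict = FALSE) {
  speaker <- as.character(speaker)
  raw_text <- as.character(raw_text)
  n <- length(speaker)
  if (length(raw_text) != n)
    stop("`speaker` and `raw_text` must have equal length", call. = FALSE)
  if (is.null(channels)) channels <- sort(unique(speaker))
  if (length(channels) > 2L)
    stop("a dyadic conversation has at most two channels, got: ",
         paste(channels, collapse = ", "), call. = FALSE)
  if (!all(speaker %in% channels))
    stop("speaker values outside declared channels: ",
         paste(setdiff(speaker, channels), collapse = ", "), call. = FALSE)
  if (is.null(clean_text) || is.null(codes) || is.null(notations)) {
    ext <- lapply(raw_text, extract_annotations, registry = registry,
                  strict = strict)
    if (is.null(clean_text)) clean_text <- vapply(ext, `[[`, "", "clean_text")
    if (is.null(codes)) codes <- lapply(ext, `[[`, "codes")
    if (is.null(notations)) notations <- lapply(ext, `[[`, "notations")
  }
  structure(list(
    id = id,
    channels = channels,
    turns = data.frame(index = seq_len(n) - 1L, speaker = speaker,
                       raw_text = raw_text, clean_text = as.character(clean_text),
                       stringsAsFactors = FALSE),
    codes = codes,
    notations = notations
  ), class = "conversation")
}

#' @export
print.conversation <- function(x, ...) {
  cat(sprintf("<conversation '%s': %d turns, channels %s>\n", x$id,
              nrow(x$turns), paste(x$channels, collapse = "/")))
  if (nrow(x$turns)) {
    head_n <- min(6L, nrow(x$turns))
    for (i in seq_len(head_n)) {
      cd <- if (length(x$codes[[i]])) paste0(" [", paste(x$codes[[i]], collapse = ","), "]") else ""
      cat(sprintf("  %3d %-4s %s%s\n", x$turns$index[i], x$turns$speaker[i],
                  x$turns$clean_text[i], cd))
    }
    if (nrow(x$turns) > head_n) cat("  ...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.conversation <- function(x, ...) {
  d <- x$turns
  d$conversation_id <- x$id
  d$behaviour_codes <- vapply(x$codes, paste, "", collapse = ";")
  d$notations <- vapply(x$notations, paste, "", collapse = ";")
  d[c("conversation_id", "index", "speaker", "raw_text", "clean_text",
      "behaviour_codes", "notations")]
}

#' Separate spoken content from inline annotations
#'
#' Splits a single raw transcript line into spoken text, behaviour codes and
#' transcription notations. Bracketed spans `[X]` whose content is a plain
#' alphanumeric label are treated as behaviour codes; bracketed reconstruction
#' fragments such as `[wh-]` are dropped from the text silently. Parenthetical
#' spans are removed from the spoken text; those matching the notation
#' vocabulary (case-insensitively) are recorded as notations.
#'
#' @param raw_text A single transcript line.
#' @param registry Admissible behaviour code labels (matched case-sensitively).
#' @param notation_vocab Recognised parenthetical notations.
#' @param strict Logical; if `TRUE`, an unknown bracketed code is an error,
#'   otherwise it is kept with a warning (supporting user-defined schemes).
#' @param quiet Logical; suppress warnings about unknown codes and unbalanced
#'   delimiters.
#' @return A list with `clean_text` (string), `codes` (sorted unique character
#'   vector) and `notations` (sorted unique character vector).
#' @examples
#' extract_annotations("That must have been a bit hard (SPause) [GiveTime].")
#' extract_annotations("And [wh-] where did you live before?")
#' @export
extract_annotations <- function(raw_text, registry = behaviour_registry()$label,
                                notation_vocab = default_notations(),
                                strict = FALSE, quiet = FALSE) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  txt <- raw_text
  codes <- character()
  m <- gregexpr("\\[[^][]*\\]", txt)
  spans <- regmatches(txt, m)[[1]]
  for (sp in spans) {
    inner <- substr(sp, 2L, nchar(sp) - 1L)
    if (grepl("^[A-Za-z][A-Za-z0-9]*$", inner)) {
      if (!(inner %in% registry)) {
        if (strict)
          stop(sprintf("unknown behaviour code '%s' in: %s", inner, raw_text),
               call. = FALSE)
        if (!quiet)
          warning(sprintf("unknown behaviour code '%s' kept", inner),
                  call. = FALSE)
      }
      codes <- c(codes, inner)
    }
    # otherwise a reconstruction fragment like [wh-]: dropped from the text
  }
  txt <- gsub("\\[[^][]*\\]", " ", txt)

  pm <- gregexpr("\\([^()]*\\)", txt)
  pspans <- regmatches(txt, pm)[[1]]
  notes <- character()
  if (length(pspans)) {
    inner <- substr(pspans, 2L, nchar(pspans) - 1L)
    hit <- tolower(trimws(inner)) %in% tolower(notation_vocab)
    # report notations under their canonical registry spelling
    canon <- notation_vocab[match(tolower(trimws(inner))[hit], tolower(notation_vocab))]
    notes <- canon
  }
  txt <- gsub("\\([^()]*\\)", " ", txt)

  if (grepl("[][()]", txt) && !quiet)
    warning("unbalanced annotation delimiters treated as literal text: ",
            raw_text, call. = FALSE)

  txt <- gsub("[[:space:]]+", " ", txt)
  txt <- gsub(" +([.,!?;:])", "\\1", txt)
  txt <- trimws(txt)
  list(clean_text = txt,
       codes = sort(unique(codes)),
       notations = sort(unique(notes)))
}

#' Parse an annotated speaker-turn transcript
#'
#' Reads a two-column delimited transcript (`speaker`, `text`; an optional
#' third `utterance_id` column is ignored for indexing), extracts behaviour
#' codes and notations from each line, and returns a [conversation()] object.
#' Rows that consist solely of an `(interruption)` notation mark excluded
#' interruptions and are dropped; remaining turns are re-indexed from 0
#' without reordering.
#'
#' @param file Path or connection to a delimited text file.
#' @param channels Optional character vector of the two channel identifiers;
#'   defaults to the distinct speaker values found (which must be exactly two).
#' @param id Conversation identifier; defaults to the file name.
#' @param sep Field delimiter (`","` by default; `"\t"` accepted).
#' @param header Logical; whether the file has a `speaker,text` header row.
#' @param strict Logical; error on behaviour codes outside `registry`.
#' @param drop_interruptions Logical; drop dedicated interruption rows.
#' @param registry,notation_vocab Code and notation vocabularies, see
#'   [extract_annotations()].
#' @param quiet Logical; suppress parse warnings.
#' @return A `conversation` object.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c('speaker,text', 'PWD,"Yes."',
#'              'CS,"Oh did you [VblAck]?"'), f)
#' parse_transcript(f)
#' @export
parse_transcript <- function(file, channels = NULL, id = NULL, sep = ",",
                             header = TRUE, strict = FALSE,
                             drop_interruptions = TRUE,
                             registry = behaviour_registry()$label,
                             notation_vocab = default_notations(),
                             quiet = FALSE) {
  dat <- tryCatch(
    utils::read.table(file, sep = sep, header = header, quote = "\"",
                      colClasses = "character", comment.char = "",
                      stringsAsFactors = FALSE, fill = FALSE,
                      blank.lines.skip = TRUE),
    error = function(e) stop("empty or unreadable transcript: ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(dat) == 0L) stop("empty transcript: no utterance rows", call. = FALSE)
  if (header) {
    nm <- tolower(names(dat))
    sp_col <- match("speaker", nm)
    tx_col <- match("text", nm)
    if (is.na(sp_col) || is.na(tx_col))
      stop("transcript header must contain `speaker` and `text` columns",
           call. = FALSE)
  } else {
    if (ncol(dat) < 2L) stop("transcript needs two columns: speaker, text",
                             call. = FALSE)
    sp_col <- 1L; tx_col <- 2L
  }
  speaker <- trimws(dat[[sp_col]])
  txt <- dat[[tx_col]]
  obs <- unique(speaker)
  if (length(obs) > 2L)
    stop("dyad violation: more than two distinct speakers: ",
         paste(obs, collapse = ", "), call. = FALSE)
  if (is.null(channels)) {
    if (length(obs) < 2L)
      stop("only one speaker channel observed (", obs,
           "); supply `channels` to parse a monologue fragment", call. = FALSE)
    channels <- obs
  } else {
    if (length(channels) != 2L)
      stop("`channels` must name exactly two speaker roles", call. = FALSE)
    if (!all(obs %in% channels))
      stop("speaker values outside declared channels: ",
           paste(setdiff(obs, channels), collapse = ", "), call. = FALSE)
  }
  ext <- lapply(txt, function(line) {
    tryCatch(extract_annotations(line, registry = registry,
                                 notation_vocab = notation_vocab,
                                 strict = strict, quiet = quiet),
             error = function(e) stop(conditionMessage(e), call. = FALSE))
  })
  clean <- vapply(ext, `[[`, "", "clean_text")
  codes <- lapply(ext, `[[`, "codes")
  notes <- lapply(ext, `[[`, "notations")
  if (drop_interruptions) {
    is_int <- vapply(notes, function(x) "interruption" %in% x, NA) & !nzchar(clean)
    if (any(is_int)) {
      keep <- !is_int
      speaker <- speaker[keep]; txt <- txt[keep]
      clean <- clean[keep]; codes <- codes[keep]; notes <- notes[keep]
    }
  }
  if (is.null(id))
    id <- if (is.character(file)) tools::file_path_sans_ext(basename(file)) else "conversation"
  conversation(speaker = speaker, raw_text = txt, clean_text = clean,
               codes = codes, notations = notes, channels = channels, id = id)
}

#' Write a conversation back to delimited text
#'
#' Emits the verbatim `speaker,text` rows (RFC-4180 quoting) so that
#' `parse_transcript(write_conversation(x))` round-trips to an identical
#' conversation. An empty conversation yields a header-only file.
#'
#' @param conv A `conversation` object.
#' @param file Path or connection to write to.
#' @return `file`, invisibly.
#' @export
write_conversation <- function(conv, file) {
  stopifnot(inherits(conv, "conversation"))
  d <- data.frame(speaker = conv$turns$speaker, text = conv$turns$raw_text,
                  stringsAsFactors = FALSE)
  utils::write.csv(d, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}
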