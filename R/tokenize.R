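#' Tokenise annotation-free utterance text
#'
#' Lowercases, strips punctuation and segments into word tokens. Contractions
#' are kept as single tokens (`don't`), hyphens act as separators so repaired
#' false starts (`they-`) yield the bare word, and leading/trailing
#' apostrophes are trimmed (`'cause` -> `cause`).
#'
#' @param text Character vector of clean utterance texts.
#' @return For a single string, a character vector of tokens; for a longer
#'   input, a list of such vectors. Empty or missing text yields no tokens.
#' @examples
#' tokenize("No they don't bark so much.")
#' tokenize("they- you- you could pet them")
#' @export
tokenize <- function(text) {
  if (length(text) == 0L) return(list())
  x <- tolower(as.character(text))
  x[is.na(x)] <- ""
  x <- gsub("[‘’ʼ]", "'", x)
  x <- gsub("-", " ", x, fixed = TRUE)
  x <- gsub("[^a-z0-9' ]", " ", x)
  x <- trimws(gsub(" +", " ", x))
  toks <- strsplit(x, " ", fixed = TRUE)
  toks <- lapply(toks, function(t) {
    t <- gsub("^'+|'+$", "", t)
    t[nzchar(t)]
  })
  if (length(text) == 1L) toks[[1]] else toks
}

#' Default stopword list
#'
#' Reads the packaged stopword file (one term per line, UTF-8, `#` comments):
#' an English function-word list extended with semantically empty or
#' ambiguous conversational fillers. Fully user-overridable — pass any
#' character vector wherever a stopword set is accepted, or point `path` at
#' a custom file.
#'
#' @param path Path to a stopword file.
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function(path = system.file("extdata", "stopwords_en.txt",
                                                 package = "convrecur")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- tolower(trimws(lines))
  unique(lines[nzchar(lines)])
}
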