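# Independent brute-force oracles used to pin expected values.
# These deliberately re-derive everything from first principles (token sets,
# pairwise loops) rather than calling package internals.

# conversation from plain space-separated word strings
make_conv <- function(speaker, texts, id = "test") {
  conversation(speaker = speaker, raw_text = texts, id = id)
}

# binary cosine of two token sets
oracle_sim <- function(set_a, set_b) {
  m <- length(set_a); n <- length(set_b)
  if (m == 0 || n == 0) return(0)
  length(intersect(set_a, set_b)) / sqrt(m * n)
}

# full similarity matrix from raw texts: lowercase space-split tokens,
# stopwords removed, distinct terms per turn
oracle_sim_matrix <- function(texts, stopwords = character()) {
  sets <- lapply(texts, function(x) {
    t <- unlist(strsplit(tolower(x), " +"))
    t <- t[nzchar(t)]
    setdiff(unique(t), stopwords)
  })
  n <- length(sets)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) S[i, j] <- oracle_sim(sets[[i]], sets[[j]])
  S
}

# exhaustive windowed means over qualifying turns
oracle_metrics <- function(S, speaker,
                           windows = c(short = 1, medium = 10, long = Inf)) {
  n <- nrow(S)
  cols <- c(t(outer(c("other", "self"),
                    c("forward_short", "forward_medium", "forward_long",
                      "backward_short", "backward_medium", "backward_long"),
                    paste, sep = "_")))
  out <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  for (t in seq_len(n)) {
    for (ty in c("other", "self")) {
      for (dir in c("forward", "backward")) {
        for (w in c("short", "medium", "long")) {
          ww <- windows[[w]]
          us <- seq_len(n)
          us <- if (dir == "forward") us[us > t & us - t <= ww]
                else us[us < t & t - us <= ww]
          us <- if (ty == "other") us[speaker[us] != speaker[t]]
                else us[speaker[us] == speaker[t]]
          out[t, paste(ty, dir, w, sep = "_")] <-
            if (length(us)) mean(S[t, us]) else 0
        }
      }
    }
  }
  out
}

# random conversation over a tiny no-stopword alphabet; same-speaker
# adjacencies allowed on purpose
random_conversation <- function(n_turns = NULL, max_vocab = 10) {
  alphabet <- c("apple", "bear", "creek", "dune", "elm", "fern", "gull",
                "heron", "iris", "jade")[seq_len(max_vocab)]
  if (is.null(n_turns)) n_turns <- sample(2:12, 1)
  speaker <- sample(c("CS", "PWD"), n_turns, replace = TRUE)
  texts <- vapply(seq_len(n_turns), function(i) {
    k <- sample(0:4, 1)
    paste(sample(alphabet, k, replace = TRUE), collapse = " ")
  }, "")
  list(conv = make_conv(speaker, texts), texts = texts, speaker = speaker)
}

# closed-form 2x2 association, written out directly
oracle_or <- function(a, b, c, d, z = qnorm(0.975)) {
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se),
       p = 2 * pnorm(-abs(log(or) / se)))
}

# records table with exactly the given 2x2 cells for one behaviour/outcome
records_from_cells <- function(a, b, c, d, behaviour = "ActListen",
                               outcome = "fwd_short") {
  n <- a + b + c + d
  rec <- data.frame(
    conversation_id = "planted", index = seq_len(n) - 1L, speaker = "CS",
    codes = rep(c(behaviour, ""), c(a + b, c + d)),
    fwd_short = FALSE, fwd_medium = FALSE, fwd_long = FALSE,
    bwd_short = FALSE, bwd_medium = FALSE, bwd_long = FALSE,
    stringsAsFactors = FALSE)
  rec[[outcome]] <- rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d))
  rec
}

excerpt_path <- function() {
  system.file("extdata", "dyad_excerpt.csv", package = "convrecur")
}
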