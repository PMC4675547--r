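test_that("tokeniser handles contractions, false starts and empty text", {
  expect_equal(tokenize("No they don't bark so much."),
               c("no", "they", "don't", "bark", "so", "much"))
  expect_equal(tokenize(""), character())
  expect_equal(tokenize("they- you- you could pet them"),
               c("they", "you", "you", "could", "pet", "them"))
  expect_equal(tokenize("'cause it's FINE!"), c("cause", "it's", "fine"))
})

test_that("vocabulary ranks by frequency with first-occurrence ties, capped and stopword-free", {
  sw <- default_stopwords()
  cv <- make_conv(c("PWD", "CS"),
                  c("bark bark yelp the and", "yelp bark wag"))
  v <- build_vocabulary(cv, stopwords = sw)
  expect_equal(v$terms, c("bark", "yelp", "wag"))   # 3,2,1 occurrences
  expect_true(length(intersect(v$terms, sw)) == 0)

  # cap not binding: all non-stopword terms retained
  expect_lte(length(v$terms), v$max_terms)

  # 300 distinct equally-frequent terms -> first 200 in occurrence order,
  # expected list derived with an independent counter
  words <- sprintf("word%03d", 1:300)
  texts <- vapply(split(words, rep(1:30, each = 10)), paste, "", collapse = " ")
  cv2 <- make_conv(rep(c("PWD", "CS"), 15), unname(texts))
  v2 <- build_vocabulary(cv2, stopwords = sw, max_terms = 200)
  toks <- unlist(strsplit(tolower(unname(texts)), " "))
  counts <- table(toks)
  expect_true(all(counts == 1))
  expect_equal(v2$terms, unique(toks)[1:200])

  # all-stopword conversation: empty vocabulary, all similarities zero
  cv3 <- make_conv(c("PWD", "CS"), c("oh yes it was", "yeah it was"))
  v3 <- build_vocabulary(cv3, stopwords = sw)
  expect_length(v3$terms, 0)
  expect_true(all(recurrence_matrix(cv3, v3)$sim == 0))
})

test_that("binary-cosine similarity matches the brute-force oracle", {
  expect_equal(term_similarity(c(1, 0), c(1, 0)), 1.0)
  expect_equal(term_similarity(c(1, 0), c(0, 1)), 0.0)
  # m = 4, n = 2, shared = 1 -> 1/sqrt(8); m = 2, n = 4, shared = 2 -> 2/sqrt(8)
  a <- c(1, 1, 1, 1, 0); b <- c(1, 0, 0, 0, 1)
  expect_equal(term_similarity(a, b), 1 / sqrt(8))
  expect_equal(term_similarity(c(1, 1, 0, 0, 0), c(1, 1, 1, 1, 0)), 2 / sqrt(8))
  expect_error(term_similarity(c(1, 0), c(1, 0, 1)), "dimension")

  set.seed(42)
  for (i in 1:50) {
    v <- sample(3:8, 1)
    a <- rbinom(v, 1, 0.5); b <- rbinom(v, 1, 0.5)
    sa <- which(a == 1); sb <- which(b == 1)
    expect_equal(term_similarity(a, b), oracle_sim(sa, sb))
    expect_equal(term_similarity(a, b), term_similarity(b, a))
    expect_gte(term_similarity(a, b), 0)
    expect_lte(term_similarity(a, b), 1)
  }
})

test_that("adding a shared term never decreases pairwise similarity", {
  set.seed(7)
  for (i in 1:40) {
    v <- sample(4:9, 1)
    a <- rbinom(v, 1, 0.5); b <- rbinom(v, 1, 0.5)
    free <- which(a == 0 & b == 0)
    if (!length(free)) next
    j <- free[1]
    a2 <- a; b2 <- b; a2[j] <- 1; b2[j] <- 1
    expect_gte(term_similarity(a2, b2), term_similarity(a, b))
  }
})

test_that("recurrence matrix is symmetric, bounded and zero without shared terms", {
  cv1 <- make_conv("PWD", "bark bark")
  m1 <- recurrence_matrix(cv1)
  expect_equal(dim(m1$sim), c(1L, 1L))
  expect_equal(m1$sim[1, 1], 1)

  cv2 <- make_conv(c("PWD", "CS"), c("bark", "yelp"))
  expect_equal(recurrence_matrix(cv2)$sim[1, 2], 0)

  set.seed(11)
  for (i in 1:20) {
    rc <- random_conversation()
    m <- recurrence_matrix(rc$conv)
    expect_equal(m$sim, t(m$sim))
    expect_true(all(m$sim >= 0 & m$sim <= 1))
    S <- oracle_sim_matrix(rc$texts)
    off <- upper.tri(S)
    expect_equal(m$sim[off], S[off], tolerance = 1e-12)
  }
})

test_that("windowed metrics match direct small-case expectations", {
  # PWD CS PWD CS ...: single shared pair at adjacent turns 1-2
  cv <- make_conv(rep(c("PWD", "CS"), 6),
                  c("fern", "creek bear", "bear dune elm", "apple", "iris",
                    "gull", "jade", "moss", "pine", "rock", "snow", "toad"))
  pm <- primitive_metrics(recurrence_matrix(cv))
  s <- 1 / sqrt(2 * 3)
  expect_equal(pm$other_forward_short[2], s)
  # medium window after turn 2 holds 5 other-speaker turns; one is nonzero
  expect_equal(pm$other_forward_medium[2], s / 5)
  expect_equal(pm$other_backward_short[3], s)
  # all-zero turn: every metric zero
  expect_true(all(pm[1, -1] >= 0))
  expect_true(all(pm[5, -1] == 0))
  # last turn has no forward window
  expect_equal(unlist(pm[12, c("other_forward_short", "other_forward_medium",
                               "other_forward_long", "self_forward_short",
                               "self_forward_medium", "self_forward_long")]),
               c(other_forward_short = 0, other_forward_medium = 0,
                 other_forward_long = 0, self_forward_short = 0,
                 self_forward_medium = 0, self_forward_long = 0))
})

test_that("windowed metrics equal the exhaustive oracle on random conversations", {
  set.seed(123)
  for (i in 1:80) {
    rc <- random_conversation()
    m <- recurrence_matrix(rc$conv)
    pm <- primitive_metrics(m)
    S <- oracle_sim_matrix(rc$texts)
    om <- oracle_metrics(S, rc$speaker)
    expect_equal(as.matrix(pm[, colnames(om)]), om, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("long-range means are bounded by the row maximum and match medium on short conversations", {
  set.seed(21)
  for (i in 1:30) {
    rc <- random_conversation(n_turns = sample(2:11, 1))
    m <- recurrence_matrix(rc$conv)
    pm <- primitive_metrics(m)
    S <- m$sim; diag(S) <- 0
    n <- nrow(S)
    for (t in seq_len(n)) {
      later <- if (t < n) max(S[t, (t + 1):n]) else 0
      expect_lte(pm$other_forward_long[t], later + 1e-12)
      expect_gte(pm$other_forward_long[t], 0)
    }
    # <= 11 turns after t means the 10-turn window spans the remainder
    expect_equal(pm$other_forward_medium, pm$other_forward_long)
    expect_equal(pm$self_backward_medium, pm$self_backward_long)
  }
})

test_that("appending stopwords to utterances leaves all metrics unchanged", {
  set.seed(5)
  rc <- random_conversation(n_turns = 10)
  pm1 <- primitive_metrics(recurrence_matrix(rc$conv))
  noisy <- paste(rc$texts, "oh yeah well you know right")
  pm2 <- primitive_metrics(recurrence_matrix(make_conv(rc$speaker, noisy)))
  expect_equal(pm1, pm2, tolerance = 1e-12)
})

test_that("recurrence plots render to file for normal, empty and all-zero inputs", {
  cv <- parse_transcript(excerpt_path())
  an <- analyze_conversation(cv)
  f <- tempfile(fileext = ".png")
  render_recurrence_plot(an$matrix, cv, file = f)
  expect_true(file.exists(f) && file.info(f)$size > 0)

  f2 <- tempfile(fileext = ".svg")
  empty <- conversation(character(), character(), channels = c("CS", "PWD"))
  render_recurrence_plot(recurrence_matrix(empty), empty, file = f2)
  expect_true(file.exists(f2))

  cvz <- make_conv(c("PWD", "CS"), c("bark", "yelp"))
  f3 <- tempfile(fileext = ".png")
  plot(recurrence_matrix(cvz), conv = cvz, file = f3)
  expect_true(file.exists(f3))
})

test_that("metrics export carries metadata and the twelve metric columns", {
  cv <- parse_transcript(excerpt_path())
  d <- metrics_table(analyze_conversation(cv))
  expect_equal(nrow(d), 14L)
  expect_true(all(c("conversation_id", "index", "speaker", "text",
                    "other_forward_short", "self_backward_long",
                    "behaviour_codes") %in% names(d)))
  expect_equal(d$behaviour_codes[4], "ActListen")
})
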