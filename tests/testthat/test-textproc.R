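test_that("sentences cover the text and slice back to exact substrings", {
  s <- segment_sentences("He is agitated. Sleep was poor.", "d")
  expect_length(s, 2L)
  expect_identical(s[[1]]$text, "He is agitated.")
  expect_identical(s[[2]]$text, "Sleep was poor.")

  s1 <- segment_sentences("no terminal punctuation here", "d")
  expect_length(s1, 1L)

  note <- "Seen on the ward today. Mood was settled; no concerns voiced.\nPlan unchanged."
  ss <- segment_sentences(note, "d")
  expect_length(ss, 3L)
  for (x in ss) {
    expect_identical(substr(note, x$start + 1L, x$end), x$text)
    # all token offsets reconstruct their token text
    for (i in seq_len(nrow(x$tokens))) {
      expect_identical(substr(note, x$tokens$start[i] + 1L, x$tokens$end[i]),
                       x$tokens$text[i])
    }
  }
  expect_identical(segment_sentences("   ", "d"), list())
})

test_that("tokenizer peels edge punctuation and keeps hyphenated words whole", {
  t1 <- tokenize("(He was well-kempt), calm.")
  expect_identical(t1$text,
                   c("(", "He", "was", "well-kempt", ")", ",", "calm", "."))
  expect_identical(t1$is_word,
                   c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  # offsets are 0-based half-open and non-overlapping in order
  expect_true(all(diff(t1$start) > 0))
  expect_true(all(t1$start < t1$end))
})

test_that("shared keywords yield one match per concept with a met definition", {
  lex <- default_lexicon()
  s <- one_sentence("There was some poverty of speech and content of thought.")
  km <- match_keywords(s, lex)
  expect_setequal(km$concept, c("Poverty of speech", "Pressured speech"))

  expect_identical(nrow(match_keywords(one_sentence("Plan unchanged"), lex)), 0L)

  km2 <- match_keywords(one_sentence("eye contact and rapport were good"), lex)
  expect_setequal(km2$concept, c("Diminished eye contact", "Poor rapport"))
})

test_that("modifiers attach within the eight-word window in both directions", {
  lex <- default_lexicon()
  x <- first_instance(paste("For past 1 week has been having auditory command",
                            "hallucinations telling him to kill himself."),
                      lex, "Hallucinations")
  expect_identical(x$modifiers$pattern, "audit*")
  expect_identical(x$modifiers$distance, 1L)

  # exactly eight intervening word tokens: attached
  x8 <- first_instance("sleep has over the past two weeks been badly disturbed",
                       lex, "Disturbed sleep")
  expect_true("disturb*" %in% x8$modifiers$pattern)
  expect_identical(x8$modifiers$distance[x8$modifiers$pattern == "disturb*"], 8L)

  # nine intervening word tokens: not attached
  x9 <- first_instance("sleep has over the past two weeks been very badly disturbed",
                       lex, "Disturbed sleep")
  expect_false("disturb*" %in% x9$modifiers$pattern)

  # punctuation-only tokens do not count towards the window
  xp <- first_instance("sleep has , over , the past two weeks been badly disturbed",
                       lex, "Disturbed sleep")
  expect_true("disturb*" %in% xp$modifiers$pattern)
})

test_that("instance definitions honour mandatory and optional modifier modes", {
  lex <- default_lexicon()
  inst <- build_instances("Speech was pressured.", "d", lex)
  expect_identical(vapply(inst, `[[`, "", "concept"), "Pressured speech")

  # keyword shared with a mandatory-modifier concept: only the met definition
  inst2 <- build_instances("Mood was elevated.", "d", lex,
                           include_excluded = TRUE)
  expect_setequal(vapply(inst2, `[[`, "", "concept"),
                  c("Elevated mood", "Low mood"))

  inst3 <- build_instances(
    "These hallucinations are sometimes in a kind of shadow form.", "d", lex)
  expect_identical(inst3[[1]]$concept, "Hallucinations")
  expect_identical(nrow(inst3[[1]]$modifiers), 0L)

  expect_identical(build_instances("", "d", lex), list())
})

test_that("instance finder is deterministic and stays within sentences", {
  lex <- compile_lexicon(default_lexicon())
  text <- paste("Presented with auditory hallucinations. No evidence of",
                "paranoia today. Speech was pressured and rapport was poor.")
  a <- instances_to_df(build_instances(text, "d", lex))
  b <- instances_to_df(build_instances(text, "d", lex))
  expect_identical(a, b)
  sents <- segment_sentences(text, "d")
  for (x in build_instances(text, "d", lex)) {
    owner <- Filter(function(s) s$start == x$sentence$start, sents)[[1]]
    expect_true(x$keyword$first >= 1 && x$keyword$last <= nrow(owner$tokens))
  }
})

test_that("instance finder agrees with the brute-force oracle on random sentences", {
  lex <- compile_lexicon(default_lexicon())
  pool <- oracle_token_pool(lex)
  set.seed(401)
  for (i in seq_len(150)) {
    toks <- random_sentence_tokens(pool, max_len = 30L)
    text <- paste(toks, collapse = " ")
    sent <- segment_sentences(text, "d")
    if (length(sent) != 1L) next
    got <- pipeline_instances_keyed(text, lex)
    want <- oracle_instances(sent[[1]]$tokens, lex)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got[c("concept", "first", "last")], want,
                     label = paste("sentence:", text))
  }
})

test_that("corpus and instance files round-trip through NDJSON", {
  corpus <- data.frame(
    doc_id = c("D1", "D2"), patient_id = c("P1", "P1"),
    doc_type = "discharge_summary", date = "2014-01-01",
    icd10_codes = I(list(c("F20.0"), character())),
    text = c("Speech was pressured.", "Plan unchanged."),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".ndjson")
  write_corpus(corpus, f)
  back <- read_corpus(f)
  expect_identical(back$doc_id, corpus$doc_id)
  expect_identical(back$text, corpus$text)
  expect_identical(back$icd10_codes[[1]], "F20.0")

  inst <- add_context(build_instances(corpus$text[1], "D1", default_lexicon()))
  f2 <- withr::local_tempfile(fileext = ".ndjson")
  write_instances(inst, f2)
  rec <- jsonlite::fromJSON(readLines(f2)[1])
  expect_identical(rec$concept, "Pressured speech")
  expect_identical(rec$doc_id, "D1")
})
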