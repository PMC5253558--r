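test_that("shipped editions carry the full 50-concept inventory", {
  for (ed in c("curated", "table1_verbatim")) {
    lex <- default_lexicon(ed)
    expect_length(lex$concepts, 50L)
    status <- vapply(lex$concepts, `[[`, "", "status")
    expect_setequal(names(status)[status == "excluded"],
                    c("Loosening of associations", "Stereotypy", "Low mood",
                      "Poor motivation"))
    expect_setequal(names(status)[status == "hand_annotate"],
                    c("Catalepsy", "Echopraxia"))
    expect_identical(names(status)[status == "keyword_only"], "Mutism")
    # every non-excluded concept maps to exactly one domain
    for (cc in lex$concepts) {
      if (cc$status != "excluded") {
        expect_true(cc$domain %in%
                      c("positive", "negative", "disorganisation", "manic",
                        "catatonic"), label = cc$name)
      }
    }
  }
})

test_that("domain groupings partition the inventory as published", {
  lex <- default_lexicon()
  doms <- vapply(lex$concepts, `[[`, "", "domain")
  status <- vapply(lex$concepts, `[[`, "", "status")
  # the five domains + the 4 excluded concepts account for all 50
  expect_identical(sum(!is.na(doms)) + sum(status == "excluded"), 50L)
  counts <- table(doms[!is.na(doms)])
  # published groupings: 8 positive, 11 negative, 7 disorganisation, 8 manic,
  # 11 catatonic, plus catatonic syndrome assigned editorially to catatonic
  expect_identical(as.integer(counts[c("positive", "negative",
                                       "disorganisation", "manic",
                                       "catatonic")]),
                   c(8L, 11L, 7L, 8L, 12L))
  expect_identical(domain_of(lex, "Grandiosity"), "manic")
  expect_identical(domain_of(lex, "Paranoia"), "positive")
  expect_identical(domain_of(lex, "Catatonic syndrome"), "catatonic")
  expect_error(domain_of(lex, "Akathisia"), "unknown concept")
  expect_error(domain_of(lex, "Low mood"), "no domain")
})

test_that("single-row parsing follows the TSV dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("concept\tkeywords\tmodifiers\tmodifier_mode\tsnomed_ids\tdomain\tstatus",
               "Delusions\tdelusion*\t\tnone\t2073000\tpositive\tml_model"), f)
  lex <- load_lexicon(f)
  cc <- lex$concepts$Delusions
  expect_length(cc$keyword_patterns, 1L)
  expect_identical(cc$keyword_patterns[[1]], "delusion*")
  expect_identical(cc$modifier_mode, "none")
  expect_identical(cc$snomed_ids, "2073000")
})

test_that("malformed lexicon input is rejected with a line reference", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), f)
  expect_error(load_lexicon(f), "empty")

  writeLines(c("concept\tkeywords\tmodifiers\tmodifier_mode\tsnomed_ids\tdomain\tstatus",
               "A\tfoo*\t\tnone\t\tpositive\tml_model",
               "A\tbar\t\tnone\t\tmanic\tml_model"), f)
  expect_error(load_lexicon(f), "duplicate")

  writeLines(c("concept\tkeywords\tmodifiers\tmodifier_mode\tsnomed_ids\tdomain\tstatus",
               "A\tfo*o\t\tnone\t\tpositive\tml_model"), f)
  expect_error(load_lexicon(f), "line 2")

  writeLines(c("concept\tkeywords\tmodifiers\tmodifier_mode\tsnomed_ids\tdomain\tstatus",
               "A\tfoo\tbar\tnone\t\tpositive\tml_model"), f)
  expect_error(load_lexicon(f), "modifier_mode")
})

test_that("concept constructor enforces its invariants", {
  expect_error(symptom_concept("X", list()), "keyword")
  expect_error(symptom_concept("X", list("a"), list(), "mandatory",
                               domain = "manic"), "modifier_mode")
  expect_error(symptom_concept("X", list("a"), domain = NA_character_,
                               status = "ml_model"), "domain")
  # excluded concepts may have no domain
  cc <- symptom_concept("X", list("a"), status = "excluded")
  expect_true(is.na(cc$domain))
})

test_that("compiled patterns follow the prefix-wildcard matching rule", {
  cc <- symptom_concept("Aggression", list(parse_phrase("aggress*")),
                        domain = "positive")
  comp <- compile_patterns(cc)
  expect_identical(nrow(match_phrase(c("aggression"), comp$keywords[[1]])), 1L)
  expect_identical(nrow(match_phrase(c("aggressive"), comp$keywords[[1]])), 1L)
  expect_identical(nrow(match_phrase(c("anger"), comp$keywords[[1]])), 0L)

  waxy <- compile_patterns(symptom_concept("Waxy flexibility",
                                           list(parse_phrase("waxy")),
                                           domain = "catatonic"))
  expect_identical(nrow(match_phrase("waxy", waxy$keywords[[1]])), 1L)
  expect_identical(nrow(match_phrase("waxes", waxy$keywords[[1]])), 0L)

  tb <- compile_patterns(symptom_concept("Thought block",
                                         list(parse_phrase("though* block")),
                                         domain = "disorganisation"))
  expect_identical(nrow(match_phrase(c("thought", "block"), tb$keywords[[1]])), 1L)
  expect_identical(nrow(match_phrase(c("thought", "blocking"), tb$keywords[[1]])), 0L)
})

test_that("lexicon round-trips through serialization", {
  lex <- default_lexicon()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, f)
  lex2 <- load_lexicon(f, version = lex$version)
  expect_identical(lex2$concepts, lex$concepts)
})

test_that("curated and verbatim editions differ exactly where documented", {
  cur <- default_lexicon("curated")
  ver <- default_lexicon("table1_verbatim")
  expect_identical(cur$concepts$Hallucinations$keyword_patterns[[1]],
                   "hallucinat*")
  expect_identical(ver$concepts$Hallucinations$keyword_patterns[[1]],
                   "hallucinate*")
  expect_identical(cur$concepts$`Flight of ideas`$keyword_patterns[[1]],
                   c("flight", "of", "idea*"))
  expect_identical(ver$concepts$`Flight of ideas`$keyword_patterns[[1]],
                   c("flight", "of", "idea"))
  same <- setdiff(names(cur$concepts), c("Hallucinations", "Flight of ideas"))
  expect_identical(cur$concepts[same], ver$concepts[same])
})
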