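test_that("dictionary tagging is leftmost-longest and spans never overlap", {
  lex <- toy_lexicon()
  tokens <- c("the", "met", "protooncogene", "precursor", "was", "isolated")
  spans <- dictionary_tag(tokens, lex)
  biomed <- spans[spans$tag == "NN-BIOMED", ]
  expect_identical(nrow(biomed), 1L)
  expect_identical(biomed$surface, "met protooncogene precursor")
  expect_identical(c(biomed$start, biomed$end), c(2L, 4L))
  # every NN-BIOMED surface form is in the lexicon's form index
  expect_true(all(vapply(biomed$surface, function(s) {
    length(lexicon_lookup(lex, s, case_fold = TRUE)) > 0
  }, logical(1))))
  # empty lexicon tags nothing
  none <- dictionary_tag(tokens, lexicon())
  expect_identical(sum(none$tag == "NN-BIOMED"), 0L)
  expect_identical(nrow(none), length(tokens))
})

test_that("overlapping candidate matches resolve to the longer, leftmost one", {
  lex <- lexicon(list(
    lexical_entry("a b", "noun"),
    lexical_entry("b c d", "noun"),
    lexical_entry("d", "noun")
  ))
  tokens <- c("a", "b", "c", "d")
  spans <- dictionary_tag(tokens, lex)
  biomed <- spans[spans$tag == "NN-BIOMED", ]
  # leftmost wins at position 1 ("a b"), then "d" matches; "b c d" is
  # blocked even though it is longer
  expect_identical(biomed$surface, c("a b", "d"))
  # brute-force check: the greedy choice among all matchings
  all_matches <- list(c(1, 2), c(2, 4), c(4, 4))
  greedy <- list()
  pos <- 1
  while (pos <= 4) {
    open <- Filter(function(m) m[1] == pos, all_matches)
    if (length(open)) {
      lens <- vapply(open, function(m) m[2] - m[1], numeric(1))
      pick <- open[[which.max(lens)]]
      greedy[[length(greedy) + 1]] <- pick
      pos <- pick[2] + 1
    } else pos <- pos + 1
  }
  expect_identical(lapply(seq_len(nrow(biomed)),
                          function(i) c(biomed$start[i], biomed$end[i])),
                   lapply(greedy, as.integer))
})

test_that("tagging random token streams is deterministic and non-overlapping", {
  lex <- lexicon(list(
    lexical_entry("gyrA", "noun"), lexical_entry("gyrA protein", "noun"),
    lexical_entry("crp", "noun"), lexical_entry("lacZ fusion", "noun")
  ))
  set.seed(47)
  pool <- c("gyrA", "protein", "crp", "lacZ", "fusion", "the", "of", "in")
  for (i in 1:10) {
    tokens <- sample(pool, sample(5:15, 1), replace = TRUE)
    s1 <- dictionary_tag(tokens, lex)
    s2 <- dictionary_tag(tokens, lex)
    expect_identical(s1, s2)
    # spans tile the token sequence without overlap
    expect_identical(s1$start[1], 1L)
    expect_identical(s1$end[nrow(s1)], length(tokens))
    if (nrow(s1) > 1) {
      expect_true(all(s1$start[-1] == s1$end[-nrow(s1)] + 1L))
    }
  }
})

test_that("the three extraction filters partition lexicon-verb instances", {
  spec <- fixture_spec(seed = 51, n_instances_per_verb = 60,
                       distractors = list(nonlex_rate = 0.2,
                                          ne_free_rate = 0.3,
                                          offframe_rate = 0.1))
  corpus <- gen_parsed_corpus(spec)
  lex <- lexicon(lapply(names(spec$verbs), lexical_entry, pos = "verb"))
  # the known planted frames, straight from the generator spec
  frames <- do.call(rbind, lapply(names(spec$verbs), function(v) {
    data.frame(verb = v, pattern = names(spec$verbs[[v]]$patterns),
               probability = unname(spec$verbs[[v]]$patterns),
               stringsAsFactors = FALSE)
  }))
  sems <- extract_sem_frames(gen_events(spec))
  links <- link_all(sems, frames)$links
  res <- extract_facts(corpus$instances, lex, frames, links)
  rep <- res$report
  # conservation: the three filter outcomes partition lexicon-verb instances
  expect_identical(rep$verbs_in_lexicon,
                   rep$facts_extracted + rep$frame_mismatch +
                     rep$absence_of_ne)
  expect_lte(rep$facts_with_prep_args, rep$facts_extracted)
  # counts match the planted composition
  truth <- corpus$truth
  expect_identical(rep$total_lexical_verbs, nrow(truth))
  expect_identical(rep$verbs_in_lexicon, sum(truth$kind != "nonlex"))
  expect_identical(rep$absence_of_ne, sum(truth$kind == "ne_free"))
  expect_identical(rep$frame_mismatch, sum(truth$kind == "offframe"))
  # planted-fact recovery is exact: precision = recall = 1
  expect_identical(rep$facts_extracted, sum(truth$kind == "planted"))
  fact_ids <- vapply(res$facts, `[[`, character(1), "sentence_id")
  planted_ids <- vapply(corpus$instances[truth$kind == "planted"],
                        `[[`, character(1), "sentence_id")
  expect_setequal(fact_ids, planted_ids)
})

test_that("a fixed no-NE rate is reported exactly", {
  # 30 planted + 70 NE-free instances: 70% of lexicon-verb instances
  # carry no NE, by construction
  spec <- fixture_spec(seed = 53, n_instances_per_verb = 30,
                       verbs = default_verb_specs()["activate"],
                       distractors = list(nonlex_rate = 0,
                                          ne_free_rate = 7 / 3,
                                          offframe_rate = 0))
  corpus <- gen_parsed_corpus(spec)
  lex <- lexicon(list(lexical_entry("activate", "verb")))
  vs <- spec$verbs$activate
  frames <- data.frame(verb = "activate", pattern = names(vs$patterns),
                       probability = unname(vs$patterns),
                       stringsAsFactors = FALSE)
  res <- extract_facts(corpus$instances, lex, frames)
  expect_equal(res$report$absence_of_ne / res$report$verbs_in_lexicon, 0.7)
})

test_that("roles are assigned through frame links, including PP arguments", {
  # "The pXPC3 plasmid codes for an XPC cDNA": an intransitive parse whose
  # for-phrase receives the THEME role through the stored link
  ins <- parsed_instance("code", "active",
                         data.frame(label = c("ARG1", "PP-for"),
                                    category = "NP",
                                    ne_type = c("EXPERIMENTAL", "DNA"),
                                    text = c("The pXPC3 plasmid",
                                             "an XPC cDNA"),
                                    stringsAsFactors = FALSE),
                         sentence_id = "pxpc3")
  lex <- lexicon(list(lexical_entry("code", "verb")))
  frames <- data.frame(verb = "code", pattern = "ARG1#PP-for",
                       probability = 0.2, passive_pct = 0, support = 10,
                       stringsAsFactors = FALSE)
  link <- link_frames(sem_frame("code", c("AGENT", "THEME"),
                                hierarchy = default_role_hierarchy()),
                      "ARG1#PP-for",
                      linking_rules(prototypes = local({
                        p <- default_prototypes()
                        p$THEME <- c("ARG2", "PP-for")
                        p
                      })))
  res <- extract_facts(list(ins), lex, frames, list(link))
  expect_length(res$facts, 1)
  fact <- res$facts[[1]]
  theme <- fact$arguments[fact$arguments$role %in% "THEME", ]
  expect_identical(theme$label, "PP-for")
  expect_identical(theme$text, "an XPC cDNA")
})

test_that("facts and reports serialize to JSONL and TSV", {
  spec <- fixture_spec(seed = 55, n_instances_per_verb = 10)
  corpus <- gen_parsed_corpus(spec)
  lex <- lexicon(lapply(names(spec$verbs), lexical_entry, pos = "verb"))
  frames <- estimate_frames(corpus$instances)
  res <- extract_facts(corpus$instances, lex, frames)
  fj <- tempfile(fileext = ".jsonl"); ft <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fj, ft)))
  write_facts(res$facts, fj)
  expect_identical(length(readLines(fj)), length(res$facts))
  rec <- jsonlite::fromJSON(readLines(fj)[1])
  expect_true(all(c("verb", "sentence_id", "frame", "args") %in% names(rec)))
  write_filter_report(res$report, ft)
  tab <- utils::read.delim(ft)
  expect_identical(tab$facts_extracted, res$report$facts_extracted)
})
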