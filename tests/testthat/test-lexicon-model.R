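test_that("entry and variant invariants are enforced", {
  expect_error(lexical_entry("", "noun"), "non-empty")
  expect_error(lexical_entry("x", "verbish"), "arg")
  expect_error(variant("", "orthographic"), "non-empty")
  # curated sources may not carry a confidence below 1
  expect_error(variant("x", "text-mined", source = "db",
                       confidence_score = 0.7), "corpus")
  expect_silent(variant("x", "text-mined", source = "corpus",
                        confidence_score = 0.7))
  expect_error(
    lexical_entry("il2", "noun",
                  variants = list(variant("IL-2", "acronym"),
                                  variant("IL-2", "acronym"))),
    "duplicate")
  expect_error(
    lexical_entry("il2", "noun",
                  accession_links = list(accession_link("UniProt", "P1"),
                                         accession_link("UniProt", "P1"))),
    "duplicate")
})

test_that("entry ids derive deterministically from lemma and pos", {
  a <- lexical_entry("transcribe", "verb")
  b <- lexical_entry("transcribe", "verb")
  expect_identical(a$entry_id, b$entry_id)
  expect_false(identical(lexical_entry("transcribe", "noun")$entry_id,
                         a$entry_id))
})

test_that("the form index reflects exactly the entries' written forms", {
  lex <- toy_lexicon()
  # every lemma and variant form is indexed to its owning entry
  for (e in lex$entries) {
    forms <- c(e$lemma, vapply(e$variants, `[[`, character(1),
                               "written_form"))
    for (f in forms) {
      expect_true(e$entry_id %in% lexicon_lookup(lex, f))
    }
  }
  # nothing else claims a form
  expect_identical(lexicon_lookup(lex, "no such form"), character(0))
  expect_identical(build_form_index(lex), lex$form_index)
})

test_that("related entries must reference existing entries", {
  a <- lexical_entry("absorb", "verb", entry_id = "v1")
  b <- lexical_entry("absorption", "noun", entry_id = "n1",
                     related_entries = data.frame(
                       entry_id = "v1", relation = "nominalized-verb-of"))
  expect_silent(lexicon(list(a, b)))
  bad <- lexical_entry("absorbent", "adjective", entry_id = "a1",
                       related_entries = data.frame(
                         entry_id = "missing", relation = "adjectival"))
  expect_error(lexicon(list(a, bad)), "unknown entries")
})

test_that("XIF round-trips are lossless and byte-deterministic", {
  lex <- lexicon(list(
    lexical_entry("interleukin-2", "noun", semantic_type = "Protein",
                  accession_links = list(accession_link("UniProt", "P60568",
                                                        curated = TRUE)),
                  variants = list(variant("IL-2", "acronym"),
                                  variant("il2", "text-mined", "corpus",
                                          0.87)),
                  inflected_forms = list(word_form("interleukin-2s",
                                                   number = "plural")),
                  data_categories = data.frame(attribute = "SourceDC",
                                               value = "BioThesaurus"),
                  frequency = data.frame(corpus = "MEDLINE",
                                         count = 1234L)),
    lexical_entry("transcribe", "verb")
  ))
  f1 <- tempfile(fileext = ".xml"); f2 <- tempfile(fileext = ".xml")
  on.exit(unlink(c(f1, f2)))
  save_xif(lex, f1)
  back <- load_xif(f1)
  # structural identity
  expect_setequal(names(back$entries), names(lex$entries))
  e0 <- lex$entries[[1]]; e1 <- back$entries[[e0$entry_id]]
  expect_identical(e1$lemma, e0$lemma)
  expect_identical(e1$semantic_type, e0$semantic_type)
  expect_identical(lapply(e1$variants, unclass), lapply(e0$variants, unclass))
  expect_identical(e1$frequency, e0$frequency)
  expect_identical(back$form_index, lex$form_index)
  # save(load(F)) reproduces F byte for byte; repeated saves identical
  save_xif(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  save_xif(lex, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("XIF round-trip identity holds on generated lexicons", {
  for (seed in c(2, 9)) {
    spec <- fixture_spec(seed = seed, n_concepts = 15)
    lex <- lexicon_from_dictionary(gen_dictionary(spec)$dictionary)
    f <- tempfile(fileext = ".xml")
    save_xif(lex, f)
    back <- load_xif(f)
    f2 <- tempfile(fileext = ".xml")
    save_xif(back, f2)
    expect_identical(readLines(f), readLines(f2))
    expect_identical(back$form_index, lex$form_index)
    unlink(c(f, f2))
  }
})

test_that("loading rejects malformed and schema-violating files", {
  bad_xml <- tempfile(fileext = ".xml")
  writeLines("<Lexicon><Entry id='x'", bad_xml)
  expect_error(load_xif(bad_xml))
  bad_pos <- tempfile(fileext = ".xml")
  writeLines(paste0(
    '<Lexicon><Entry id="e1" pos="verbish">',
    '<Lemma writtenForm="x"/></Entry></Lexicon>'), bad_pos)
  expect_error(load_xif(bad_pos), "e1")
  no_lemma <- tempfile(fileext = ".xml")
  writeLines('<Lexicon><Entry id="e2" pos="noun"/></Lexicon>', no_lemma)
  expect_error(load_xif(no_lemma), "e2")
  unlink(c(bad_xml, bad_pos, no_lemma))
})

test_that("staged load is atomic: one bad entry commits nothing", {
  good <- vapply(1:99, function(i) {
    sprintf('<Entry id="e%03d" pos="noun"><Lemma writtenForm="t%03d"/></Entry>',
            i, i)
  }, character(1))
  bad <- '<Entry id="e100" pos="verbish"><Lemma writtenForm="zzz"/></Entry>'
  f <- tempfile(fileext = ".xml")
  writeLines(c("<Lexicon>", good, bad, "</Lexicon>"), f)
  res <- staged_load(f)
  expect_false(res$committed)
  expect_null(res$lexicon)
  expect_length(res$errors, 1)
  expect_match(res$errors, "e100")
  # the valid counterpart commits, and re-loading is idempotent
  f2 <- tempfile(fileext = ".xml")
  writeLines(c("<Lexicon>", good, "</Lexicon>"), f2)
  res1 <- staged_load(f2)
  res2 <- staged_load(f2)
  expect_true(res1$committed)
  expect_length(res1$lexicon$entries, 99)
  expect_identical(names(res1$lexicon$entries), names(res2$lexicon$entries))
  unlink(c(f, f2))
})

test_that("import filtering drops nonsense names and preserves order", {
  terms <- data.frame(
    accession = sprintf("P%d", 1:10),
    term = c("hypothetical protein", "cytochrome c", "Hypothetical Protein 2",
             "lacZ", "unknown gene product", "recA", "fis", "uncharacterized protein X",
             "gyrA", "crp"),
    source = "db", stringsAsFactors = FALSE)
  res <- filter_import_terms(terms)
  expect_identical(nrow(res$rejected), 4L)
  expect_true(all(grepl("hypothetical|unknown|uncharacterized",
                        res$rejected$term, ignore.case = TRUE)))
  expect_identical(rbind(res$kept, res$rejected)[order(c(
    as.integer(rownames(res$kept)), as.integer(rownames(res$rejected)))), ],
    terms)
  # empty stop list keeps everything
  res0 <- filter_import_terms(terms, character(0))
  expect_identical(res0$kept, terms)
  expect_identical(nrow(res0$rejected), 0L)
})
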