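test_that("individual rules are total, deterministic and idempotent", {
  set.seed(41)
  rules <- list(
    norm_rule("case_fold"),
    norm_rule("delete_class", "hyphens"),
    norm_rule("delete_class", "punctuation"),
    norm_rule("delete_class", "spaces"),
    norm_rule("delete_class", "whitespace"),
    norm_rule("substring_rewrite", "our", "or"),
    norm_rule("substring_rewrite", "aa", "a"),  # not idempotent per pass
    norm_rule("token_sort")
  )
  pool <- c(letters[1:5], "A", "B", "-", " ", ".", ",", "o", "u", "r")
  terms <- vapply(1:60, function(i) {
    paste(sample(pool, sample(1:12, 1), replace = TRUE), collapse = "")
  }, character(1))
  terms <- c(terms, "NF-KB", "amino-acid", "tumour", "aaaa b-c")
  for (r in rules) {
    rs <- ruleset(list(r))
    once <- normalize_terms(terms, rs)
    expect_identical(normalize_terms(once, rs), once,
                     info = paste("rule:", r$kind, r$pattern))
  }
})

test_that("normalization applies rules in rank order and handles edge cases", {
  r <- ruleset(list(norm_rule("case_fold"), norm_rule("delete_class", "hyphens")))
  expect_identical(normalize_terms("NF-KB", r), "nfkb")
  expect_identical(normalize_terms("", r), "")
  expect_identical(normalize_terms(c("IL-2", "Il2"), r), c("il2", "il2"))
  # full-set idempotence on random strings
  set.seed(7)
  terms <- replicate(40, paste(sample(c(LETTERS[1:4], "-", " ", "our"), 6,
                                      replace = TRUE), collapse = ""))
  once <- normalize_terms(terms, r)
  expect_identical(normalize_terms(once, r), once)
})

test_that("metrics match the hand-enumerated examples", {
  d <- clustered_dictionary(list(A = c("IL-2", "Il2"), B = "il2"))
  m0 <- compute_metrics(d, ruleset())
  expect_equal(m0$variability, 1.5)
  expect_equal(m0$ambiguity, 1.0)
  r <- ruleset(list(norm_rule("case_fold"), norm_rule("delete_class", "hyphens")))
  m1 <- compute_metrics(d, r)
  expect_equal(m1$variability, 1.0)
  expect_equal(m1$ambiguity, 2.0)
  # dictionary where every cluster already has one unique form
  u <- clustered_dictionary(list(A = "abc", B = "def", C = "ghi"))
  mu <- compute_metrics(u, ruleset())
  expect_equal(mu$variability, 1.0)
  expect_equal(mu$ambiguity, 1.0)
  expect_error(compute_metrics(clustered_dictionary(list(A = "x"))[0, ],
                               ruleset()),
               "empty")
})

test_that("metrics agree with brute-force enumeration on random dictionaries", {
  set.seed(11)
  rules_pool <- list(
    ruleset(),
    ruleset(list(norm_rule("case_fold"))),
    ruleset(list(norm_rule("case_fold"), norm_rule("delete_class", "hyphens"))),
    ruleset(list(norm_rule("delete_class", "spaces")))
  )
  for (i in 1:30) {
    d <- random_dictionary(n_clusters = sample(2:8, 1))
    r <- rules_pool[[sample(length(rules_pool), 1)]]
    m <- compute_metrics(d, r)
    bf <- brute_force_metrics(d, r)
    expect_equal(m$variability, bf$variability)
    expect_equal(m$ambiguity, bf$ambiguity)
  }
})

test_that("appending a rule never increases variability nor decreases ambiguity", {
  set.seed(13)
  extra <- list(norm_rule("case_fold"), norm_rule("delete_class", "hyphens"),
                norm_rule("delete_class", "spaces"),
                norm_rule("substring_rewrite", "b", "a"))
  for (i in 1:20) {
    d <- random_dictionary(n_clusters = sample(3:8, 1))
    base <- ruleset(list(norm_rule("case_fold"))[sample(0:1, 1) + 0])
    r <- extra[[sample(length(extra), 1)]]
    m0 <- compute_metrics(d, base)
    m1 <- compute_metrics(d, ruleset(c(base$rules, list(r))))
    expect_lte(m1$variability, m0$variability)
    expect_gte(m1$ambiguity, m0$ambiguity)
  }
})

test_that("candidate generation recognizes the classic variant pairs", {
  kinds <- function(d) {
    vapply(generate_candidate_rules(d), function(r) {
      paste(r$kind, r$pattern, r$replacement)
    }, character(1))
  }
  expect_true("delete_class hyphens " %in%
                kinds(clustered_dictionary(list(A = c("amino acid",
                                                      "amino-acid")))))
  expect_true("substring_rewrite our or" %in%
                kinds(clustered_dictionary(list(A = c("tumour", "tumor")))))
  expect_true("case_fold  " %in%
                kinds(clustered_dictionary(list(A = c("NF-KB", "NF-kb")))))
  # single-term clusters yield nothing
  expect_length(generate_candidate_rules(
    clustered_dictionary(list(A = "abc", B = "def"))), 0)
})

test_that("greedy induction collapses case-only dictionaries completely", {
  d <- clustered_dictionary(list(A = c("AbcD1", "abcd1"),
                                 B = c("XyZ2", "xyz2"),
                                 C = c("QqQ3", "qqq3")))
  rs <- induce_ruleset(d)
  expect_true("case_fold" %in% vapply(rs$rules, `[[`, character(1), "kind"))
  m <- compute_metrics(d, rs)
  expect_equal(m$variability, 1.0)
  expect_equal(m$ambiguity, 1.0)
})

test_that("a huge ambiguity penalty blocks every harmful candidate", {
  # collapsing case here merges forms across clusters
  d <- clustered_dictionary(list(A = c("ABC", "abc x"), B = "abc"))
  rs <- induce_ruleset(d, lambda = 1e9)
  expect_length(rs$rules, 0)
})

test_that("k_max = 1 selects exactly the single best-scoring candidate", {
  d <- clustered_dictionary(list(A = c("IL-2", "il2", "IL 2"),
                                 B = c("tnf-a", "tnfa")))
  cands <- generate_candidate_rules(d)
  # brute force: score every candidate alone
  m0 <- compute_metrics(d, ruleset())
  scores <- vapply(cands, function(r) {
    m <- compute_metrics(d, ruleset(list(r)))
    (m0$variability - m$variability) - (m$ambiguity - m0$ambiguity)
  }, numeric(1))
  best <- cands[[which.max(scores)]]
  rs <- induce_ruleset(d, k_max = 1)
  expect_length(rs$rules, 1)
  expect_identical(rs$rules[[1]]$kind, best$kind)
  expect_identical(rs$rules[[1]]$pattern, best$pattern)
})

test_that("induction is deterministic", {
  spec <- fixture_spec(seed = 5, n_concepts = 20)
  d <- gen_dictionary(spec)$dictionary
  r1 <- induce_ruleset(d)
  r2 <- induce_ruleset(d)
  expect_identical(lapply(r1$rules, format), lapply(r2$rules, format))
})

test_that("the inverse index equals brute-force normalization of every term", {
  q <- q8k4r9_dictionary()
  rs <- induce_ruleset(q)
  idx <- build_inverse_index(q, rs)
  # every printed variant resolves to the single accession
  for (term in q$term) {
    expect_identical(index_lookup(idx, normalize_terms(term, rs)), "Q8K4R9")
  }
  # raw forms are the keys under the empty rule set
  idx0 <- build_inverse_index(q, ruleset())
  expect_setequal(names(idx0$forms), q$term)
  # random fixtures against independent recomputation
  set.seed(19)
  for (i in 1:10) {
    d <- random_dictionary()
    r <- ruleset(list(norm_rule("case_fold")))
    idx <- build_inverse_index(d, r)
    for (f in names(idx$forms)) {
      hits <- unique(d$accession[normalize_terms(d$term, r) == f])
      expect_setequal(idx$forms[[f]], hits)
    }
  }
})

test_that("rule sets round-trip through their TSV serialization", {
  rs <- ruleset(list(norm_rule("case_fold"),
                     norm_rule("delete_class", "hyphens"),
                     norm_rule("substring_rewrite", "our", "or")))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_ruleset(rs, path)
  rs2 <- read_ruleset(path)
  expect_identical(vapply(rs2$rules, format, character(1)),
                   vapply(rs$rules, format, character(1)))
})
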