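# shared in-code fixtures

# the six printed variants of one hepatoma-up-regulated-protein accession
q8k4r9_dictionary <- function() {
  clustered_dictionary(list(Q8K4R9 = c(
    "Hepatoma up-regulated protein", "Hurp",
    "hepatoma up-regulated protein", "discs large homolog 7",
    "discs, large homolog 7", "Dlg7")))
}

# random accession-clustered dictionary for oracle comparisons
random_dictionary <- function(n_clusters = 5, max_terms = 4) {
  clusters <- lapply(seq_len(n_clusters), function(i) {
    k <- sample(max_terms, 1)
    vapply(seq_len(k), function(j) {
      paste0(paste(sample(c(letters[1:6], "-", " "), sample(3:8, 1),
                          replace = TRUE), collapse = ""), i)
    }, character(1))
  })
  names(clusters) <- sprintf("C%03d", seq_len(n_clusters))
  clusters <- lapply(clusters, function(x) {
    x <- trimws(x)
    unique(x[nzchar(gsub("[- ]", "", x))])
  })
  clusters <- Filter(length, clusters)
  clustered_dictionary(clusters)
}

# brute-force metric computation, written independently of compute_metrics
brute_force_metrics <- function(dict, rules) {
  clusters <- split(dict$term, dict$accession)
  norm <- lapply(clusters, function(terms) {
    unique(normalize_terms(terms, rules))
  })
  variability <- mean(vapply(norm, length, integer(1)))
  all_forms <- unique(unlist(norm))
  amb <- vapply(all_forms, function(f) {
    sum(vapply(norm, function(cl) f %in% cl, logical(1)))
  }, numeric(1))
  list(variability = variability, ambiguity = mean(amb))
}

# small lexicon with two noun entries and one verb entry
toy_lexicon <- function() {
  lexicon(list(
    lexical_entry("met protooncogene precursor", "noun",
                  semantic_type = "Protein",
                  accession_links = list(accession_link("UniProt", "P08581",
                                                        curated = TRUE)),
                  variants = list(variant("MET precursor", "acronym"))),
    lexical_entry("interleukin-2", "noun", semantic_type = "Protein",
                  variants = list(variant("IL-2", "acronym"))),
    lexical_entry("activate", "verb")
  ))
}

# parsed instances built from compact triples (verb, voice, slots, ne types)
mk_instances <- function(...) {
  specs <- list(...)
  lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    parsed_instance(s$verb, s$voice %||% "active",
                    data.frame(label = s$slots,
                               category = "NP",
                               ne_type = s$ne %||% rep(NA_character_,
                                                       length(s$slots)),
                               text = s$text %||% rep(NA_character_,
                                                      length(s$slots)),
                               stringsAsFactors = FALSE),
                    sentence_id = sprintf("t%03d", i))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
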