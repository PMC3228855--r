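#' Semantic type inventory for lexical entries
#'
#' The closed set of semantic categories a term entry may carry, matching
#' the sources the terminological repository draws on (gene and protein
#' names, chemicals, species, operons, ...).
#'
#' @return character vector of category labels.
#' @export
semantic_types <- function() {
  c("Cell", "Cell Component", "Chemical", "Disease", "Enzyme", "Gene",
    "Ligand", "Nuclear Receptor", "Nucleic Acid Region", "Operon",
    "Organism", "Transcription-Factor-Binding-Site", "Protein",
    "Protein Complex", "Protein Domain", "Transcription Regulator")
}

lf_pos <- c("noun", "verb", "adjective", "adverb")
lf_variant_types <- c("orthographic", "morphological", "acronym", "synonym",
                      "structural", "semantic", "text-mined")
lf_relations <- c("nominalization", "adjectival", "adverbial",
                  "orthographic-variant", "nominalized-verb-of")

#' A written variant of a lexical entry
#'
#' @param written_form the variant's written form (non-empty).
#' @param variant_type one of orthographic, morphological, acronym, synonym,
#'   structural, semantic, text-mined.
#' @param source resource name, or `"corpus"` for text-mined variants.
#' @param confidence_score confidence in \[0, 1\]; curated sources carry 1,
#'   and a score below 1 is only allowed for corpus-derived variants.
#' @return a list of class `lf_variant`.
#' @export
variant <- function(written_form, variant_type = "orthographic",
                    source = "db", confidence_score = 1) {
  written_form <- stringi::stri_trans_nfc(written_form)
  if (!nzchar(written_form)) stop("variant written form must be non-empty")
  variant_type <- match.arg(variant_type, lf_variant_types)
  stopifnot(confidence_score >= 0, confidence_score <= 1)
  if (confidence_score < 1 && source != "corpus") {
    stop("confidence below 1 is only allowed for source = 'corpus'")
  }
  structure(list(written_form = written_form, variant_type = variant_type,
                 source = source, confidence_score = confidence_score),
            class = "lf_variant")
}

#' An inflected word form
#'
#' @param written_form non-empty written form.
#' @param ... named feature values (e.g. `tense = "past"`).
#' @return a list of class `lf_wordform`.
#' @export
word_form <- function(written_form, ...) {
  written_form <- stringi::stri_trans_nfc(written_form)
  if (!nzchar(written_form)) stop("word form must be non-empty")
  feats <- list(...)
  structure(list(written_form = written_form, features = feats),
            class = "lf_wordform")
}

#' A link from an entry to a database accession
#'
#' @param database_name e.g. "UniProt", "ChEBI", "NCBI taxonomy".
#' @param accession_id accession identifier.
#' @param curated whether the link comes from a curated source.
#' @return a list of class `lf_accession`.
#' @export
accession_link <- function(database_name, accession_id, curated = FALSE) {
  structure(list(database_name = as.character(database_name),
                 accession_id = as.character(accession_id),
                 curated = isTRUE(curated)),
            class = "lf_accession")
}

#' A lexical entry
#'
#' The unit of the lexicon: a lemma with part of speech, optional semantic
#' type, accession links, scored written variants, inflected forms,
#' derivational relations to other entries, free data categories
#' (attribute-value pairs) and corpus frequency metadata.
#'
#' @param lemma non-empty lemma.
#' @param pos part of speech: noun, verb, adjective or adverb.
#' @param entry_id identifier; derived deterministically from (lemma, pos)
#'   when not supplied, so merges are reproducible.
#' @param semantic_type optional label from [semantic_types()].
#' @param accession_links list of [accession_link()] objects; (database,
#'   accession) pairs must be unique within the entry.
#' @param variants list of [variant()] objects; (written form, type) pairs
#'   must be unique within the entry.
#' @param inflected_forms list of [word_form()] objects.
#' @param related_entries data.frame with columns `entry_id`, `relation`
#'   (one of nominalization, adjectival, adverbial, orthographic-variant,
#'   nominalized-verb-of).
#' @param data_categories data.frame with columns `attribute`, `value`.
#' @param frequency data.frame with columns `corpus`, `count`.
#' @return a list of class `lf_entry`.
#' @export
lexical_entry <- function(lemma, pos, entry_id = NULL, semantic_type = NULL,
                          accession_links = list(), variants = list(),
                          inflected_forms = list(), related_entries = NULL,
                          data_categories = NULL, frequency = NULL) {
  lemma <- stringi::stri_trans_nfc(lemma)
  if (!nzchar(lemma)) stop("lemma must be non-empty")
  pos <- match.arg(pos, lf_pos)
  if (is.null(entry_id)) entry_id <- derive_entry_id(lemma, pos)
  if (!is.null(semantic_type) && !semantic_type %in% semantic_types()) {
    stop("unknown semantic type: ", semantic_type)
  }
  stopifnot(all(vapply(accession_links, inherits, logical(1), "lf_accession")),
            all(vapply(variants, inherits, logical(1), "lf_variant")),
            all(vapply(inflected_forms, inherits, logical(1), "lf_wordform")))
  vkey <- vapply(variants, function(v) paste(v$written_form, v$variant_type),
                 character(1))
  if (anyDuplicated(vkey)) stop("duplicate (written form, variant type) pair")
  akey <- vapply(accession_links,
                 function(a) paste(a$database_name, a$accession_id),
                 character(1))
  if (anyDuplicated(akey)) stop("duplicate accession link")
  if (!is.null(related_entries)) {
    stopifnot(is.data.frame(related_entries),
              all(c("entry_id", "relation") %in% names(related_entries)),
              all(related_entries$relation %in% lf_relations))
  }
  structure(list(entry_id = as.character(entry_id), lemma = lemma, pos = pos,
                 semantic_type = semantic_type,
                 accession_links = accession_links, variants = variants,
                 inflected_forms = inflected_forms,
                 related_entries = related_entries,
                 data_categories = data_categories, frequency = frequency),
            class = "lf_entry")
}

# deterministic id from (lemma, pos): hex of a small polynomial hash
derive_entry_id <- function(lemma, pos) {
  x <- utf8ToInt(paste(pos, lemma, sep = ":"))
  h <- 0
  for (c in x) h <- (h * 131 + c) %% 2^28
  sprintf("e%07x", h)
}

#' @export
print.lf_entry <- function(x, ...) {
  cat(sprintf("<%s> %s (%s)%s | %d variant(s), %d accession link(s)\n",
              x$entry_id, x$lemma, x$pos,
              if (is.null(x$semantic_type)) ""
              else paste0(" [", x$semantic_type, "]"),
              length(x$variants), length(x$accession_links)))
  invisible(x)
}

#' A lexicon: entries plus a derived form index
#'
#' @param entries list of [lexical_entry()] objects with unique ids; entries
#'   referenced by derivational relations must exist in the lexicon.
#' @return an object of class `lf_lexicon` with fields `entries` (named by
#'   entry_id) and `form_index` (written form -> entry ids, rebuildable).
#' @export
lexicon <- function(entries = list()) {
  stopifnot(all(vapply(entries, inherits, logical(1), "lf_entry")))
  ids <- vapply(entries, `[[`, character(1), "entry_id")
  if (anyDuplicated(ids)) {
    stop("duplicate entry id(s): ", paste(unique(ids[duplicated(ids)]),
                                          collapse = ", "))
  }
  names(entries) <- ids
  for (e in entries) {
    if (!is.null(e$related_entries)) {
      missing <- setdiff(e$related_entries$entry_id, ids)
      if (length(missing)) {
        stop("entry ", e$entry_id, " references unknown entries: ",
             paste(missing, collapse = ", "))
      }
    }
  }
  lex <- structure(list(entries = entries, form_index = NULL),
                   class = "lf_lexicon")
  lex$form_index <- build_form_index(lex)
  lex
}

#' Rebuild the written-form index of a lexicon
#'
#' Maps every written form (lemma and variant forms, NFC-normalized) to the
#' ids of the entries that carry it.
#'
#' @param lex an `lf_lexicon`.
#' @return named list: form -> character vector of entry ids.
#' @export
build_form_index <- function(lex) {
  forms <- lapply(lex$entries, function(e) {
    unique(c(e$lemma,
             vapply(e$variants, `[[`, character(1), "written_form")))
  })
  ids <- rep(names(forms), lengths(forms))
  all_forms <- unlist(forms, use.names = FALSE)
  lapply(split(ids, all_forms), function(x) sort(unique(x)))
}

#' @export
print.lf_lexicon <- function(x, ...) {
  pos <- table(vapply(x$entries, `[[`, character(1), "pos"))
  cat(sprintf("Lexicon: %d entries (%s); %d indexed forms\n",
              length(x$entries),
              paste(names(pos), pos, sep = " ", collapse = ", "),
              length(x$form_index)))
  invisible(x)
}

#' Look up a written form in a lexicon
#'
#' @param lex an `lf_lexicon`.
#' @param form written form.
#' @param case_fold fall back to case-insensitive comparison.
#' @return character vector of entry ids (possibly empty).
#' @export
lexicon_lookup <- function(lex, form, case_fold = FALSE) {
  form <- stringi::stri_trans_nfc(form)
  hit <- lex$form_index[[form]]
  if (!is.null(hit)) return(hit)
  if (case_fold) {
    lower <- stringi::stri_trans_tolower(form)
    keys <- stringi::stri_trans_tolower(names(lex$form_index))
    hit <- unique(unlist(lex$form_index[keys == lower], use.names = FALSE))
    if (length(hit)) return(sort(hit))
  }
  character(0)
}

#' Filter imported terms against a stop list
#'
#' Database labels such as "hypothetical protein" carry no information value
#' and are excluded before dictionary import.  Patterns are literal strings
#' or simple wildcards (`*` matches any substring), compared
#' case-insensitively against the whole term.
#'
#' @param terms a data.frame with columns `accession`, `term`, `source` (an
#'   `lf_dictionary` qualifies).
#' @param stoplist character vector of patterns; see
#'   [default_import_stoplist()].
#' @return list with `kept` and `rejected`, partitioning the rows in input
#'   order.
#' @export
filter_import_terms <- function(terms, stoplist = default_import_stoplist()) {
  stopifnot(is.data.frame(terms), all(c("accession", "term") %in% names(terms)))
  if (!length(stoplist)) {
    return(list(kept = terms, rejected = terms[0, , drop = FALSE]))
  }
  res <- utils::glob2rx(stoplist)
  hit <- Reduce(`|`, lapply(res, function(r) {
    grepl(r, terms$term, ignore.case = TRUE)
  }))
  list(kept = terms[!hit, , drop = FALSE],
       rejected = terms[hit, , drop = FALSE])
}

#' Default import stop list
#'
#' @return character vector of wildcard patterns for nonsense database
#'   labels.
#' @export
default_import_stoplist <- function() {
  c("hypothetical protein*", "uncharacterized protein*",
    "putative protein*", "unknown*", "unnamed protein product*",
    "predicted protein*")
}

# ---- XIF serialization -----------------------------------------------------

xif_bool <- function(x) if (isTRUE(x)) "true" else "false"

#' Save a lexicon in the XML interchange format (XIF)
#'
#' The XIF dialect is a flat XML schema (documented in the package vignette):
#' a `Lexicon` root containing `Entry` elements, each with a `Lemma`, and
#' optional `Variant`, `WordForm`, `AccessionLink`, `Related`, `DC` and
#' `Frequency` children.  Output is deterministic: entries are ordered by
#' entry id, children and attributes in fixed order, so two saves of the
#' same lexicon are byte-identical.
#'
#' @param lex an `lf_lexicon`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_xif <- function(lex, path) {
  stopifnot(inherits(lex, "lf_lexicon"))
  doc <- xml2::xml_new_root("Lexicon")
  for (id in sort(names(lex$entries))) {
    e <- lex$entries[[id]]
    node <- xml2::xml_add_child(doc, "Entry", id = e$entry_id, pos = e$pos)
    if (!is.null(e$semantic_type)) {
      xml2::xml_set_attr(node, "semanticType", e$semantic_type)
    }
    xml2::xml_add_child(node, "Lemma", writtenForm = e$lemma)
    for (v in e$variants) {
      xml2::xml_add_child(node, "Variant", writtenForm = v$written_form,
                          type = v$variant_type, source = v$source,
                          confidenceScore = format(v$confidence_score,
                                                   digits = 15))
    }
    for (w in e$inflected_forms) {
      wn <- xml2::xml_add_child(node, "WordForm",
                                writtenForm = w$written_form)
      for (f in names(w$features)) {
        xml2::xml_set_attr(wn, f, as.character(w$features[[f]]))
      }
    }
    for (a in e$accession_links) {
      xml2::xml_add_child(node, "AccessionLink", db = a$database_name,
                          id = a$accession_id, curated = xif_bool(a$curated))
    }
    if (!is.null(e$related_entries)) {
      re <- e$related_entries
      for (i in seq_len(nrow(re))) {
        xml2::xml_add_child(node, "Related", target = re$entry_id[i],
                            relation = re$relation[i])
      }
    }
    if (!is.null(e$data_categories)) {
      dc <- e$data_categories
      for (i in seq_len(nrow(dc))) {
        xml2::xml_add_child(node, "DC", att = dc$attribute[i],
                            val = as.character(dc$value[i]))
      }
    }
    if (!is.null(e$frequency)) {
      fr <- e$frequency
      for (i in seq_len(nrow(fr))) {
        xml2::xml_add_child(node, "Frequency", corpus = fr$corpus[i],
                            count = as.character(fr$count[i]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

xif_attr <- function(node, name, default = NULL) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

#' Load a lexicon from XIF
#'
#' Parses and validates the file; malformed XML is a parse error (with line
#' information from the XML parser), and schema violations (unknown part of
#' speech, missing or empty lemma, malformed children) raise a validation
#' error listing the offending entry ids.
#'
#' @param path XIF file path.
#' @return an `lf_lexicon` with the form index built.
#' @export
load_xif <- function(path) {
  doc <- xml2::read_xml(path)  # malformed XML errors here, naming the line
  if (xml2::xml_name(doc) != "Lexicon") {
    stop("not a XIF lexicon: root element is <", xml2::xml_name(doc), ">")
  }
  errors <- character(0)
  entries <- list()
  for (node in xml2::xml_find_all(doc, "./Entry")) {
    id <- xif_attr(node, "id", "<missing id>")
    e <- tryCatch(parse_xif_entry(node), error = function(e) {
      errors <<- c(errors, paste0(id, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(e)) entries[[length(entries) + 1L]] <- e
  }
  if (length(errors)) {
    stop("XIF validation failed for entry/entries:\n  ",
         paste(errors, collapse = "\n  "))
  }
  lexicon(entries)
}

parse_xif_entry <- function(node) {
  lemma_node <- xml2::xml_find_first(node, "./Lemma")
  if (inherits(lemma_node, "xml_missing")) stop("missing Lemma")
  lemma <- xif_attr(lemma_node, "writtenForm", "")
  pos <- xif_attr(node, "pos", "")
  if (!pos %in% lf_pos) stop("unknown pos '", pos, "'")
  variants <- lapply(xml2::xml_find_all(node, "./Variant"), function(v) {
    variant(xif_attr(v, "writtenForm", ""),
            xif_attr(v, "type", "orthographic"),
            xif_attr(v, "source", "db"),
            as.numeric(xif_attr(v, "confidenceScore", "1")))
  })
  wordforms <- lapply(xml2::xml_find_all(node, "./WordForm"), function(w) {
    attrs <- xml2::xml_attrs(w)
    feats <- as.list(attrs[setdiff(names(attrs), "writtenForm")])
    do.call(word_form, c(list(attrs[["writtenForm"]]), feats))
  })
  acc <- lapply(xml2::xml_find_all(node, "./AccessionLink"), function(a) {
    accession_link(xif_attr(a, "db", ""), xif_attr(a, "id", ""),
                   xif_attr(a, "curated", "false") == "true")
  })
  rel_nodes <- xml2::xml_find_all(node, "./Related")
  related <- if (length(rel_nodes)) {
    data.frame(
      entry_id = vapply(rel_nodes, xif_attr, character(1), name = "target"),
      relation = vapply(rel_nodes, xif_attr, character(1), name = "relation"),
      stringsAsFactors = FALSE)
  }
  dc_nodes <- xml2::xml_find_all(node, "./DC")
  dcs <- if (length(dc_nodes)) {
    data.frame(
      attribute = vapply(dc_nodes, xif_attr, character(1), name = "att"),
      value = vapply(dc_nodes, xif_attr, character(1), name = "val"),
      stringsAsFactors = FALSE)
  }
  fr_nodes <- xml2::xml_find_all(node, "./Frequency")
  freq <- if (length(fr_nodes)) {
    data.frame(
      corpus = vapply(fr_nodes, xif_attr, character(1), name = "corpus"),
      count = as.integer(vapply(fr_nodes, xif_attr, character(1),
                                name = "count")),
      stringsAsFactors = FALSE)
  }
  lexical_entry(lemma, pos, entry_id = xif_attr(node, "id"),
                semantic_type = xif_attr(node, "semanticType"),
                accession_links = acc, variants = variants,
                inflected_forms = wordforms, related_entries = related,
                data_categories = dcs, frequency = freq)
}

#' Atomic, staged load of a XIF file
#'
#' Mirrors a staged database load: phase 1 parses the file into a volatile
#' staging structure and validates every entry; phase 2 commits to a lexicon
#' only when validation passed in full.  A file with any invalid entry
#' commits nothing and returns the full error report.
#'
#' @param path XIF file path.
#' @return list with `lexicon` (an `lf_lexicon`, or `NULL` on failure),
#'   `committed` (logical) and `errors` (character vector).
#' @export
staged_load <- function(path) {
  res <- tryCatch(list(lexicon = load_xif(path), committed = TRUE,
                       errors = character(0)),
                  error = function(e) {
                    list(lexicon = NULL, committed = FALSE,
                         errors = conditionMessage(e))
                  })
  res
}
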