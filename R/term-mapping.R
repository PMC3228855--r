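#' Text-mined term candidates
#'
#' Candidates come from a named-entity recognizer run over the literature;
#' each carries the recognizer's probability, which distinguishes mined
#' variants from curated dictionary terms.
#'
#' @param surface_form character vector of surface forms.
#' @param ner_probability numeric vector in \[0, 1\].
#' @param doc_id,start,end optional provenance (document id and character
#'   span).
#' @return an object of class `lf_candidates` (a data.frame).
#' @export
candidate_terms <- function(surface_form, ner_probability,
                            doc_id = NA_character_, start = NA_integer_,
                            end = NA_integer_) {
  stopifnot(length(surface_form) == length(ner_probability),
            all(ner_probability >= 0 & ner_probability <= 1))
  df <- data.frame(
    surface_form = stringi::stri_trans_nfc(as.character(surface_form)),
    ner_probability = as.numeric(ner_probability),
    doc_id = doc_id, start = start, end = end,
    stringsAsFactors = FALSE
  )
  class(df) <- c("lf_candidates", "data.frame")
  df
}

#' Read candidate terms from TSV or JSONL
#'
#' TSV columns / JSONL keys: form (or surface_form), probability (or
#' ner_probability), doc_id, start, end.
#'
#' @param path file path; `.jsonl`/`.json` files are read as JSON lines.
#' @return an `lf_candidates` data.frame.
#' @export
read_candidates <- function(path) {
  if (grepl("\\.jsonl?$", path)) {
    rec <- jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    rec <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  }
  form <- if (!is.null(rec$form)) rec$form else rec$surface_form
  prob <- if (!is.null(rec$probability)) rec$probability else rec$ner_probability
  candidate_terms(form, prob,
                  doc_id = if (is.null(rec$doc_id)) NA_character_ else rec$doc_id,
                  start = if (is.null(rec$start)) NA_integer_ else rec$start,
                  end = if (is.null(rec$end)) NA_integer_ else rec$end)
}

#' Configuration for candidate filtering and mapping
#'
#' Defaults follow the acquisition pipeline's operating point: candidates are
#' kept only above recognizer probability 0.99 (strictly greater), mappings
#' hitting more than 10 accession numbers are discarded as too ambiguous, and
#' sub-clustering joins terms at string similarity 0.8 or above.
#'
#' @param ner_prob_min probability cut-off; selection is strict (`>`).
#' @param max_accessions maximum number of accessions a mapped term may hit.
#' @param similarity_threshold single-linkage threshold for sub-clustering.
#' @return an object of class `lf_mapping_config`.
#' @export
mapping_config <- function(ner_prob_min = 0.99, max_accessions = 10L,
                           similarity_threshold = 0.8) {
  stopifnot(ner_prob_min >= 0, ner_prob_min <= 1, max_accessions >= 1,
            similarity_threshold >= 0)
  structure(list(ner_prob_min = ner_prob_min,
                 max_accessions = as.integer(max_accessions),
                 similarity_threshold = similarity_threshold),
            class = "lf_mapping_config")
}

#' Filter candidates by recognizer probability
#'
#' Keeps candidates whose probability is strictly greater than
#' `cfg$ner_prob_min`; a candidate at exactly the cut-off is rejected.
#'
#' @param cands an [candidate_terms()] data.frame.
#' @param cfg an [mapping_config()].
#' @return list with elements `selected` and `rejected`, partitioning the
#'   input with order preserved.
#' @export
filter_candidates <- function(cands, cfg = mapping_config()) {
  stopifnot(inherits(cands, "lf_candidates"))
  keep <- cands$ner_probability > cfg$ner_prob_min
  list(selected = cands[keep, , drop = FALSE],
       rejected = cands[!keep, , drop = FALSE])
}

char_bigrams <- function(x) {
  n <- nchar(x)
  if (n < 2) return(x)
  substring(x, 1:(n - 1), 2:n)
}

#' Soft string similarity
#'
#' The mean of character-bigram Dice and whitespace-token Jaccard, computed
#' on NFC-normalized, case-folded strings.  It is symmetric and equals 1
#' exactly when the two strings are equal up to Unicode normalization and
#' case; case-folding is required for the measure to rank a cased variant of
#' a name above an unrelated long form.
#'
#' @param a,b character scalars.
#' @return similarity in \[0, 1\].
#' @examples
#' string_similarity("Dlg7", "Dlg7")   # 1
#' string_similarity("Hurp", "HURP")   # 1 (case variants)
#' @export
string_similarity <- function(a, b) {
  a <- stringi::stri_trans_tolower(stringi::stri_trans_nfc(a))
  b <- stringi::stri_trans_tolower(stringi::stri_trans_nfc(b))
  if (a == b) return(1)
  ba <- char_bigrams(a); bb <- char_bigrams(b)
  # multiset Dice on bigrams
  ta <- table(ba); tb <- table(bb)
  shared <- intersect(names(ta), names(tb))
  common <- sum(pmin(as.integer(ta[shared]), as.integer(tb[shared])))
  dice <- 2 * common / (length(ba) + length(bb))
  toka <- unique(strsplit(a, "\\s+")[[1]])
  tokb <- unique(strsplit(b, "\\s+")[[1]])
  jac <- length(intersect(toka, tokb)) / length(union(toka, tokb))
  (dice + jac) / 2
}

#' Sub-cluster an accession cluster by soft string matching
#'
#' Single-linkage connected components of the graph joining term pairs whose
#' [string_similarity()] is at least the configured threshold.  Gene/protein
#' clusters typically split into sub-clusters of orthographically related
#' forms (e.g. the long-name forms versus the short symbol forms of the same
#' accession).
#'
#' @param cluster character vector of terms (non-empty).
#' @param cfg an [mapping_config()].
#' @return list of character vectors partitioning `cluster`.
#' @export
subcluster_terms <- function(cluster, cfg = mapping_config()) {
  cluster <- unique(as.character(cluster))
  stopifnot(length(cluster) >= 1)
  n <- length(cluster)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (string_similarity(cluster[i], cluster[j]) >= cfg$similarity_threshold) {
        comp[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(cluster, roots))
}

#' Map a candidate term to accession numbers
#'
#' Normalizes the surface form with the index's rule set and looks it up in
#' the inverse index.  No hit gives status `unmapped`; more than
#' `cfg$max_accessions` hits gives `discarded_ambiguous`; a candidate that
#' fails the probability filter gives `rejected_low_prob`; otherwise the
#' candidate is `mapped`, its confidence score is the highest similarity
#' between the surface form and a dictionary term sharing its normalized
#' form, and `polysemy_flag` marks mappings to two or more accessions.
#'
#' @param cand a single-row [candidate_terms()] data.frame, or a character
#'   scalar (probability then taken as 1).
#' @param index an [build_inverse_index()] result.
#' @param rules the [ruleset()] the index was built with; a mismatch is an
#'   error.
#' @param dict the [clustered_dictionary()] behind the index (used for the
#'   confidence score; may be `NULL`, in which case confidence is `NA`).
#' @param cfg an [mapping_config()].
#' @return an object of class `lf_mapping` : list with `candidate`,
#'   `accessions`, `confidence_score`, `status`, `polysemy_flag`.
#' @export
map_term <- function(cand, index, rules, dict = NULL,
                     cfg = mapping_config()) {
  if (is.character(cand)) cand <- candidate_terms(cand, 1)
  stopifnot(inherits(cand, "lf_candidates"), nrow(cand) == 1,
            inherits(index, "lf_index"), inherits(rules, "lf_ruleset"))
  if (!identical(index$ruleset_sig, ruleset_signature(rules))) {
    stop("index was built with a different rule set")
  }
  res <- list(candidate = cand, accessions = character(0),
              confidence_score = NA_real_, status = "unmapped",
              polysemy_flag = FALSE)
  if (cand$ner_probability <= cfg$ner_prob_min) {
    res$status <- "rejected_low_prob"
    return(structure(res, class = "lf_mapping"))
  }
  form <- normalize_terms(cand$surface_form, rules)
  acc <- index_lookup(index, form)
  if (length(acc) == 0) {
    res$status <- "unmapped"
  } else if (length(acc) > cfg$max_accessions) {
    res$status <- "discarded_ambiguous"
    res$accessions <- acc
  } else {
    res$status <- "mapped"
    res$accessions <- acc
    res$polysemy_flag <- length(acc) >= 2
    if (!is.null(dict)) {
      hit <- dict[dict$accession %in% acc &
                    normalize_terms(dict$term, rules) == form, "term"]
      if (length(hit)) {
        res$confidence_score <- max(vapply(unique(hit), string_similarity,
                                           numeric(1), b = cand$surface_form))
      }
    }
  }
  structure(res, class = "lf_mapping")
}

#' @export
print.lf_mapping <- function(x, ...) {
  cat(sprintf("'%s' -> %s [%s]%s\n", x$candidate$surface_form,
              if (length(x$accessions)) paste(x$accessions, collapse = ",")
              else "-",
              x$status, if (x$polysemy_flag) " (polysemous)" else ""))
  invisible(x)
}

#' Map a batch of candidates
#'
#' Applies [map_term()] to every row; every candidate ends in exactly one
#' status, so status counts partition the input.
#'
#' @inheritParams map_term
#' @param cands an [candidate_terms()] data.frame.
#' @return a data.frame with columns `surface_form`, `ner_probability`,
#'   `status`, `accessions` (comma-separated), `n_accessions`,
#'   `confidence_score`, `polysemy_flag`.
#' @export
map_terms <- function(cands, index, rules, dict = NULL,
                      cfg = mapping_config()) {
  stopifnot(inherits(cands, "lf_candidates"))
  rows <- lapply(seq_len(nrow(cands)), function(i) {
    m <- map_term(cands[i, , drop = FALSE], index, rules, dict, cfg)
    data.frame(surface_form = cands$surface_form[i],
               ner_probability = cands$ner_probability[i],
               status = m$status,
               accessions = paste(m$accessions, collapse = ","),
               n_accessions = length(m$accessions),
               confidence_score = m$confidence_score,
               polysemy_flag = m$polysemy_flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
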