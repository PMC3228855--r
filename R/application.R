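#' Dictionary-based tagging of a token sequence
#'
#' Greedy leftmost-longest matching of token n-grams against the lexicon's
#' form index: at each position the longest matching form (case-sensitive
#' first, case-folded as fallback) is tagged `NN-BIOMED` and treated as a
#' single unit, so a multi-word protein name like "met protooncogene
#' precursor" is not broken up by a general-language tagger.  Tagged spans
#' never overlap; unmatched tokens pass through with tag `TOK`.
#'
#' @param tokens character vector of tokens (non-empty).
#' @param lex an [lexicon()].
#' @param max_len maximum n-gram length tried; defaults to the longest form
#'   in the lexicon.
#' @return a data.frame with columns `start`, `end` (token indices,
#'   inclusive), `surface`, `tag`, `entry_id` (`NA` for pass-through
#'   tokens).
#' @export
dictionary_tag <- function(tokens, lex, max_len = NULL) {
  stopifnot(length(tokens) > 0, inherits(lex, "lf_lexicon"))
  forms <- names(lex$form_index)
  if (is.null(max_len)) {
    max_len <- if (length(forms)) {
      max(lengths(strsplit(forms, "\\s+")))
    } else 1L
  }
  lower_index <- stats::setNames(names(lex$form_index),
                                 stringi::stri_trans_tolower(forms))
  out <- list()
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    hit_len <- 0L
    hit_id <- NA_character_
    for (len in rev(seq_len(min(max_len, n - i + 1L)))) {
      cand <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      cand <- stringi::stri_trans_nfc(cand)
      ids <- lex$form_index[[cand]]
      if (is.null(ids)) {
        key <- unname(lower_index[stringi::stri_trans_tolower(cand)])
        if (length(key) == 1 && !is.na(key)) ids <- lex$form_index[[key]]
      }
      if (!is.null(ids)) {
        hit_len <- len
        hit_id <- ids[1]
        break
      }
    }
    if (hit_len > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        start = i, end = i + hit_len - 1L,
        surface = paste(tokens[i:(i + hit_len - 1L)], collapse = " "),
        tag = "NN-BIOMED", entry_id = hit_id, stringsAsFactors = FALSE)
      i <- i + hit_len
    } else {
      out[[length(out) + 1L]] <- data.frame(
        start = i, end = i, surface = tokens[i], tag = "TOK",
        entry_id = NA_character_, stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  do.call(rbind, out)
}

#' Frame-filtered fact extraction from a parsed, NE-annotated corpus
#'
#' Three successive filters turn verb instances into facts: (1) the verb
#' must be a verb entry of the lexicon (lexicon verbs are the potential
#' textual anchors of biomedical events); (2) at least one argument filler
#' must carry an NE annotation (an event needs a biologically relevant
#' participant); (3) the instance's canonical slot pattern must match a
#' stored grammatical frame of the verb, where a frame matches when its
#' slots are a subset of the instance's slots -- extra adjuncts never block
#' extraction, missing frame slots do.  Survivors become facts; when several
#' frames subsume the instance, the most specific (largest) frame wins, ties
#' broken by higher frame probability.  Semantic roles are assigned to
#' arguments through the chosen frame's argument-level link, which is how a
#' prepositional argument (e.g. the for-phrase of "codes for") receives the
#' THEME role even though it is not a grammatical object.
#'
#' @param instances list of [parsed_instance()] objects with NE annotations
#'   in their slots.
#' @param lex an [lexicon()]; its verb entries define filter 1.
#' @param frames an [estimate_frames()] data.frame for the lexicon's verbs.
#' @param links optional list of `lf_framelink` objects (from
#'   [link_frames()] / [link_all()]); used for role assignment.
#' @param aux_stoplist auxiliary verbs excluded from the lexical-verb
#'   denominator of the report.
#' @return list with `facts` (list of `lf_fact`) and `report` (class
#'   `lf_filter_report`), whose counts partition the lexicon-verb instances:
#'   `verbs_in_lexicon = facts_extracted + frame_mismatch + absence_of_ne`.
#' @export
extract_facts <- function(instances, lex, frames, links = NULL,
                          aux_stoplist = c("be", "have", "do", "will",
                                           "would", "can", "could", "may",
                                           "might", "shall", "should",
                                           "must")) {
  stopifnot(inherits(lex, "lf_lexicon"), inherits(frames, "data.frame"))
  verb_entries <- Filter(function(e) e$pos == "verb", lex$entries)
  verb_lemmas <- vapply(verb_entries, `[[`, character(1), "lemma")
  link_by_key <- list()
  for (lk in links) {
    key <- paste(lk$verb, lk$syn_pattern, sep = "\x1f")
    if (is.null(link_by_key[[key]])) link_by_key[[key]] <- lk
  }
  facts <- list()
  n_lexical <- 0L
  n_in_lex <- 0L
  n_no_ne <- 0L
  n_mismatch <- 0L
  n_prep <- 0L
  for (ins in instances) {
    if (ins$verb_lemma %in% aux_stoplist) next
    n_lexical <- n_lexical + 1L
    if (!ins$verb_lemma %in% verb_lemmas) next        # filter 1
    n_in_lex <- n_in_lex + 1L
    if (all(is.na(ins$slots$ne_type))) {              # filter 2
      n_no_ne <- n_no_ne + 1L
      next
    }
    vframes <- frames[frames$verb == ins$verb_lemma, , drop = FALSE]
    ins_slots <- ins$slots$label
    subsumes <- vapply(vframes$pattern, function(p) {
      fslots <- strsplit(p, "#", fixed = TRUE)[[1]]
      all(fslots %in% ins_slots)
    }, logical(1))
    if (!any(subsumes)) {                             # filter 3
      n_mismatch <- n_mismatch + 1L
      next
    }
    vframes <- vframes[subsumes, , drop = FALSE]
    size <- vapply(strsplit(vframes$pattern, "#", fixed = TRUE), length,
                   integer(1))
    vframes <- vframes[order(-size, -vframes$probability), , drop = FALSE]
    chosen <- vframes[1, , drop = FALSE]
    lk <- link_by_key[[paste(ins$verb_lemma, chosen$pattern, sep = "\x1f")]]
    args <- ins$slots
    args$role <- NA_character_
    if (!is.null(lk)) {
      m <- lk$links[lk$links$role != "0" & lk$links$slot != "0", ,
                    drop = FALSE]
      args$role <- m$role[match(args$label, m$slot)]
    }
    if (any(startsWith(args$label, "PP-"))) n_prep <- n_prep + 1L
    facts[[length(facts) + 1L]] <- structure(
      list(verb_lemma = ins$verb_lemma, sentence_id = ins$sentence_id,
           arguments = args, frame = chosen$pattern,
           link = if (is.null(lk)) NULL else format(lk)),
      class = "lf_fact")
  }
  report <- structure(list(
    total_lexical_verbs = n_lexical,
    verbs_in_lexicon = n_in_lex,
    facts_extracted = length(facts),
    frame_mismatch = n_mismatch,
    absence_of_ne = n_no_ne,
    facts_with_prep_args = n_prep
  ), class = "lf_filter_report")
  list(facts = facts, report = report)
}

#' @export
print.lf_fact <- function(x, ...) {
  args <- x$arguments
  lab <- ifelse(is.na(args$role), args$label,
                paste0(args$label, "/", args$role))
  cat(sprintf("%s(%s) [frame %s]\n", x$verb_lemma,
              paste(lab, collapse = ", "), x$frame))
  invisible(x)
}

#' @export
print.lf_filter_report <- function(x, ...) {
  pct <- function(a, b) if (b > 0) sprintf(" (%.1f%%)", 100 * a / b) else ""
  cat("Fact extraction report\n")
  cat(sprintf("  lexical verb instances : %d\n", x$total_lexical_verbs))
  cat(sprintf("  verbs in lexicon       : %d%s\n", x$verbs_in_lexicon,
              pct(x$verbs_in_lexicon, x$total_lexical_verbs)))
  cat(sprintf("  facts extracted        : %d%s\n", x$facts_extracted,
              pct(x$facts_extracted, x$verbs_in_lexicon)))
  cat(sprintf("  frame mismatch         : %d%s\n", x$frame_mismatch,
              pct(x$frame_mismatch, x$verbs_in_lexicon)))
  cat(sprintf("  no NE among arguments  : %d%s\n", x$absence_of_ne,
              pct(x$absence_of_ne, x$verbs_in_lexicon)))
  cat(sprintf("  facts with prep. args  : %d%s\n", x$facts_with_prep_args,
              pct(x$facts_with_prep_args, x$facts_extracted)))
  invisible(x)
}

#' Write a fact list as JSONL
#'
#' One object per fact: verb, sentence_id, frame, args (slot, role, text,
#' ne_type).
#'
#' @param facts list of `lf_fact` objects.
#' @param path file path.
#' @export
write_facts <- function(facts, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (f in facts) {
    rec <- list(verb = f$verb_lemma, sentence_id = f$sentence_id,
                frame = f$frame,
                args = f$arguments[, c("label", "role", "text", "ne_type")])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

#' Write a filter report as TSV
#'
#' One row with the six counts and the derived fractions.
#'
#' @param report an `lf_filter_report`.
#' @param path file path.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(
    total_lexical_verbs = report$total_lexical_verbs,
    verbs_in_lexicon = report$verbs_in_lexicon,
    facts_extracted = report$facts_extracted,
    frame_mismatch = report$frame_mismatch,
    absence_of_ne = report$absence_of_ne,
    facts_with_prep_args = report$facts_with_prep_args,
    pct_in_lexicon = 100 * report$verbs_in_lexicon /
      max(1L, report$total_lexical_verbs),
    pct_facts = 100 * report$facts_extracted /
      max(1L, report$verbs_in_lexicon),
    pct_no_ne = 100 * report$absence_of_ne /
      max(1L, report$verbs_in_lexicon)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
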