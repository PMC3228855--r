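#' Predicate-argument instances of verbs
#'
#' One record per verb occurrence, as produced by a deep parser.  Slot labels
#' are logical (passive-normalized): `ARG1` is the logical subject and `ARG2`
#' the logical object, so active and passive realizations of the same event
#' share a pattern.  Recognized labels: `ARG1`, `ARG2`, `ARG3`, `THAT-CL`,
#' `TO-INF`, `ADV`, and `PP-<preposition>` for prepositional arguments.
#'
#' @param verb_lemma verb lemma.
#' @param voice `"active"` or `"passive"`.
#' @param slots a character vector of slot labels, or a data.frame with
#'   columns `label`, and optionally `category` (NP / clause / adverb) and
#'   `ne_type`.
#' @param sentence_id provenance.
#' @param text optional per-slot argument text (parallel to `slots`).
#' @return an object of class `lf_instance`.
#' @export
parsed_instance <- function(verb_lemma, voice = c("active", "passive"),
                            slots = character(0), sentence_id = NA_character_,
                            text = NULL) {
  voice <- match.arg(voice)
  if (is.character(slots)) {
    slots <- data.frame(label = slots, category = NA_character_,
                        ne_type = NA_character_, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(slots))
  if (is.null(slots$category)) slots$category <- NA_character_
  if (is.null(slots$ne_type)) slots$ne_type <- NA_character_
  if (!is.null(text)) slots$text <- text
  if (is.null(slots$text)) slots$text <- NA_character_
  check_slot_labels(slots$label)
  if (sum(slots$label == "ARG1") > 1 || sum(slots$label == "ARG2") > 1) {
    stop("at most one ARG1 and one ARG2 per instance")
  }
  structure(list(verb_lemma = as.character(verb_lemma), voice = voice,
                 slots = slots, sentence_id = as.character(sentence_id)),
            class = "lf_instance")
}

check_slot_labels <- function(labels) {
  ok <- labels %in% c("ARG1", "ARG2", "ARG3", "THAT-CL", "TO-INF", "ADV") |
    grepl("^PP-[a-z]+$", labels)
  if (any(!ok)) {
    stop("unknown slot label(s): ", paste(unique(labels[!ok]), collapse = ", "))
  }
  invisible(labels)
}

#' Read a parsed corpus from JSONL
#'
#' One JSON object per line:
#' `{"verb": ..., "sentence_id": ..., "voice": ..., "slots":
#'  [{"label": ..., "category": ..., "ne_type": ..., "text": ...}, ...]}`.
#'
#' @param path file path.
#' @return list of [parsed_instance()] objects.
#' @export
read_parsed_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyDataFrame = TRUE)
    slots <- rec$slots
    if (is.null(slots) || (is.data.frame(slots) && !nrow(slots))) {
      slots <- character(0)
    }
    parsed_instance(rec$verb, rec$voice, slots,
                    sentence_id = rec$sentence_id %||% NA_character_)
  })
}

#' Write a parsed corpus as JSONL
#'
#' @param instances list of [parsed_instance()] objects.
#' @param path file path.
#' @export
write_parsed_corpus <- function(instances, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (ins in instances) {
    rec <- list(verb = ins$verb_lemma, sentence_id = ins$sentence_id,
                voice = ins$voice, slots = ins$slots)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

slot_sort_key <- function(labels) {
  core <- c(ARG1 = 1, ARG2 = 2, ARG3 = 3, `THAT-CL` = 4, `TO-INF` = 5)
  vapply(labels, function(l) {
    if (l %in% names(core)) sprintf("0%d", core[[l]])
    else if (startsWith(l, "PP-")) paste0("1", substring(l, 4))
    else "2"  # ADV last
  }, character(1))
}

#' Canonicalize a slot set into a frame pattern
#'
#' Grammatical frames abstract over surface argument order, which varies with
#' voice and adjunct placement.  The canonical order is: core arguments ARG1,
#' ARG2, ARG3 (those present), then THAT-CL and TO-INF, then prepositional
#' slots sorted alphabetically by preposition, then ADV.  Repeated slots with
#' the same preposition are collapsed to one occurrence (multiplicity is
#' recorded in the `multiplicity` attribute).  The serialized pattern joins
#' slots with `"#"`, e.g. `"ARG1#ARG2#PP-in"`.
#'
#' @param x an [parsed_instance()] or a character vector of slot labels.
#' @return the serialized canonical pattern (character scalar) with attribute
#'   `multiplicity` (named integer vector over collapsed slots).
#' @examples
#' canonicalize_pattern(c("PP-in", "ARG2", "ARG1"))  # "ARG1#ARG2#PP-in"
#' @export
canonicalize_pattern <- function(x) {
  labels <- if (inherits(x, "lf_instance")) x$slots$label else as.character(x)
  check_slot_labels(labels)
  mult <- table(labels)
  labels <- names(mult)
  ord <- order(slot_sort_key(labels))
  labels <- labels[ord]
  structure(paste(labels, collapse = "#"),
            multiplicity = stats::setNames(as.integer(mult[labels]), labels))
}

#' Induction configuration for grammatical frames
#'
#' @param prob_threshold minimum conditional probability `P(pattern | verb)`
#'   for a pattern to be retained as a frame; the comparison is inclusive
#'   (a pattern at exactly the threshold is kept).  Default 0.03, the
#'   operating point that discards noisy patterns from parser error while
#'   keeping genuine low-frequency subcategorization.
#' @param min_support minimum observation count for a retained frame
#'   (default 1; a guard for very small corpora).
#' @param verb_list optional character vector restricting induction to these
#'   lemmas.
#' @return an object of class `lf_induction_config`.
#' @export
induction_config <- function(prob_threshold = 0.03, min_support = 1L,
                             verb_list = NULL) {
  stopifnot(prob_threshold > 0, prob_threshold <= 1, min_support >= 1)
  structure(list(prob_threshold = prob_threshold,
                 min_support = as.integer(min_support),
                 verb_list = verb_list),
            class = "lf_induction_config")
}

#' Estimate grammatical frames from a parsed corpus
#'
#' For each verb, counts canonical patterns and estimates the conditional
#' probability of each pattern given the verb.  Patterns with probability at
#' or above the threshold (and support at or above `min_support`) are
#' retained as frames; each frame records its support, per-frame passive
#' percentage, and the verb's overall passive percentage.  Probabilities
#' reported are pre-filter, so for any verb they sum to 1 over all observed
#' patterns.
#'
#' @param instances list of [parsed_instance()] objects.
#' @param cfg an [induction_config()].
#' @return an object of class `lf_frames`: a data.frame with columns `verb`,
#'   `pattern`, `probability`, `passive_pct`, `support`,
#'   `verb_passive_pct`, plus attribute `all_patterns` holding the unfiltered
#'   table.
#' @export
estimate_frames <- function(instances, cfg = induction_config()) {
  stopifnot(length(instances) > 0)
  df <- data.frame(
    verb = vapply(instances, `[[`, character(1), "verb_lemma"),
    pattern = vapply(instances, function(i) canonicalize_pattern(i),
                     character(1)),
    passive = vapply(instances, function(i) i$voice == "passive", logical(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(cfg$verb_list)) df <- df[df$verb %in% cfg$verb_list, ]
  if (!nrow(df)) stop("no instances for the requested verbs")
  agg <- stats::aggregate(cbind(support = passive) ~ verb + pattern, df, length)
  pas <- stats::aggregate(passive ~ verb + pattern, df, function(p) 100 * mean(p))
  agg$passive_pct <- pas$passive[match(paste(agg$verb, agg$pattern),
                                       paste(pas$verb, pas$pattern))]
  verb_n <- table(df$verb)
  verb_pas <- tapply(df$passive, df$verb, function(p) 100 * mean(p))
  agg$probability <- agg$support / as.integer(verb_n[agg$verb])
  agg$verb_passive_pct <- as.numeric(verb_pas[agg$verb])
  agg <- agg[order(agg$verb, -agg$probability, agg$pattern), ]
  keep <- agg$probability >= cfg$prob_threshold & agg$support >= cfg$min_support
  out <- agg[keep, c("verb", "pattern", "probability", "passive_pct",
                     "support", "verb_passive_pct")]
  rownames(out) <- NULL
  attr(out, "all_patterns") <- agg
  class(out) <- c("lf_frames", "data.frame")
  out
}

#' Passive-voice rate of a verb
#'
#' @param instances list of [parsed_instance()] objects.
#' @param verb verb lemma; must have at least one instance.
#' @return percentage in \[0, 100\] of instances in the passive voice.
#' @export
passive_rate <- function(instances, verb) {
  voice <- vapply(instances, function(i) {
    if (i$verb_lemma == verb) i$voice else NA_character_
  }, character(1))
  voice <- voice[!is.na(voice)]
  if (!length(voice)) stop("no instances of verb '", verb, "'")
  100 * mean(voice == "passive")
}

#' Log-likelihood association between a verb and a slot
#'
#' The likelihood-ratio statistic G2 = 2 * sum(O * ln(O / E)) over the 2x2
#' contingency table crossing instances of the verb against instances of all
#' other verbs, by presence of the slot.  Expected counts come from the
#' table margins under independence; zero observed cells contribute 0.  The
#' statistic quantifies how strongly a grammatical argument is associated
#' with the verb, complementing the conditional pattern probabilities.
#'
#' @param instances list of [parsed_instance()] objects covering at least two
#'   distinct verbs.
#' @param verb verb lemma.
#' @param slot slot label (e.g. `"ARG2"`, `"PP-in"`).
#' @return an object of class `lf_slot_assoc`: list with `verb_lemma`,
#'   `slot_label`, `ll` and the 2x2 `counts` matrix.  When a margin is
#'   degenerate (the slot occurs in all instances or none, or only one verb
#'   is present in the margin) `ll` is 0 with a warning.
#' @export
slot_loglik <- function(instances, verb, slot) {
  verbs <- vapply(instances, `[[`, character(1), "verb_lemma")
  if (length(unique(verbs)) < 2) {
    stop("corpus must contain at least two distinct verbs")
  }
  has_slot <- vapply(instances, function(i) slot %in% i$slots$label, logical(1))
  is_verb <- verbs == verb
  counts <- matrix(c(sum(is_verb & has_slot), sum(is_verb & !has_slot),
                     sum(!is_verb & has_slot), sum(!is_verb & !has_slot)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c(verb, "other"),
                                   c("slot", "no_slot")))
  ll <- g2_statistic(counts)
  if (is.na(ll)) {
    warning("degenerate margins for slot '", slot, "'; ll set to 0")
    ll <- 0
  }
  structure(list(verb_lemma = verb, slot_label = slot, ll = ll,
                 counts = counts), class = "lf_slot_assoc")
}

# G2 over a 2x2 table; NA when a margin is zero (degenerate)
g2_statistic <- function(counts) {
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) return(NA_real_)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  terms <- counts * log(counts / expected)
  terms[counts == 0] <- 0
  2 * sum(terms)
}

#' @export
print.lf_slot_assoc <- function(x, ...) {
  cat(sprintf("%s ~ %s : ll = %.3f\n", x$verb_lemma, x$slot_label, x$ll))
  invisible(x)
}

#' Write grammatical frames as TSV
#'
#' Columns: verb, pattern, probability, passive_pct, support,
#' verb_passive_pct; patterns use the `#`-joined notation.
#'
#' @param frames an [estimate_frames()] result.
#' @param path file path.
#' @export
write_frames <- function(frames, path) {
  utils::write.table(as.data.frame(frames), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
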