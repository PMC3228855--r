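# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Specification for the synthetic-data generators
#'
#' Every input the toolkit consumes can be generated synthetically, with
#' planted ground truth, as a pure function of this specification and its
#' seed.  The defaults describe a desk-scale study: a dictionary of 50
#' concepts with 3 written variants each produced by realistic variant
#' processes (case change, hyphen toggling, Anglo-American spelling), and a
#' parsed corpus over a handful of biologically typical verbs with planted
#' pattern distributions, passive rates and named-entity fillers.
#'
#' @param seed integer RNG seed.
#' @param n_concepts number of accession clusters in the dictionary.
#' @param variants_per_concept written forms per concept (including the base
#'   name).
#' @param processes named probability weights over the variant processes
#'   `case_change`, `hyphen_toggle`, `spelling_swap`, `whitespace_jitter`,
#'   `acronym`, `token_permutation`.  Acronym and token permutation are not
#'   recoverable by string rewrites and are flagged as such in the ground
#'   truth.
#' @param ambiguity_injection_rate fraction of concepts that additionally
#'   receive another concept's base name as a variant (planted ambiguity).
#' @param verbs list of per-verb specifications, see [default_verb_specs()];
#'   each has `patterns` (named probabilities summing to 1), `passive`
#'   (passive-voice probability), `ne` (named list slot -> NE class) and
#'   `roles` (named character vector role -> NE class for event generation).
#' @param n_instances_per_verb parsed instances per verb.
#' @param ne_rate probability that an eligible slot carries its NE
#'   annotation.
#' @param n_events_per_verb annotated events per verb.
#' @param distractors list with rates for fact-extraction distractors:
#'   `nonlex_rate` (instances of out-of-lexicon verbs), `ne_free_rate`
#'   (instances stripped of NEs), `offframe_rate` (instances with a pattern
#'   missing the frames' core slots).
#' @return an object of class `lf_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_concepts = 50L,
                         variants_per_concept = 3L,
                         processes = c(case_change = 0.4,
                                       hyphen_toggle = 0.3,
                                       spelling_swap = 0.3),
                         ambiguity_injection_rate = 0,
                         verbs = default_verb_specs(),
                         n_instances_per_verb = 500L,
                         ne_rate = 1,
                         n_events_per_verb = 30L,
                         distractors = list(nonlex_rate = 0,
                                            ne_free_rate = 0,
                                            offframe_rate = 0)) {
  all_proc <- c("case_change", "hyphen_toggle", "spelling_swap",
                "whitespace_jitter", "acronym", "token_permutation")
  stopifnot(all(names(processes) %in% all_proc), all(processes >= 0),
            sum(processes) > 0,
            ambiguity_injection_rate >= 0, ambiguity_injection_rate <= 1,
            ne_rate >= 0, ne_rate <= 1)
  for (v in verbs) {
    stopifnot(abs(sum(v$patterns) - 1) < 1e-9, all(v$patterns >= 0),
              v$passive >= 0, v$passive <= 1)
  }
  structure(list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
                 variants_per_concept = as.integer(variants_per_concept),
                 processes = processes / sum(processes),
                 ambiguity_injection_rate = ambiguity_injection_rate,
                 verbs = verbs,
                 n_instances_per_verb = as.integer(n_instances_per_verb),
                 ne_rate = ne_rate,
                 n_events_per_verb = as.integer(n_events_per_verb),
                 distractors = distractors),
            class = "lf_fixture_spec")
}

#' Default per-verb fixture specifications
#'
#' Four gene-regulation verbs with typical subcategorization distributions,
#' passive rates and NE fillers, plus the role patterns used for paired
#' event generation (fillers compatible with the prototypic realizations, so
#' frame linking is exercised end to end).
#'
#' @return named list of per-verb specifications.
#' @export
default_verb_specs <- function() {
  list(
    activate = list(
      patterns = c("ARG1#ARG2" = 0.7, "ARG1#ARG2#PP-in" = 0.25,
                   "ARG1" = 0.05),
      passive = 0.3,
      ne = list(ARG1 = "PROTEIN", ARG2 = "DNA"),
      roles = c(AGENT = "PROTEIN", THEME = "DNA")
    ),
    transcribe = list(
      patterns = c("ARG1#ARG2" = 0.6, "ARG1#ARG2#PP-from" = 0.3,
                   "ARG1#ARG2#PP-as" = 0.1),
      passive = 0.55,
      ne = list(ARG1 = "PROTEIN", ARG2 = "DNA"),
      roles = c(AGENT = "PROTEIN", THEME = "DNA", SOURCE = "DNA")
    ),
    bind = list(
      patterns = c("ARG1#ARG2" = 0.5, "ARG1#PP-to" = 0.45, "ARG1" = 0.05),
      passive = 0.2,
      ne = list(ARG1 = "PROTEIN", ARG2 = "PROTEIN", `PP-to` = "DNA"),
      roles = c(AGENT = "PROTEIN", THEME = "PROTEIN")
    ),
    clone = list(
      patterns = c("ARG1#ARG2#PP-into" = 0.6, "ARG1#ARG2" = 0.4),
      passive = 0.8,
      ne = list(ARG2 = "DNA", `PP-into` = "EXPERIMENTAL"),
      roles = c(THEME = "DNA", DESTINATION = "EXPERIMENTAL")
    )
  )
}

# gene-symbol-like stems and multiword headwords; some carry Anglo-American
# spelling material so spelling_swap has something to act on
lf_stems <- c("dna", "rpo", "cys", "fis", "omp", "lac", "rec", "gyr", "mar",
              "sox", "crp", "fnr", "lex", "pho", "ara", "trp", "gal", "mal",
              "uvr", "pyr", "nar", "fur", "arc", "him", "tor", "cad", "env",
              "tol", "mot", "che")
lf_heads <- c("protein", "factor", "regulator", "tumour antigen",
              "polymerase", "repressor", "activator", "kinase",
              "synthetase", "transport protein")
lf_greek <- c("alpha", "beta", "gamma", "delta", "")

gen_base_name <- function() {
  stem <- sample(lf_stems, 1)
  suff <- sample(LETTERS, 1)
  num <- sample(1:99, 1)
  greek <- sample(lf_greek, 1)
  head <- sample(lf_heads, 1)
  sym <- paste0(stem, suff, "-", num)
  if (nzchar(greek)) paste(sym, greek, head) else paste(sym, head)
}

# skeleton used to guarantee concepts stay distinguishable after
# normalization: lower case, no dashes/spaces, American spelling
name_skeleton <- function(x) {
  x <- tolower(x)
  x <- gsub("our", "or", x, fixed = TRUE)
  x <- gsub("ise", "ize", x, fixed = TRUE)
  gsub("[-\\s]", "", x, perl = TRUE)
}

apply_process <- function(term, process) {
  switch(process,
    case_change = {
      v <- c(toupper(term),
             stringi::stri_trans_totitle(term),
             tolower(term))
      v <- v[v != term]
      if (length(v)) sample(v, 1) else NA_character_
    },
    hyphen_toggle = {
      if (grepl("-", term, fixed = TRUE)) {
        sub("-", "", term, fixed = TRUE)
      } else NA_character_
    },
    spelling_swap = {
      if (grepl("our", term, fixed = TRUE)) {
        sub("our", "or", term, fixed = TRUE)
      } else if (grepl("ise", term, fixed = TRUE)) {
        sub("ise", "ize", term, fixed = TRUE)
      } else if (grepl("or", term, fixed = TRUE)) {
        sub("or", "our", term, fixed = TRUE)
      } else NA_character_
    },
    whitespace_jitter = {
      if (grepl(" ", term, fixed = TRUE)) {
        sub(" ", "  ", term, fixed = TRUE)
      } else NA_character_
    },
    acronym = {
      tok <- strsplit(term, "[\\s-]+", perl = TRUE)[[1]]
      if (length(tok) >= 2) {
        paste(toupper(substr(tok, 1, 1)), collapse = "")
      } else NA_character_
    },
    token_permutation = {
      tok <- strsplit(term, " ", fixed = TRUE)[[1]]
      if (length(tok) >= 2) {
        paste(rev(tok), collapse = " ")
      } else NA_character_
    }
  )
}

recoverable_processes <- c("case_change", "hyphen_toggle", "spelling_swap",
                           "whitespace_jitter")

#' Generate a clustered dictionary with planted variant processes
#'
#' Concepts receive synthetic gene/protein-style base names (symbol stems
#' with digits, Greek letters, hyphens, multiword heads) guaranteed to stay
#' distinguishable after full normalization; additional variants are
#' produced by the spec's variant processes.  With a positive ambiguity
#' injection rate, some concepts also receive another concept's base name,
#' planting genuine cross-cluster ambiguity.
#'
#' @param spec an [fixture_spec()].
#' @return list with `dictionary` (an [clustered_dictionary()]) and `truth`
#'   (data.frame accession / term / base / process / recoverable).
#' @export
gen_dictionary <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "lf_fixture_spec"))
  with_seed(spec$seed, {
    bases <- character(0)
    skels <- character(0)
    while (length(bases) < spec$n_concepts) {
      b <- gen_base_name()
      s <- name_skeleton(b)
      if (!s %in% skels) {
        bases <- c(bases, b)
        skels <- c(skels, s)
      }
    }
    acc <- sprintf("ACC%04d", seq_len(spec$n_concepts))
    rows <- list()
    for (i in seq_len(spec$n_concepts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc[i], term = bases[i], base = bases[i],
        process = "base", recoverable = TRUE, stringsAsFactors = FALSE)
      made <- bases[i]
      tries <- 0L
      while (length(made) < spec$variants_per_concept && tries < 50L) {
        tries <- tries + 1L
        p <- sample(names(spec$processes), 1, prob = spec$processes)
        v <- apply_process(bases[i], p)
        if (is.na(v) || v %in% made) next
        made <- c(made, v)
        rows[[length(rows) + 1L]] <- data.frame(
          accession = acc[i], term = v, base = bases[i], process = p,
          recoverable = p %in% recoverable_processes,
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, rows)
    # planted ambiguity: share another concept's base name
    n_amb <- round(spec$ambiguity_injection_rate * spec$n_concepts)
    if (n_amb > 0 && spec$n_concepts >= 2) {
      pick <- sample(spec$n_concepts, n_amb)
      for (i in pick) {
        j <- sample(setdiff(seq_len(spec$n_concepts), i), 1)
        truth <- rbind(truth, data.frame(
          accession = acc[i], term = bases[j], base = bases[j],
          process = "ambiguity_injection", recoverable = TRUE,
          stringsAsFactors = FALSE))
      }
    }
    dict <- clustered_dictionary(truth[, c("accession", "term")],
                                 source = "synthetic")
    list(dictionary = dict, truth = truth)
  })
}

#' Generate a parsed corpus with planted frame distributions
#'
#' Instances are drawn per verb from the spec's pattern distribution and
#' passive rate; slot NE annotations follow the per-verb filler map at the
#' spec's NE rate.  Distractor instances for fact-extraction tests (unknown
#' verbs, NE-free instances, off-frame patterns) are appended at the spec's
#' distractor rates and labelled in the ground truth.
#'
#' @param spec an [fixture_spec()].
#' @return list with `instances` (list of [parsed_instance()]) and `truth`
#'   (data.frame index / verb / pattern / voice / kind, where kind is one of
#'   planted, nonlex, ne_free, offframe).
#' @export
gen_parsed_corpus <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "lf_fixture_spec"))
  with_seed(spec$seed + 1L, {
    instances <- list()
    truth <- list()
    add <- function(ins, verb, pattern, kind) {
      instances[[length(instances) + 1L]] <<- ins
      truth[[length(truth) + 1L]] <<- data.frame(
        index = length(instances), verb = verb, pattern = pattern,
        voice = ins$voice, kind = kind, stringsAsFactors = FALSE)
    }
    mk_instance <- function(verb, pattern, vspec, with_ne = TRUE) {
      labels <- strsplit(pattern, "#", fixed = TRUE)[[1]]
      ne <- vapply(labels, function(l) {
        fill <- vspec$ne[[l]]
        if (with_ne && !is.null(fill) && stats::runif(1) <= spec$ne_rate) {
          fill
        } else NA_character_
      }, character(1))
      voice <- if (stats::runif(1) < vspec$passive) "passive" else "active"
      parsed_instance(verb, voice,
                      data.frame(label = labels, category = "NP",
                                 ne_type = unname(ne),
                                 stringsAsFactors = FALSE),
                      sentence_id = sprintf("s%06d", length(instances) + 1L))
    }
    n <- spec$n_instances_per_verb
    for (verb in names(spec$verbs)) {
      vspec <- spec$verbs[[verb]]
      draws <- sample(names(vspec$patterns), n, replace = TRUE,
                      prob = vspec$patterns)
      for (pat in draws) add(mk_instance(verb, pat, vspec), verb, pat,
                             "planted")
      # distractors
      d <- spec$distractors
      for (k in seq_len(round(d$ne_free_rate * n))) {
        pat <- sample(names(vspec$patterns), 1, prob = vspec$patterns)
        add(mk_instance(verb, pat, vspec, with_ne = FALSE), verb, pat,
            "ne_free")
      }
      for (k in seq_len(round(d$offframe_rate * n))) {
        # object only: every stored frame requires ARG1, so this pattern
        # carries an NE yet matches no frame
        add(mk_instance(verb, "ARG2", vspec), verb, "ARG2", "offframe")
      }
      for (k in seq_len(round(d$nonlex_rate * n))) {
        pat <- sample(names(vspec$patterns), 1, prob = vspec$patterns)
        add(mk_instance("happen", pat, vspec), "happen", pat, "nonlex")
      }
    }
    list(instances = instances, truth = do.call(rbind, truth))
  })
}

#' Generate annotated events paired with the parsed corpus
#'
#' Each verb's events realize the spec's role pattern with its NE fillers,
#' so that [extract_sem_frames()] recovers exactly the planted frames and
#' [link_frames()] succeeds against the verb's grammatical frames.
#'
#' @param spec an [fixture_spec()].
#' @return list of [event_annotation()] objects.
#' @export
gen_events <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "lf_fixture_spec"))
  with_seed(spec$seed + 2L, {
    events <- list()
    for (verb in names(spec$verbs)) {
      vspec <- spec$verbs[[verb]]
      if (is.null(vspec$roles)) next
      for (k in seq_len(spec$n_events_per_verb)) {
        events[[length(events) + 1L]] <- event_annotation(
          verb, roles = names(vspec$roles), ne_types = unname(vspec$roles),
          sentence_id = sprintf("ev-%s-%03d", verb, k))
      }
    }
    events
  })
}

#' Generate term candidates against a dictionary
#'
#' True candidates are corruptions of dictionary base names by recoverable
#' processes with recognizer probability above 0.99; sub-threshold
#' candidates carry probability at most 0.99; junk candidates are random
#' strings with no dictionary counterpart.  The truth table records each
#' candidate's intended accession (`NA` for junk).
#'
#' @param dict_truth the `truth` component of [gen_dictionary()].
#' @param spec an [fixture_spec()].
#' @param n_true,n_subthreshold,n_junk candidate counts.
#' @param processes corruption processes used for true candidates; defaults
#'   to the recoverable processes of the dictionary spec, so induced rules
#'   cover the corruptions.
#' @return list with `candidates` (an [candidate_terms()] data.frame) and
#'   `truth` (data.frame surface_form / accession / kind).
#' @export
gen_candidates <- function(dict_truth, spec = fixture_spec(),
                           n_true = 50L, n_subthreshold = 10L,
                           n_junk = 10L,
                           processes = intersect(names(spec$processes),
                                                 recoverable_processes)) {
  with_seed(spec$seed + 3L, {
    bases <- dict_truth[dict_truth$process == "base", ]
    mk_true <- function(n) {
      out <- list()
      while (length(out) < n) {
        i <- sample(nrow(bases), 1)
        p <- if (length(processes) == 1) processes
             else sample(processes, 1)
        v <- apply_process(bases$term[i], p)
        if (is.na(v)) next
        out[[length(out) + 1L]] <- data.frame(
          surface_form = v, accession = bases$accession[i], kind = "true",
          stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }
    true_df <- mk_true(n_true)
    sub_df <- if (n_subthreshold > 0) {
      d <- mk_true(n_subthreshold)
      d$kind <- "subthreshold"
      d
    }
    junk_df <- if (n_junk > 0) {
      data.frame(
        surface_form = vapply(seq_len(n_junk), function(i) {
          paste0("zz", paste(sample(letters, 6, replace = TRUE),
                             collapse = ""), sample(100:999, 1))
        }, character(1)),
        accession = NA_character_, kind = "junk", stringsAsFactors = FALSE)
    }
    truth <- rbind(true_df, sub_df, junk_df)
    prob <- ifelse(truth$kind == "subthreshold",
                   stats::runif(nrow(truth), 0.5, 0.99),
                   stats::runif(nrow(truth), 0.991, 0.9999))
    cands <- candidate_terms(truth$surface_form, prob)
    list(candidates = cands, truth = truth)
  })
}
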