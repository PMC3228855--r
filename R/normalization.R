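#' Deterministic term-normalization rules
#'
#' A normalization rule is a total, deterministic, idempotent rewrite on
#' strings.  Rules collapse written variants of biomedical terms (case
#' variation, hyphenation, Anglo-American spelling, ...) onto a shared
#' canonical form so that an inverse index can map any variant to its
#' accession number by a single lookup instead of pairwise similarity
#' computation over the whole dictionary.
#'
#' Four kinds of rule are supported:
#' \describe{
#'   \item{case_fold}{lower-case the whole string (no pattern).}
#'   \item{delete_class}{delete or collapse a character class; `pattern` names
#'     the class: `"hyphens"` (remove dashes), `"punctuation"` (remove
#'     punctuation other than dashes and spaces), `"spaces"` (remove all
#'     whitespace), `"whitespace"` (collapse whitespace runs to one space and
#'     trim).}
#'   \item{substring_rewrite}{replace every occurrence of a fixed substring
#'     (`pattern`) by `replacement`, iterated to a fixed point so the rule is
#'     idempotent.}
#'   \item{token_sort}{sort whitespace-separated tokens alphabetically
#'     (catches structural variants such as "discs, large homolog 7"); off by
#'     default in induction.}
#' }
#'
#' @param kind one of `"case_fold"`, `"delete_class"`, `"substring_rewrite"`,
#'   `"token_sort"`.
#' @param pattern character class name or substring to replace; `""` for
#'   parameterless kinds.
#' @param replacement replacement string (substring_rewrite only).
#' @param rank integer application order within a rule set.
#' @param support number of intra-cluster variant pairs supporting the rule
#'   (filled in by [generate_candidate_rules()]).
#' @return an object of class `lf_rule`.
#' @seealso [ruleset()], [normalize_terms()], [induce_ruleset()]
#' @export
norm_rule <- function(kind, pattern = "", replacement = "", rank = 1L,
                      support = 0L) {
  kind <- match.arg(kind, c("case_fold", "delete_class", "substring_rewrite",
                            "token_sort"))
  if (kind == "delete_class") {
    pattern <- match.arg(pattern,
                         c("hyphens", "punctuation", "spaces", "whitespace"))
  }
  if (kind == "substring_rewrite" && !nzchar(pattern)) {
    stop("substring_rewrite requires a non-empty pattern")
  }
  structure(list(kind = kind, pattern = pattern, replacement = replacement,
                 rank = as.integer(rank), support = as.integer(support)),
            class = "lf_rule")
}

#' @export
format.lf_rule <- function(x, ...) {
  paste(x$kind, x$pattern, x$replacement, sep = "\t")
}

#' @export
print.lf_rule <- function(x, ...) {
  desc <- switch(x$kind,
    case_fold = "case_fold",
    delete_class = paste0("delete_class(", x$pattern, ")"),
    substring_rewrite = sprintf("substring_rewrite('%s' -> '%s')",
                                x$pattern, x$replacement),
    token_sort = "token_sort")
  cat(sprintf("<rule %d> %s\n", x$rank, desc))
  invisible(x)
}

# canonical one-line representation, used for dedup and tie-breaking
rule_repr <- function(rule) {
  paste(rule$kind, rule$pattern, rule$replacement, sep = "\x1f")
}

apply_rule <- function(x, rule) {
  switch(rule$kind,
    case_fold = stringi::stri_trans_tolower(x),
    delete_class = switch(rule$pattern,
      hyphens     = gsub("\\p{Pd}", "", x, perl = TRUE),
      punctuation = gsub("(?![\\p{Pd}])[\\p{P}\\p{S}]", "", x, perl = TRUE),
      spaces      = gsub("\\s", "", x, perl = TRUE),
      whitespace  = trimws(gsub("\\s+", " ", x, perl = TRUE))
    ),
    substring_rewrite = {
      # iterate to fixed point so the rule is idempotent even for patterns
      # whose single application is not (e.g. "aa" -> "a")
      for (i in seq_len(25L)) {
        y <- gsub(rule$pattern, rule$replacement, x, fixed = TRUE)
        if (identical(y, x)) break
        x <- y
      }
      x
    },
    token_sort = vapply(strsplit(x, "\\s+"), function(tok) {
      paste(sort(tok), collapse = " ")
    }, character(1))
  )
}

#' Ordered set of normalization rules
#'
#' @param rules a list of [norm_rule()] objects; ranks are reassigned to the
#'   strictly increasing sequence 1..n in the given order.
#' @return an object of class `lf_ruleset`.
#' @export
ruleset <- function(rules = list()) {
  stopifnot(all(vapply(rules, inherits, logical(1), "lf_rule")))
  for (i in seq_along(rules)) rules[[i]]$rank <- i
  structure(list(rules = rules), class = "lf_ruleset")
}

#' @export
length.lf_ruleset <- function(x) length(x$rules)

#' @export
print.lf_ruleset <- function(x, ...) {
  cat(sprintf("Normalization rule set: %d rule(s)\n", length(x$rules)))
  for (r in x$rules) print(r)
  invisible(x)
}

ruleset_signature <- function(rules) {
  stopifnot(inherits(rules, "lf_ruleset"))
  paste(vapply(rules$rules, rule_repr, character(1)), collapse = "\x1e")
}

#' Normalize terms with a rule set
#'
#' Terms are first Unicode-normalized (NFC), then every rule is applied once
#' in rank order.  The function is total and deterministic, and
#' `normalize_terms(normalize_terms(x, r), r) == normalize_terms(x, r)`.
#'
#' @param terms character vector.
#' @param rules an [ruleset()].
#' @return character vector of normalized forms.
#' @examples
#' r <- ruleset(list(norm_rule("case_fold"),
#'                   norm_rule("delete_class", "hyphens")))
#' normalize_terms("NF-KB", r)  # "nfkb"
#' @export
normalize_terms <- function(terms, rules) {
  stopifnot(inherits(rules, "lf_ruleset"))
  x <- stringi::stri_trans_nfc(as.character(terms))
  for (r in rules$rules) x <- apply_rule(x, r)
  x
}

#' Accession-clustered synonym dictionary
#'
#' A dictionary of terms clustered by database accession number (e.g. a
#' UniProt accession).  A term may belong to several clusters: that is genuine
#' ambiguity, not an error.
#'
#' @param x either a data.frame with columns `accession`, `term` and
#'   optionally `source`, or a named list mapping accession to a character
#'   vector of terms.
#' @param source default source label when `x` carries none.
#' @return an object of class `lf_dictionary` (a data.frame with columns
#'   `accession`, `term`, `source`).
#' @export
clustered_dictionary <- function(x, source = "db") {
  if (is.list(x) && !is.data.frame(x)) {
    stopifnot(!is.null(names(x)))
    x <- data.frame(
      accession = rep(names(x), lengths(x)),
      term = unlist(x, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(x), all(c("accession", "term") %in% names(x)))
  if (is.null(x$source)) x$source <- source
  x <- x[, c("accession", "term", "source")]
  x$accession <- as.character(x$accession)
  x$term <- stringi::stri_trans_nfc(as.character(x$term))
  if (any(!nzchar(x$term))) stop("dictionary terms must be non-empty")
  if (!nrow(x)) stop("dictionary must contain at least one term")
  x <- unique(x)
  rownames(x) <- NULL
  class(x) <- c("lf_dictionary", "data.frame")
  x
}

dict_clusters <- function(dict) {
  split(dict$term, dict$accession)
}

#' Read / write a clustered dictionary as TSV
#'
#' Columns: accession, term, source, and optionally semantic_type, curated
#' (extra columns are preserved).
#'
#' @param path file path.
#' @param dict an `lf_dictionary`.
#' @return `read_dictionary()` returns an `lf_dictionary`;
#'   `write_dictionary()` returns `path` invisibly.
#' @export
read_dictionary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  clustered_dictionary(df)
}

#' @rdname read_dictionary
#' @export
write_dictionary <- function(dict, path) {
  utils::write.table(as.data.frame(dict), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Ambiguity and variability of a dictionary under a rule set
#'
#' Variability is the mean, over accession clusters, of the number of distinct
#' normalized forms in the cluster (1 iff every cluster collapses to a single
#' form).  Ambiguity is the mean, over distinct normalized forms, of the
#' number of clusters containing a term with that form (1 iff no form is
#' shared across clusters).  Rules trade the two off: a rewrite can only merge
#' forms, so it never increases variability and never decreases ambiguity.
#'
#' @param dict an [clustered_dictionary()].
#' @param rules an [ruleset()].
#' @return an object of class `lf_metrics`: list with `ambiguity`,
#'   `variability`, `n_forms`, `n_clusters`.
#' @examples
#' d <- clustered_dictionary(list(A = c("IL-2", "Il2"), B = "il2"))
#' compute_metrics(d, ruleset())  # variability 1.5, ambiguity 1
#' @export
compute_metrics <- function(dict, rules = ruleset()) {
  stopifnot(inherits(dict, "lf_dictionary"))
  if (!nrow(dict)) stop("dictionary is empty")
  forms <- normalize_terms(dict$term, rules)
  metrics_from_forms(dict$accession, forms)
}

metrics_from_forms <- function(accession, forms) {
  pairs <- unique(data.frame(accession = accession, form = forms,
                             stringsAsFactors = FALSE))
  per_cluster <- table(pairs$accession)
  per_form <- table(pairs$form)
  structure(list(
    ambiguity = mean(per_form),
    variability = mean(per_cluster),
    n_forms = length(per_form),
    n_clusters = length(per_cluster)
  ), class = "lf_metrics")
}

#' @export
print.lf_metrics <- function(x, ...) {
  cat(sprintf(
    "ambiguity %.4f | variability %.4f | %d forms | %d clusters\n",
    x$ambiguity, x$variability, x$n_forms, x$n_clusters))
  invisible(x)
}

# -- candidate generation ----------------------------------------------------

# longest common prefix / suffix lengths of two character scalars
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- substring(a, 1:n, 1:n); cb <- substring(b, 1:n, 1:n)
  d <- which(ca != cb)
  if (!length(d)) n else d[1] - 1L
}

strip_chars <- function(x, class_re) gsub(class_re, "", x, perl = TRUE)

#' Generate candidate normalization rules from a dictionary
#'
#' Candidates are derived from pairs of terms inside the same accession
#' cluster: a case-only difference yields `case_fold`; a difference explained
#' by deleting/collapsing one character class yields `delete_class`; any other
#' bounded difference yields a `substring_rewrite` built from the differing
#' middle plus one character of context on each side (so "tumour"/"tumor"
#' yields "our" -> "or" rather than a bare deletion of "u").  Candidates are
#' deduplicated and carry the number of supporting pairs.
#'
#' @param dict an [clustered_dictionary()].
#' @param max_mid maximum length of the differing middle on either side for a
#'   substring rewrite to be proposed.
#' @param max_terms_per_cluster pair enumeration is capped at this many terms
#'   per cluster.
#' @return list of [norm_rule()] objects, ordered by decreasing support then
#'   by rule representation.
#' @export
generate_candidate_rules <- function(dict, max_mid = 3L,
                                     max_terms_per_cluster = 25L) {
  stopifnot(inherits(dict, "lf_dictionary"))
  support <- new.env(parent = emptyenv())
  bump <- function(rule) {
    key <- rule_repr(rule)
    cur <- support[[key]]
    if (is.null(cur)) {
      rule$support <- 1L
      support[[key]] <- rule
    } else {
      cur$support <- cur$support + 1L
      support[[key]] <- cur
    }
  }
  for (terms in dict_clusters(dict)) {
    terms <- unique(terms)
    if (length(terms) > max_terms_per_cluster) {
      terms <- terms[seq_len(max_terms_per_cluster)]
    }
    if (length(terms) < 2) next
    idx <- utils::combn(length(terms), 2)
    for (k in seq_len(ncol(idx))) {
      a <- terms[idx[1, k]]; b <- terms[idx[2, k]]
      for (rule in pair_candidates(a, b, max_mid)) bump(rule)
    }
  }
  out <- as.list(support)
  ord <- order(-vapply(out, function(r) r$support, integer(1)),
               vapply(out, rule_repr, character(1)))
  unname(out[ord])
}

pair_candidates <- function(a, b, max_mid = 3L) {
  out <- list()
  la <- stringi::stri_trans_tolower(a)
  lb <- stringi::stri_trans_tolower(b)
  if (la == lb) {
    if (a != b) return(list(norm_rule("case_fold")))
    return(out)
  }
  # the pair differs beyond case: keep a case_fold candidate when case is
  # part of the difference, then diagnose the rest case-insensitively
  # (induced rule sets apply case folding first in practice)
  if (la != a || lb != b) out <- list(norm_rule("case_fold"))
  a <- la; b <- lb
  collapse <- function(x) trimws(gsub("\\s+", " ", x, perl = TRUE))
  if (collapse(a) == collapse(b)) {
    return(c(out, list(norm_rule("delete_class", "whitespace"))))
  }
  re_punct <- "(?![\\p{Pd}])[\\p{P}\\p{S}]"
  if (collapse(strip_chars(a, re_punct)) == collapse(strip_chars(b, re_punct))) {
    return(c(out, list(norm_rule("delete_class", "punctuation"))))
  }
  if (strip_chars(a, "\\p{Pd}") == strip_chars(b, "\\p{Pd}")) {
    return(c(out, list(norm_rule("delete_class", "hyphens"))))
  }
  # hyphen/space interchange or joint removal ("amino acid" ~ "amino-acid")
  sa <- strip_chars(a, "[\\p{Pd}\\s]"); sb <- strip_chars(b, "[\\p{Pd}\\s]")
  if (sa == sb) {
    if (grepl("\\p{Pd}", paste(a, b), perl = TRUE)) {
      out <- c(out, list(norm_rule("delete_class", "hyphens")))
    }
    if (grepl("\\s", paste(a, b), perl = TRUE)) {
      out <- c(out, list(norm_rule("delete_class", "spaces")))
    }
    return(out)
  }
  # token permutation
  tok <- function(x) paste(sort(strsplit(collapse(x), " ")[[1]]), collapse = " ")
  if (tok(a) == tok(b)) return(c(out, list(norm_rule("token_sort"))))
  # bounded substring rewrite with one character of context on each side
  p <- lcp_len(a, b)
  ra <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
  rb <- paste(rev(strsplit(b, "")[[1]]), collapse = "")
  s <- lcp_len(ra, rb)
  s <- min(s, nchar(a) - p, nchar(b) - p)  # keep prefix/suffix disjoint
  mid_a <- substr(a, p + 1L, nchar(a) - s)
  mid_b <- substr(b, p + 1L, nchar(b) - s)
  if (nchar(mid_a) > max_mid || nchar(mid_b) > max_mid) return(out)
  ctx_pre <- if (p > 0) substr(a, p, p) else ""
  ctx_suf <- if (s > 0) substr(a, nchar(a) - s + 1L, nchar(a) - s + 1L) else ""
  from <- paste0(ctx_pre, mid_a, ctx_suf)
  to <- paste0(ctx_pre, mid_b, ctx_suf)
  if (from == to || !nzchar(from) || !nzchar(to)) return(out)
  # orient longer -> shorter (ties: lexicographically larger -> smaller)
  if (nchar(to) > nchar(from) || (nchar(to) == nchar(from) && to > from)) {
    tmp <- from; from <- to; to <- tmp
  }
  c(out, list(norm_rule("substring_rewrite", from, to)))
}

#' Greedy induction of a normalization rule set
#'
#' Repeatedly adds the candidate rule that maximizes the reduction in
#' variability minus `lambda` times the increase in ambiguity, stopping when
#' no candidate scores above zero or when `k_max` rules have been selected.
#' Ties are broken by higher supporting-pair count, then by the lexicographic
#' rule representation, so induction is deterministic.
#'
#' @param dict an [clustered_dictionary()].
#' @param k_max maximum number of rules (default 1000).
#' @param lambda penalty weight on ambiguity increase (default 1).
#' @param candidates optional pre-computed candidate list; defaults to
#'   [generate_candidate_rules()] on `dict`.
#' @param include_token_sort keep `token_sort` candidates (default `FALSE`;
#'   token reordering is aggressive and off unless asked for).
#' @return an [ruleset()] ordered by selection.
#' @export
induce_ruleset <- function(dict, k_max = 1000L, lambda = 1,
                           candidates = NULL, include_token_sort = FALSE) {
  stopifnot(inherits(dict, "lf_dictionary"), k_max >= 1, lambda >= 0)
  if (is.null(candidates)) candidates <- generate_candidate_rules(dict)
  if (!include_token_sort) {
    candidates <- Filter(function(r) r$kind != "token_sort", candidates)
  }
  chosen <- list()
  forms <- normalize_terms(dict$term, ruleset())
  cur <- metrics_from_forms(dict$accession, forms)
  while (length(chosen) < k_max && length(candidates)) {
    scores <- vapply(candidates, function(r) {
      m <- metrics_from_forms(dict$accession, apply_rule(forms, r))
      (cur$variability - m$variability) - lambda * (m$ambiguity - cur$ambiguity)
    }, numeric(1))
    # candidates are pre-sorted by support then repr, so which.max respects
    # the tie-breaking order
    best <- which.max(scores)
    if (scores[best] <= 0) break
    rule <- candidates[[best]]
    chosen <- c(chosen, list(rule))
    candidates <- candidates[-best]
    forms <- apply_rule(forms, rule)
    cur <- metrics_from_forms(dict$accession, forms)
  }
  ruleset(chosen)
}

#' Read / write a rule set as TSV
#'
#' Columns: rank, kind, pattern, replacement, support.
#'
#' @param rules an [ruleset()].
#' @param path file path.
#' @return `read_ruleset()` returns an `lf_ruleset`; `write_ruleset()`
#'   returns `path` invisibly.
#' @export
write_ruleset <- function(rules, path) {
  df <- data.frame(
    rank = vapply(rules$rules, `[[`, integer(1), "rank"),
    kind = vapply(rules$rules, `[[`, character(1), "kind"),
    pattern = vapply(rules$rules, `[[`, character(1), "pattern"),
    replacement = vapply(rules$rules, `[[`, character(1), "replacement"),
    support = vapply(rules$rules, `[[`, integer(1), "support")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = c(rank = "integer", kind = "character",
                                         pattern = "character",
                                         replacement = "character",
                                         support = "integer"))
  df <- df[order(df$rank), , drop = FALSE]
  df$pattern[is.na(df$pattern)] <- ""
  df$replacement[is.na(df$replacement)] <- ""
  ruleset(lapply(seq_len(nrow(df)), function(i) {
    norm_rule(df$kind[i], df$pattern[i], df$replacement[i], df$rank[i],
              df$support[i])
  }))
}

#' Inverse index from normalized form to accession numbers
#'
#' Maps the normalized form of every dictionary term to the set of accessions
#' whose cluster contains a term with that form.  Looking a candidate up in
#' the index replaces the pairwise similarity computation over the whole
#' dictionary with one normalization plus one hash lookup.
#'
#' @param dict an [clustered_dictionary()].
#' @param rules the [ruleset()] used for normalization; its identity is
#'   stored so that [map_term()] can refuse a mismatched rule set.
#' @return an object of class `lf_index`.
#' @export
build_inverse_index <- function(dict, rules = ruleset()) {
  stopifnot(inherits(dict, "lf_dictionary"))
  forms <- normalize_terms(dict$term, rules)
  by_form <- split(dict$accession, forms)
  by_form <- lapply(by_form, function(a) sort(unique(a)))
  structure(list(forms = by_form, ruleset_sig = ruleset_signature(rules)),
            class = "lf_index")
}

#' @export
print.lf_index <- function(x, ...) {
  cat(sprintf("Inverse index: %d normalized forms\n", length(x$forms)))
  invisible(x)
}

#' Look up a normalized form in an inverse index
#'
#' @param index an [build_inverse_index()] result.
#' @param form normalized form (already normalized by the index's rule set).
#' @return character vector of accessions (empty when unseen).
#' @export
index_lookup <- function(index, form) {
  stopifnot(inherits(index, "lf_index"))
  hit <- index$forms[[form]]
  if (is.null(hit)) character(0) else hit
}

#' Write an inverse index as TSV (normalized_form, accessions)
#'
#' @param index an `lf_index`.
#' @param path file path.
#' @export
write_index <- function(index, path) {
  df <- data.frame(
    normalized_form = names(index$forms),
    accessions = vapply(index$forms, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$normalized_form), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
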