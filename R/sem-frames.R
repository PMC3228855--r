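#' The semantic role inventory
#'
#' The closed set of 13 event-independent semantic roles used to annotate
#' biomedical events: who drives the event (AGENT), what is affected by it
#' (THEME), and the circumstantial roles that matter for the precise
#' interpretation of biological relations (location, experimental condition,
#' rate of change, ...).
#'
#' @return character vector of the 13 role names.
#' @export
role_inventory <- function() {
  c("AGENT", "THEME", "MANNER", "INSTRUMENT", "LOCATION", "SOURCE",
    "DESTINATION", "TEMPORAL", "CONDITION", "RATE", "DESCRIPTIVE-AGENT",
    "DESCRIPTIVE-THEME", "PURPOSE")
}

#' Named-entity taxonomy
#'
#' Five top-level NE classes annotate event participants: DNA, PROTEIN,
#' EXPERIMENTAL, ORGANISMS and PROCESSES.  Subtypes (e.g. PROMOTER under DNA)
#' resolve to their top-level class through the extensible `subtypes` map.
#'
#' @param extra named character vector of additional subtype -> class
#'   mappings.
#' @return an object of class `lf_ne_taxonomy`: list with `classes` and
#'   `subtypes`.
#' @export
ne_taxonomy <- function(extra = character(0)) {
  classes <- c("DNA", "PROTEIN", "EXPERIMENTAL", "ORGANISMS", "PROCESSES")
  subtypes <- c(
    PROMOTER = "DNA", GENE = "DNA", OPERON = "DNA", BINDING_SITE = "DNA",
    ENZYME = "PROTEIN", TRANSCRIPTION_FACTOR = "PROTEIN",
    PROTEIN_COMPLEX = "PROTEIN",
    SPECIES = "ORGANISMS", STRAIN = "ORGANISMS", CELL = "ORGANISMS",
    ASSAY = "EXPERIMENTAL", PLASMID = "EXPERIMENTAL",
    REGULATION = "PROCESSES", TRANSCRIPTION = "PROCESSES",
    extra
  )
  bad <- setdiff(unique(subtypes), classes)
  if (length(bad)) stop("subtype maps to unknown class: ",
                        paste(bad, collapse = ", "))
  structure(list(classes = classes, subtypes = subtypes),
            class = "lf_ne_taxonomy")
}

#' Resolve an NE type to its top-level class
#'
#' @param ne_type character vector of annotated NE types.
#' @param taxonomy an [ne_taxonomy()].
#' @return character vector of top-level classes (`NA` stays `NA`; unknown
#'   types are an error).
#' @export
resolve_ne_class <- function(ne_type, taxonomy = ne_taxonomy()) {
  up <- toupper(ne_type)
  out <- ifelse(up %in% taxonomy$classes, up,
                unname(taxonomy$subtypes[up]))
  bad <- !is.na(ne_type) & is.na(out)
  if (any(bad)) {
    stop("NE type(s) outside taxonomy: ",
         paste(unique(ne_type[bad]), collapse = ", "))
  }
  out
}

#' A manually annotated event
#'
#' An event is anchored on a trigger (a verb, or a nominalized verb such as
#' "regulation") and carries role-labelled arguments, each optionally typed
#' with an NE class, e.g. the annotation of "Fis activates rrnB P1" has
#' AGENT = Fis (Protein) and THEME = rrnB P1 (DNA).
#'
#' @param trigger_lemma lemma of the trigger.
#' @param roles character vector of role labels (from [role_inventory()]).
#' @param ne_types character vector of NE types parallel to `roles` (`NA`
#'   allowed).
#' @param texts optional argument texts.
#' @param is_nominalized whether the trigger is a nominalized verb.
#' @param base_verb base verb lemma for a nominalized trigger (e.g.
#'   "regulate" for "regulation"); defaults to the trigger lemma.
#' @param sentence_id provenance.
#' @return an object of class `lf_event`.
#' @export
event_annotation <- function(trigger_lemma, roles, ne_types = NA,
                             texts = NA, is_nominalized = FALSE,
                             base_verb = trigger_lemma,
                             sentence_id = NA_character_) {
  roles <- toupper(roles)
  bad <- setdiff(roles, role_inventory())
  if (length(bad)) stop("role(s) outside inventory: ",
                        paste(bad, collapse = ", "))
  if (sum(roles == "AGENT") > 1 || sum(roles == "THEME") > 1) {
    stop("at most one AGENT and one THEME per event")
  }
  args <- data.frame(role = roles,
                     ne_type = rep_len(as.character(ne_types), length(roles)),
                     text = rep_len(as.character(texts), length(roles)),
                     stringsAsFactors = FALSE)
  structure(list(trigger_lemma = as.character(trigger_lemma),
                 base_verb = as.character(base_verb),
                 is_nominalized = isTRUE(is_nominalized),
                 arguments = args,
                 sentence_id = as.character(sentence_id)),
            class = "lf_event")
}

#' Read events from JSONL
#'
#' One object per line: `{"trigger": ..., "base_verb": ..., "nominalized":
#' ..., "sentence_id": ..., "args": [{"role": ..., "ne_type": ..., "text":
#' ...}, ...]}`.
#'
#' @param path file path.
#' @return list of [event_annotation()] objects.
#' @export
read_events <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyDataFrame = TRUE)
    args <- rec$args
    event_annotation(rec$trigger,
                     roles = args$role,
                     ne_types = args$ne_type %||% NA,
                     texts = args$text %||% NA,
                     is_nominalized = isTRUE(rec$nominalized),
                     base_verb = rec$base_verb %||% rec$trigger,
                     sentence_id = rec$sentence_id %||% NA_character_)
  })
}

#' Write events as JSONL
#'
#' @param events list of [event_annotation()] objects.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (ev in events) {
    rec <- list(trigger = ev$trigger_lemma, base_verb = ev$base_verb,
                nominalized = ev$is_nominalized,
                sentence_id = ev$sentence_id, args = ev$arguments)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

role_rank <- function(roles, hierarchy = default_role_hierarchy()) {
  match(roles, hierarchy)
}

#' Default role hierarchy
#'
#' Total order on the role inventory used for argument alignment: core roles
#' first (AGENT before THEME), then circumstantials, descriptives last.
#'
#' @return character vector (highest first).
#' @export
default_role_hierarchy <- function() {
  c("AGENT", "THEME", "INSTRUMENT", "SOURCE", "DESTINATION", "LOCATION",
    "TEMPORAL", "CONDITION", "RATE", "MANNER", "PURPOSE",
    "DESCRIPTIVE-AGENT", "DESCRIPTIVE-THEME")
}

# display form of a role: AGENT -> Agent, DESCRIPTIVE-AGENT -> Descriptive-Agent
role_display <- function(role) {
  parts <- strsplit(role, "-", fixed = TRUE)
  vapply(parts, function(p) {
    paste(paste0(substr(p, 1, 1), tolower(substring(p, 2))), collapse = "-")
  }, character(1))
}

# display form of an NE class: PROTEIN -> Protein, DNA -> DNA
ne_display <- function(cls) {
  ifelse(is.na(cls) | cls == "DNA", cls,
         paste0(substr(cls, 1, 1), tolower(substring(cls, 2))))
}

#' Construct a single semantic frame
#'
#' @param verb verb lemma.
#' @param roles character vector of roles.
#' @param fillers character vector of NE classes parallel to `roles` (`NA`
#'   for untyped roles).
#' @param support observation count.
#' @param hierarchy role ordering (see [default_role_hierarchy()]).
#' @return an object of class `lf_semframe`.
#' @export
sem_frame <- function(verb, roles, fillers = NA, support = 1L,
                      hierarchy = default_role_hierarchy()) {
  roles <- toupper(roles)
  bad <- setdiff(roles, role_inventory())
  if (length(bad)) stop("role(s) outside inventory: ",
                        paste(bad, collapse = ", "))
  fillers <- rep_len(as.character(fillers), length(roles))
  ord <- order(role_rank(roles, hierarchy))
  structure(list(verb = as.character(verb), roles = roles[ord],
                 fillers = fillers[ord], support = as.integer(support)),
            class = "lf_semframe")
}

#' @export
format.lf_semframe <- function(x, ...) {
  inner <- ifelse(is.na(x$fillers), role_display(x$roles),
                  paste0(role_display(x$roles), "=>", ne_display(x$fillers)))
  paste0(x$verb, "(", paste(inner, collapse = ","), ")")
}

#' @export
print.lf_semframe <- function(x, ...) {
  cat(format(x), sprintf(" [support %d]\n", x$support))
  invisible(x)
}

#' Extract semantic frames from annotated events
#'
#' Groups events by verb, role pattern and NE-filler pattern, producing one
#' frame per distinct combination with its support count.  Nominalized
#' triggers contribute to their base verb's frames (so "regulation" events
#' reinforce the frames of "regulate") unless `merge_nominalized = FALSE`.
#' NE types are resolved to top-level classes through the taxonomy.
#'
#' @param events list of [event_annotation()] objects.
#' @param taxonomy an [ne_taxonomy()].
#' @param hierarchy role ordering.
#' @param merge_nominalized merge nominalized triggers into the base verb.
#' @return list of [sem_frame()] objects, sorted by verb then decreasing
#'   support then serialization.
#' @export
extract_sem_frames <- function(events, taxonomy = ne_taxonomy(),
                               hierarchy = default_role_hierarchy(),
                               merge_nominalized = TRUE) {
  if (!length(events)) return(list())
  frames <- lapply(events, function(ev) {
    verb <- if (merge_nominalized && ev$is_nominalized) ev$base_verb
            else ev$trigger_lemma
    fill <- resolve_ne_class(ev$arguments$ne_type, taxonomy)
    sem_frame(verb, ev$arguments$role, fill, hierarchy = hierarchy)
  })
  keys <- vapply(frames, format, character(1))
  tab <- table(keys)
  uniq <- frames[!duplicated(keys)]
  for (i in seq_along(uniq)) {
    uniq[[i]]$support <- as.integer(tab[[format(uniq[[i]])]])
  }
  ord <- order(vapply(uniq, `[[`, character(1), "verb"),
               -vapply(uniq, `[[`, integer(1), "support"),
               vapply(uniq, format, character(1)))
  uniq[ord]
}

#' Write semantic frames as TSV
#'
#' Columns: verb, roles, fillers, support, serialization (the
#' `verb(Role=>Filler,...)` notation).
#'
#' @param frames list of [sem_frame()] objects.
#' @param path file path.
#' @export
write_sem_frames <- function(frames, path) {
  df <- data.frame(
    verb = vapply(frames, `[[`, character(1), "verb"),
    roles = vapply(frames, function(f) paste(f$roles, collapse = ","),
                   character(1)),
    fillers = vapply(frames, function(f) paste(f$fillers, collapse = ","),
                     character(1)),
    support = vapply(frames, `[[`, integer(1), "support"),
    serialization = vapply(frames, format, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Constraints for linking semantic to grammatical frames
#'
#' Linking aligns the arguments of a semantic frame with the slots of a
#' grammatical frame of the same verb, using (a) a total order on semantic
#' roles and one on grammatical slots, with mapping proceeding left to right,
#' and (b) a table of prototypic grammatical realizations per role: the
#' AGENT is typically the grammatical subject, the INSTRUMENT typically a
#' prepositional phrase headed by with/through/using/via/by, the PURPOSE an
#' infinitival clause, and so on.
#'
#' @param role_hierarchy total order on roles, beginning AGENT > THEME.
#' @param prototypes named list mapping each role to its admissible slot
#'   labels.
#' @return an object of class `lf_linking_rules`.
#' @export
linking_rules <- function(role_hierarchy = default_role_hierarchy(),
                          prototypes = default_prototypes()) {
  stopifnot(setequal(role_hierarchy, role_inventory()),
            all(role_inventory() %in% names(prototypes)))
  structure(list(role_hierarchy = role_hierarchy, prototypes = prototypes),
            class = "lf_linking_rules")
}

#' Default prototypic realizations of semantic roles
#'
#' @return named list: role -> admissible slot labels.
#' @export
default_prototypes <- function() {
  list(
    AGENT = "ARG1",
    THEME = "ARG2",
    INSTRUMENT = c("PP-with", "PP-through", "PP-using", "PP-via", "PP-by"),
    SOURCE = "PP-from",
    DESTINATION = c("PP-to", "PP-into", "PP-towards", "PP-onto"),
    LOCATION = c("PP-in", "PP-on", "PP-at", "PP-within"),
    TEMPORAL = c("PP-after", "PP-before", "PP-during", "PP-upon"),
    CONDITION = c("PP-under", "PP-in", "PP-upon"),
    RATE = "PP-by",
    MANNER = c("PP-by", "PP-in", "PP-with", "ADV"),
    PURPOSE = c("TO-INF", "PP-for"),
    `DESCRIPTIVE-AGENT` = c("PP-as", "ARG3"),
    `DESCRIPTIVE-THEME` = c("PP-as", "ARG3")
  )
}

gram_rank <- function(slots) {
  # core args, clausal complements, PPs alphabetical, ADV last
  order(slot_sort_key(slots))
}

#' Link a semantic frame to a grammatical frame
#'
#' Three-stage alignment for frames of the same verb: (1) forced matches
#' through prototypic realizations whose admissible slots intersect the
#' unclaimed grammatical slots in exactly one element, taking roles in
#' hierarchy order so preposition-compatible PP slots are claimed first;
#' (2) roles whose admissible slots intersect several unclaimed slots take
#' the first by the grammatical hierarchy, and roles with no compatible slot
#' fall back to unclaimed core slots (ARG1/ARG2/ARG3) left to right;
#' (3) leftovers on either side link to 0.  Every role and every slot appears
#' in exactly one link.
#'
#' @param sem an [sem_frame()].
#' @param syn a grammatical frame: a serialized pattern such as
#'   `"ARG1#ARG2#PP-into"`, or a one-row [estimate_frames()] frame.
#' @param rules an [linking_rules()].
#' @param verb verb lemma of `syn` when `syn` is a bare pattern; defaults to
#'   the semantic frame's verb.
#' @return an object of class `lf_framelink`: list with `verb`, `sem`,
#'   `syn_pattern`, `links` (data.frame role/slot with `"0"` for unmapped
#'   sides), `contested` (roles whose unique prototypic slot was already
#'   claimed) and `ties` (roles matched by hierarchy among several
#'   compatible slots).
#' @examples
#' lk <- link_frames(sem_frame("activate", c("AGENT", "THEME")), "ARG1#ARG2")
#' format(lk)  # "AGENT > ARG1#THEME > ARG2"
#' @export
link_frames <- function(sem, syn, rules = linking_rules(), verb = NULL) {
  stopifnot(inherits(sem, "lf_semframe"))
  if (inherits(syn, "data.frame")) {
    stopifnot(nrow(syn) == 1)
    verb <- syn$verb
    syn <- syn$pattern
  }
  if (!is.null(verb) && !identical(verb, sem$verb)) {
    stop("verb mismatch: semantic frame is for '", sem$verb,
         "', grammatical frame for '", verb, "'")
  }
  slots <- strsplit(syn, "#", fixed = TRUE)[[1]]
  check_slot_labels(slots)
  roles <- sem$roles[order(role_rank(sem$roles, rules$role_hierarchy))]
  assigned <- stats::setNames(rep(NA_character_, length(roles)), roles)
  claimed <- character(0)
  claimer <- list()  # slot -> role that claimed it
  contested <- character(0)
  deferred <- character(0)
  # stage 1: unique prototypic matches, roles in hierarchy order
  for (r in roles) {
    adm <- rules$prototypes[[r]]
    compat <- intersect(adm, setdiff(slots, claimed))
    if (length(compat) == 1) {
      assigned[r] <- compat
      claimed <- c(claimed, compat)
      claimer[[compat]] <- r
    } else if (length(compat) > 1) {
      deferred <- c(deferred, r)
    } else if (length(intersect(adm, slots)) > 0) {
      # a prototypic slot exists but was claimed by a higher role; only a
      # genuine conflict when the hierarchy cannot justify the claim, i.e.
      # the claimer's prototypic realizations are identical to this role's
      # (e.g. the two descriptive roles competing for one PP-as)
      for (s in intersect(adm, slots)) {
        cl <- claimer[[s]]
        if (!is.null(cl) && setequal(rules$prototypes[[cl]], adm)) {
          contested <- c(contested, r)
          break
        }
      }
    }
  }
  # stage 2a: ties resolved along the grammatical hierarchy
  ties <- character(0)
  for (r in deferred) {
    compat <- intersect(rules$prototypes[[r]], setdiff(slots, claimed))
    if (length(compat)) {
      pick <- compat[gram_rank(compat)[1]]
      assigned[r] <- pick
      claimed <- c(claimed, pick)
      if (length(compat) > 1) ties <- c(ties, r)
    }
  }
  # stage 2b: left-to-right fallback of unmatched roles onto core slots
  core_free <- setdiff(intersect(c("ARG1", "ARG2", "ARG3"), slots), claimed)
  for (r in roles[is.na(assigned)]) {
    if (!length(core_free)) break
    assigned[r] <- core_free[1]
    claimed <- c(claimed, core_free[1])
    core_free <- core_free[-1]
  }
  # hierarchy repair: among roles holding core slots, re-pair so that role
  # order and slot order agree (a fallback can otherwise land a higher role
  # on a later slot than a forced lower role)
  core_roles <- roles[!is.na(assigned) &
                        assigned[roles] %in% c("ARG1", "ARG2", "ARG3")]
  if (length(core_roles) >= 2) {
    core_slots <- sort(unname(assigned[core_roles]))
    core_roles <- core_roles[order(role_rank(core_roles,
                                             rules$role_hierarchy))]
    assigned[core_roles] <- core_slots
  }
  # stage 3: leftovers to 0
  links <- data.frame(role = roles,
                      slot = ifelse(is.na(assigned), "0", assigned),
                      stringsAsFactors = FALSE)
  left_slots <- setdiff(slots, claimed)
  if (length(left_slots)) {
    links <- rbind(links, data.frame(role = "0", slot = left_slots,
                                     stringsAsFactors = FALSE))
  }
  # present pairs in grammatical-slot order, role > 0 pairs last
  has_slot <- links$slot != "0"
  links <- rbind(
    links[has_slot, , drop = FALSE][gram_rank(links$slot[has_slot]), ,
                                    drop = FALSE],
    links[!has_slot, , drop = FALSE]
  )
  rownames(links) <- NULL
  structure(list(verb = sem$verb, sem = sem, syn_pattern = syn,
                 links = links, contested = contested, ties = ties),
            class = "lf_framelink")
}

#' @export
format.lf_framelink <- function(x, ...) {
  paste(paste(x$links$role, x$links$slot, sep = " > "), collapse = "#")
}

#' @export
print.lf_framelink <- function(x, ...) {
  cat(format(x$sem), "x", x$syn_pattern, ":\n  ", format(x), "\n", sep = "")
  if (length(x$contested)) {
    cat("  contested role(s):", paste(x$contested, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Link all compatible frame pairs of shared verbs
#'
#' Attempts [link_frames()] on every (semantic, grammatical) frame pair of
#' the same verb.  Pairs whose forced-match stage is contested -- a role's
#' only prototypic slot already claimed by a higher role -- are reported as
#' conflicts rather than guessed.
#'
#' @param sems list of [sem_frame()] objects.
#' @param syns an [estimate_frames()] data.frame (or any data.frame with
#'   `verb` and `pattern` columns).
#' @param rules an [linking_rules()].
#' @return list with `links` (list of `lf_framelink`) and `conflicts`
#'   (data.frame verb / sem / syn / contested_roles).
#' @export
link_all <- function(sems, syns, rules = linking_rules()) {
  links <- list()
  conflicts <- list()
  for (sem in sems) {
    pats <- syns$pattern[syns$verb == sem$verb]
    for (p in pats) {
      lk <- link_frames(sem, p, rules)
      if (length(lk$contested)) {
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          verb = sem$verb, sem = format(sem), syn = p,
          contested_roles = paste(lk$contested, collapse = ","),
          stringsAsFactors = FALSE)
      } else {
        links[[length(links) + 1L]] <- lk
      }
    }
  }
  list(links = links,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts)
                   else data.frame(verb = character(0), sem = character(0),
                                   syn = character(0),
                                   contested_roles = character(0)))
}

#' Write frame links as TSV
#'
#' Columns: verb, sem, syn, mapping (the `ROLE > SLOT#...` notation).
#'
#' @param links list of `lf_framelink` objects.
#' @param path file path.
#' @export
write_links <- function(links, path) {
  df <- data.frame(
    verb = vapply(links, `[[`, character(1), "verb"),
    sem = vapply(links, function(l) format(l$sem), character(1)),
    syn = vapply(links, `[[`, character(1), "syn_pattern"),
    mapping = vapply(links, format, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
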