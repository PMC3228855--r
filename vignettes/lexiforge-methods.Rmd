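---
title: "Building and applying a biomedical lexicon: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and applying a biomedical lexicon: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexiforge)
```

## The problem

Biomedical concepts appear in the literature under many written forms:
spelling variants (*tumour* / *tumor*), hyphenation and case variants
(*NF-KB* / *NF-kb*), acronyms (*Interleukin-2* / *IL-2*), and outright
synonyms. A text-mining system that wants to resolve any of these forms to a
stable database identifier (e.g. a UniProt accession) needs (a) a dictionary
of known forms clustered by accession, and (b) a way of mapping newly mined
forms onto those clusters. At the same time, extracting *events* — who
activated what, where, under which conditions — requires knowing how
individual verbs behave: which grammatical arguments they take, which
semantic roles those arguments play, and how the two levels line up.

`lexiforge` implements both halves: term normalization and mapping on the
noun side, and grammatical/semantic frame acquisition with argument-level
linking on the verb side, plus the two downstream applications (dictionary
tagging and frame-filtered fact extraction) and an XML interchange
serialization of the resulting lexicon.

## Term normalization

A **normalization rule** is a deterministic, idempotent string rewrite. Four
kinds are supported: case folding, character-class deletion (dashes,
punctuation, spaces, whitespace collapse), bounded fixed-substring rewrites
(e.g. `our -> or`), and alphabetical token sorting. All comparisons operate
on NFC-normalized text, since Greek letters and typographic dashes are
common in gene names. Substring rewrites are applied to a fixed point, which
makes every rule idempotent even when a single pass is not (e.g.
`aa -> a`).

Rule sets are scored against an accession-clustered dictionary with two
metrics:

* **variability** — the mean, over clusters, of the number of distinct
  normalized forms in the cluster; 1 iff every cluster collapses to one
  form;
* **ambiguity** — the mean, over distinct normalized forms, of the number
  of clusters containing that form; 1 iff no form is shared.

The published description of these metrics is verbal; the macro-averages
above are our operationalization of "average number of variant forms per
term" and "number of terms sharing identically spelled variants". Because a
rewrite can only merge forms, appending a rule never increases variability
and never decreases ambiguity — a property the test suite checks on random
dictionaries.

**Candidate generation** diffs pairs of terms inside the same cluster: a
case-only difference proposes case folding; a difference explained by
deleting one character class proposes that deletion; any other difference
with a middle of at most 3 characters proposes a substring rewrite built
from the differing middle plus one character of context on each side (so
*tumour*/*tumor* proposes `our -> or` rather than a context-free deletion of
`u`). Pairs that differ in case *and* something else still support the case
fold, since induced rule sets apply it first.

**Induction** is greedy: at each step the candidate maximizing
`Δvariability_reduction − λ·Δambiguity_increase` is appended, stopping at
`k_max` rules (default 1000, matching the scale at which such rule sets are
generated in practice; far fewer are needed at fixture scale) or when no
candidate scores above zero. λ defaults to 1 — the published account asks
for maximal variability reduction "while increasing ambiguity as little as
possible" without naming a trade-off constant, so equal weighting is the
neutral choice, and it is exposed as a parameter. Ties break on higher
supporting-pair count, then on the lexicographic rule representation, making
induction fully deterministic. Token sorting is excluded from induction by
default: it is aggressive (it would merge any permuted multiword names) and
is only worth enabling for dictionaries rich in structural variants.

## The inverse index and term mapping

With about 2 M dictionary names and tens of millions of mined candidates, a
pairwise similarity computation is on the order of 10^13 comparisons; the
inverse index reduces this to one normalization plus one lookup per
candidate. `build_inverse_index()` maps every dictionary term's normalized
form to the accessions whose clusters contain it, and records the identity
of the rule set so `map_term()` can refuse a mismatched one.

Mapping applies, in order: the recognizer-probability filter (strictly
greater than 0.99 by default — a candidate at exactly 0.99 is rejected), the
index lookup (no hit: `unmapped`), and the ambiguity guard (more than 10
accessions: `discarded_ambiguous`). Mapped candidates hitting two or more
accessions are flagged potentially polysemous; resolving polysemy is out of
scope, the flag is metadata.

**Soft string similarity** is the mean of character-bigram Dice and
whitespace-token Jaccard, computed on NFC-normalized, case-folded strings.
No formula is published for the soft matcher; this pair covers both
character-level variation (bigrams) and word-order/structure variation
(tokens). Case folding is deliberate: the measure must rank `HURP` closer to
`Hurp` than a long spelled-out name is, so similarity is 1 exactly when two
strings are equal up to Unicode normalization and case. Sub-clustering is
single-linkage at threshold 0.8; the confidence score attached to a mapped
variant is its best similarity to a dictionary term sharing its normalized
form. When several sub-clusters tie, the variant keeps all memberships above
threshold rather than guessing one.

## Grammatical frames

Input is a parsed corpus of predicate–argument records, one per verb
instance, with *logical* slot labels: `ARG1` is the logical subject and
`ARG2` the logical object, so actives and passives of one event share a
frame — this is what lets a single frame `ARG1#ARG2#PP-in` account for both
"X controls Y in E. coli" and "Y is controlled by X in E. coli". Running the
deep parser itself is out of scope; its output format is the interface.

Canonical order within a frame is: `ARG1 ARG2 ARG3`, then `THAT-CL`
`TO-INF`, then PP slots alphabetically by preposition, then `ADV`. The
published account says frames are order-normalized but not how; alphabetical
PP order makes the `#`-joined serialization injective and stable. Repeated
PPs with the same preposition collapse to one slot with recorded
multiplicity.

`estimate_frames()` computes `P(pattern | verb)` by relative frequency and
retains patterns at or above the threshold — the published threshold is
written `>= 0.03`, so the boundary case is kept. Per-verb probabilities are
reported pre-filter and sum to 1. Each frame also records its support, its
own passive percentage, and the verb's overall passive percentage. A
`min_support` parameter (default 1) is an extension beyond the published
procedure, guarding against single-observation frames on tiny corpora.

Per-slot association uses the likelihood-ratio statistic
G² = 2·Σ O·ln(O/E) over the 2×2 table crossing the verb against all other
verbs by slot presence — the de-facto corpus-linguistics association
statistic, adopted because the source names "log likelihood" without a
formula. Zero cells contribute zero; degenerate margins yield 0 with a
warning. It is computed per (verb, slot); a per-filler variant was
considered and rejected as under-determined by the source.

## Semantic frames and linking

Events are annotated with a closed inventory of 13 verb-independent roles
(AGENT, THEME, MANNER, INSTRUMENT, LOCATION, SOURCE, DESTINATION, TEMPORAL,
CONDITION, RATE, DESCRIPTIVE-AGENT, DESCRIPTIVE-THEME, PURPOSE) and NE
fillers resolving to five top-level classes (DNA, PROTEIN, EXPERIMENTAL,
ORGANISMS, PROCESSES; subtypes such as PROMOTER resolve upward).
`extract_sem_frames()` groups events by verb, role pattern and filler
pattern with support counts; nominalized triggers (e.g. *regulation*)
contribute to their base verb's frames by default, since nominalized verbs
are linked to their verbal entries in the lexicon — keeping them separate is
available as an option.

Linking a semantic frame to a grammatical frame of the same verb uses:

1. **Prototypic realizations** — AGENT is typically the subject; INSTRUMENT
   a PP headed by *with/through/using/via/by*; PURPOSE an infinitival;
   SOURCE `PP-from`; DESTINATION `PP-to/into/towards`; LOCATION
   `PP-in/on/at`; and so on. Only a handful of these are published; the
   remaining roles received conservative PP classes and the whole table is
   a replaceable argument of `linking_rules()`.
2. **Hierarchies** — a total role order beginning AGENT > THEME (the full
   order beyond that is our choice: core roles, then circumstantials,
   descriptives last) and the grammatical order ARG1 > ARG2 > ARG3 >
   clausal > PPs > ADV, aligned left to right.

The algorithm: (1) roles claim uniquely-compatible prototypic slots in
hierarchy order; (2) roles with several compatible slots take the first by
grammatical order, and roles with none fall back to unclaimed *core* slots
left-to-right — the fallback is restricted to core slots because letting,
say, DESTINATION fall back onto a subject position would contradict every
published worked mapping; (3) leftovers on either side link to `0`. A final
repair re-pairs core-slot assignments so role order and slot order agree.
THEME's prototypic realization is ARG2 only; subject-THEMEs (unaccusatives
like *accumulate*) are reached through the core fallback.

Both directions of surplus are legitimate links (`0 > ARG1` for agentless
passives; `CONDITION > 0` for annotation beyond the parse). The published
linking was manual; `link_all()` automates the stated constraints and
*reports* rather than resolves genuine conflicts — defined as a role whose
prototypic slot was claimed by a role with an identical realization set
(e.g. the two descriptive roles competing for one `PP-as`), the one case
the hierarchy cannot justify.

## Applications

**Dictionary tagging** matches token n-grams against the lexicon's form
index, greedy leftmost-longest, case-sensitive with a case-folded fallback,
tagging matches `NN-BIOMED` so that multiword names like *met protooncogene
precursor* survive as units. The matching policy of the original tagger is
unpublished; leftmost-longest is the standard dictionary-tagger choice and
is verified against brute-force matching enumeration in the tests.

**Fact extraction** applies three filters to parsed instances: the verb must
be a lexicon verb; at least one argument must carry an NE; and the
instance's canonical pattern must match a stored frame. Frame matching is by
*subsumption* (frame slots ⊆ instance slots), not equality: stored PP slots
act as licensers and optionality is built into frames, so extra adjuncts
never block extraction while missing core slots do. When several frames
subsume an instance the largest wins, ties broken by probability. Roles are
assigned through the chosen frame's argument link — which is how an
intransitive parse of "codes for an XPC cDNA" still gets a THEME, from the
for-phrase. The filter report partitions lexicon-verb instances exactly into
facts, frame mismatches and NE-free instances.

## Synthetic data

The generators produce every input the toolkit consumes, as pure functions
of a seed: dictionaries with planted variant processes (case change, hyphen
toggling, Anglo-American spelling swaps, whitespace jitter, plus acronym
formation and token permutation, the last two flagged irrecoverable by
string rewrites), parsed corpora with planted per-verb pattern
distributions, passive rates and NE fillers, paired event annotations whose
fillers respect the prototypic realizations (so linking is exercised end to
end), and candidate sets mixing recoverable corruptions, sub-threshold
probabilities and junk strings.

Default study conditions are desk-scale: 50 concepts × 3 variants for the
dictionary (200 concepts in the rule-recovery setting), 4 gene-regulation
verbs with 500–2000 instances each (2000 where estimates are compared to
planted values, so that three binomial standard errors stay below the
tolerances used), and 30 events per verb. Base names mimic real gene-name
morphology (symbol stems, digits, Greek letters, hyphens, multiword heads)
so that induced rules face realistic character classes, and are constructed
to remain distinguishable after full normalization, so planted ambiguity is
controlled by the injection rate alone.

What the fixtures do *not* emulate: real corpora have heavy-tailed verb and
pattern distributions, parser errors, nested and discontinuous names,
genuine cross-species polysemy, and annotation disagreement. Passing tests
therefore demonstrate the correctness of the machinery under known
conditions — recovery of planted truth, conservation and determinism
properties, exact reproduction of the worked examples — not performance on
MEDLINE-scale data.

## Numerical and degenerate-input choices

* Empty rule sets are valid (normalization is then NFC only); an empty
  dictionary is an error for metrics, and a verb with no instances is an
  error for passive rates.
* Probabilities at filter boundaries: the candidate filter is strict
  (`> 0.99`); the frame filter is inclusive (`>= 0.03`). Both follow the
  published wording.
* G² returns 0 with a warning on degenerate margins rather than NaN.
* All ties anywhere (rule induction, frame choice, linking) break
  deterministically, so identical inputs give identical outputs.

## Limitations

The toolkit consumes parser and annotation output; it does not parse, tag
named entities, or label roles in raw text. The relational database of the
original resource is represented only by the atomic staged-load contract
and flat TSV exports. No attempt is made to reproduce the released
resource's content or counts, which depend on external databases and
corpora.
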