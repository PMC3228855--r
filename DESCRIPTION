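Package: lexiforge
Title: Building and Applying a Biomedical Computational Lexicon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing, representing and applying a large-scale
    biomedical lexicon. Induces deterministic term-normalization rules from
    accession-clustered synonym dictionaries and maps text-mined term variants
    to database accession numbers through an inverse index; acquires
    grammatical (subcategorization) frames for domain verbs from
    predicate-argument parse records and semantic event frames from
    role-annotated corpora; links the two frame inventories at argument level;
    and applies the resulting lexicon for dictionary-based tagging and
    frame-filtered fact extraction. Includes seeded synthetic-data generators
    for every input format, an XML interchange serialization of the lexicon,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
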