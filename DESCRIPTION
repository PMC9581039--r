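Package: tandemscan
Title: Tandem Repeat Detection and Evolutionary Realignment with Circular
    Profile Hidden Markov Models
Version: 1.0.0
Authors@R:
    person("Matthias", "Keller", email = "tandemscan@posteo.net",
           role = c("aut", "cre"))
Description: Detects and segments tandem repeats in protein and DNA
    sequences with circular profile hidden Markov models (cpHMMs). A
    linear profile HMM is built from an alignment of repeat units (or
    ingested from a HMMER3 text profile) and circularized so that a
    single model pass can emit arbitrarily many adjacent units, entering
    and leaving the repeat at any match position. Hits are scored by
    Viterbi and forward log-odds against a random-sequence null,
    evaluated for unit homology with a likelihood-ratio test under a
    star-tree substitution model, and de-duplicated by overlap
    filtering. Detected units can be realigned under the Poisson Indel
    Process (progressive PIP) with guide-tree inference and indel-rate
    estimation, enabling iterative refinement of the cpHMM. A simulator
    generates repeat-bearing sequences with known unit boundaries,
    divergence and indels for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
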