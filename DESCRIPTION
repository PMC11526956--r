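Package: nflevo
Title: Evolution of Negative Feedback Loops in Immune Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulator of host-pathogen coevolution for a
    minimal immune signaling network. Hosts carry five signaling proteins
    (receptor, activator, immunity, upstream and downstream regulators)
    encoded as bit-string genotypes whose Hamming distances set signed
    interaction coefficients; within-host signaling follows a bounded ODE
    system integrated over the host lifetime; populations evolve under
    Wright-Fisher-style fitness-proportional selection with sexual host
    reproduction (per-protein recombination) and asexual pathogen
    reproduction. Includes a consensus-sequence ka/ks (omega) estimator of
    per-domain evolutionary rates and a classifier that calls which
    regulators evolved as negative feedback loops. The generational loop is
    compiled (Rcpp) with pure-R reference implementations of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
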