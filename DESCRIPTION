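Package: keeper
Title: Knowledge-Enhanced Electronic Profile Review for Phenotype Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts a patient's standardized structured electronic health
    record data (OMOP Common Data Model tables) into a compact, clinically
    organized profile for phenotype evaluation, as an interpretable and
    scalable alternative to manual chart review. Resolves hierarchy-based
    concept sets against a concept-ancestor vocabulary, applies temporal
    windows anchored on a cohort index date, rolls drug exposures up to the
    ingredient level with days supply, and classifies laboratory values
    against reference ranges. Includes the full evaluation apparatus for
    comparing profile review against chart review: two-period two-sequence
    crossover assignment, percent agreement, Cohen's and Fleiss's kappa with
    confidence intervals, accuracy against a gold standard,
    Cochran-Mantel-Haenszel and Fisher exact comparisons, and review-time
    t-tests. A synthetic CDM generator with planted phenotype signatures and
    simulated reviewers makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
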