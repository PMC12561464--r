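Package: reboatree
Title: Interpretable Policy Trees for REBOA Prescription in Blunt Trauma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns interpretable binary policy trees that prescribe resuscitative
    endovascular balloon occlusion of the aorta (REBOA) versus no REBOA for
    hemodynamically unstable blunt-trauma patients so as to minimize 24-hour
    mortality, and evaluates the learned policy with doubly-robust off-policy
    estimates of absolute risk reduction overall, by observed treatment group,
    and by terminal leaf. Includes trauma-registry style cohort filters with an
    auditable attrition log, k-nearest-neighbour imputation, cross-fitted
    random-forest propensity and outcome models, a greedy tree optimizer with
    local search and an exhaustive small-instance oracle, descriptive group
    comparison tables, and a synthetic blunt-trauma hemorrhagic-shock cohort
    generator with known treatment-effect ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
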