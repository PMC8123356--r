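Package: lbassign
Title: Learning-Based Assignment of Patients to Medical Professionals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for learning online patient-to-professional assignment
    policies from offline-optimal schedules. Small scheduling scenarios are
    solved to optimality (an exact dynamic program for emergency-department
    patient-physician matching with preemption; Monte-Carlo tree search for
    radiology study-to-reader exposure under probabilistic reader choice),
    the optimal decisions are distilled into pairwise preference data, and an
    anti-symmetric shared-weight neural comparator is trained on the pairs and
    deployed as an online policy (majority-vote selection, ordered-pool
    insertion). Includes scenario generators, baseline heuristics
    (first-come-first-served with urgencies; interval-based exposure), an
    event-driven shift simulator with a five-component objective, exponential
    lateness loss evaluation, and a reproducible experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
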