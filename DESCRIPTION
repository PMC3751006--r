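Package: dmprevent
Title: Decision-Tree Markov Microsimulation of Diabetes Screening and
    Lifestyle Intervention Economics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hybrid decision-tree plus annual-cycle Markov microsimulation
    for evaluating one-off population screening for undiagnosed diabetes and
    impaired glucose tolerance (IGT) followed by six-year lifestyle
    interventions (diet, exercise, or both) in IGT subjects, against
    screening alone and no screening.  Simulates individual trajectories
    over eight health states with six IGT tunnel states and life-table
    competing mortality, and reports remaining survival years, discounted
    quality-adjusted life years and societal costs, cost savings, time
    gained before diabetes onset and complications, one-way sensitivity
    analyses, and Wilcoxon rank-sum comparisons between strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
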