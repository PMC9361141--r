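Package: promptsleep
Title: Sleep Diary Analytics, Sleep-Restriction Titration, Prompt
    Scheduling, and Trial Machinery for a Digital Brief Insomnia
    Intervention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the computational core of a smartphone-delivered
    brief behavioral therapy for insomnia and of the randomized trial
    that evaluates it. Computes sleep-diary variables (time in bed, total
    sleep time, sleep efficiency) with cross-midnight clock arithmetic,
    titrates a sleep-restriction schedule from weekly sleep efficiency,
    selects and schedules personalized prompt messages from a rule-based
    catalog, scores the Insomnia Severity Index, Chalder Fatigue Scale,
    WHO-HPQ presenteeism measures, and PHQ-9 eligibility screen, and
    provides stratified permuted-block randomization, power and sample
    size calculation, CONSORT accounting, baseline contingency tests,
    and a random-intercept longitudinal model for weekly outcomes. A
    synthetic-cohort simulator generates virtual participants, diaries,
    and trial outcomes so the whole pipeline can be exercised and
    verified without any participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    withr,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
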