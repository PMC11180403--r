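Package: hpitrial
Title: Simulation and Analysis of Predictive-Alarm Hypotension Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying intraoperative hypotension management
    guided by a predictive alarm index versus reactive standard of care.
    Provides a seeded two-arm synthetic cohort generator (mean-reverting
    arterial-pressure dynamics, a predictive index proxy, protocolised
    treatment responses), threshold-excursion burden metrics (area under
    the threshold, duration, time-weighted average), alarm and hypotensive
    episode detection with 15-minute event merging, silent-alarm
    reconstruction and treatment-latency analytics, a configurable
    hemodynamic treatment-decision engine, and the trial statistics
    (Mann-Whitney, Hodges-Lehmann, summary t-tests, chi-square/Fisher with
    the expected-count rule, proportion-difference intervals, noncentral-t
    sample-size calculation) assembled into reproducible report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
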