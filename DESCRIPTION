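Package: cosinorsel
Title: Cosinor Analysis of Time-of-Day Effects with Selection-Effect Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a time-of-day effect observed in an
    always-available (online) study reflects a circadian rhythm or a
    self-selection process. Implements residualized single-component 24-hour
    cosinor regression (mesor, amplitude, acrophase, variance explained),
    joint sine/cosine interaction tests of rhythm moderation, per-age-year
    acrophase modelling with weighted linear summaries, and a benchmark that
    fits cosinors to fixed person-level variables (age, gender) which cannot
    have circadian rhythms, so that their apparent rhythmicity measures the
    strength of selection. Includes a seeded synthetic participant-record
    generator with controllable circadian and selection scenarios, timezone
    and daylight-saving handling for server-clock timestamps, and an
    end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
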