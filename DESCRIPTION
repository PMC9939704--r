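Package: safide
Title: Deterministic Saccade, Fixation and Blink Detection from Eye Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects saccade, fixation and blink periods from sampled eye
    traces recorded with video eye trackers, electrooculography (EOG) or
    scleral search coils. Candidate saccades are samples whose velocity or
    absolute acceleration reach thresholds suggested from the empirical
    cumulative distribution of the trace's own kinematics; blinks are found
    from pupillometry noise (video) or from their separation on the
    amplitude-duration main sequence (EOG); overshoots are merged back into
    their parent saccade and fixations are defined as the residual periods.
    The detector is fully deterministic. A synthetic free-viewing trace
    simulator with ground-truth annotations and an event-matching evaluator
    make the whole pipeline testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
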