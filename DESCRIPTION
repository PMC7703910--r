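Package: ehrmdetect
Title: Moving-Window Detection of Extra-Home Range Movements from GPS
    Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects extra-home range movements (EHRMs) -- temporary,
    long-distance excursions outside an animal's usual area of use -- from
    GPS relocation data.  Home ranges are estimated with Brownian bridge
    movement models and summarised as 95% utilization-distribution
    contours.  Two detectors are provided: the conventional Fixed-Period
    method, which screens relocations against a seasonal home range built
    from the whole season's data, and an iterative Moving-Window method
    that compares each day's relocations against the home range used over
    the immediately preceding period only, so that movements followed by
    range shifts are not masked by their own aftermath.  Also included
    are a registry of literature-derived EHRM definition criteria with a
    comparison engine, pairing and contrast of the two methods' outputs,
    and an Ornstein-Uhlenbeck trajectory simulator with plantable
    sallies, range shifts and dispersals for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
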