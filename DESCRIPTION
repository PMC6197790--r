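Package: riskplot
Title: Risk-Plot Mapping of Heart Rate Variability for ICU Mortality Risk Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converting single-lead ECG recordings into a beat-by-beat
    mortality-risk signal for intensive-care monitoring. The package detects R
    peaks (Pan-Tompkins style), derives the RR-interval (heart rate variability)
    series, and feeds it through a discrete "risk plot" state machine: each
    RR interval is projected as a token onto a binned stair, per-stair springs
    drain tokens at a fixed rate into a valley-of-life sink, and a stair whose
    occupancy reaches capacity becomes stuck. Window summaries of the dynamics
    (stair-occupation entropy, stuck time, drainage throughput) are combined
    into a bounded risk index with green/amber/red alarms. Includes notch and
    Daubechies-wavelet ECG preprocessing, WFDB/CSV/plain-text interval I/O, a
    ground-truth synthetic ECG and RR-interval generator for validation, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
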