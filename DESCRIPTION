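Package: fieldsync
Title: Simulation and Cross-Correlation Analysis of Paired Hippocampal
    Field-Potential Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates seeded, ground-truth-annotated synthetic CA3/CA1
    field-potential recordings that emulate pharmacologically defined
    epileptiform activity regimes (spontaneous discharges, discharge
    bursts, nonsynaptic population spikes, seizure-like activity, and
    latency-to-block drug effects), detects epileptiform events in field
    traces, quantifies CA3-CA1 synchronization as the first maximum of
    the Gaussian-low-pass-filtered, Lowess-smoothed cross-correlation
    function, and compares conditions with a Shapiro-Wilk-gated protocol
    (paired t or exact Wilcoxon signed-rank; Welch t or two-sample
    Kolmogorov-Smirnov).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
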