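Package: ecgmotif
Title: Personalized ECG Heartbeat Monitoring via Time-Series Motif Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Patient-specific classification of single-lead electrocardiogram
    (ECG) heartbeats by radius-constrained subsequence motif discovery. Each
    patient's recording is segmented into fixed-length pattern units; the top-k
    motif circles per beat class (normal N, ventricular V) are extracted from a
    training prefix under a similarity threshold r, and their central
    subsequences become the nodes of an artificial logical network that labels
    unseen beats by nearest motif, flagging beats outside every motif radius as
    anomalies. Includes two pooled (generalized) baseline training samplers, an
    (R, K, T) parameter-sweep evaluation harness with per-patient and
    cohort-average accuracy and distance-operation accounting, a seeded
    multi-patient synthetic ECG cohort generator, readers and writers for a CSV
    dialect and minimal WFDB-format records, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
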