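Package: idrproteo
Title: Disorder Profiling, Degron Scanning, FRAP Curve Fitting, and
    Spectral-Count Quantification for IDR-Driven Proteostasis Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how intrinsically disordered regions (IDRs)
    shape protein turnover and phase separation. Provides per-residue
    disorder profiling with maximal long-IDR segmentation and regional
    statistics; PEST-find scoring and APC/C degron (D-box, KEN-box) motif
    scanning; two-stage constrained fitting of fluorescence recovery after
    photobleaching (FRAP) traces with liquid/gel/solid material-state
    classification; and distributed-NSAF spectral-count quantification with
    target-decoy FDR filtering, protein parsimony, and bait-versus-mock
    enrichment. Seeded synthetic-data generators emulate each input type so
    the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
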