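Package: ablatrack
Title: Lesion Depth Tracking from All-Optical Ultrasound M-Mode Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring thermal ablation lesions with all-optical
    pulse-echo ultrasound. Simulates raw A-line sequences with a known
    surface position and lesion-depth trajectory, forms log-compressed
    M-mode envelope images (Butterworth band-pass, Hilbert envelope, log
    transform), segments the high-echogenicity ablation region with
    spatially regularised fuzzy c-means, traces per-frame lesion depth
    below the tissue surface, and compares paired depth measurements with
    a from-scratch two-tailed Wilcoxon signed-rank test (exact enumeration
    for small samples, tie-corrected normal approximation otherwise).
License: MIT
Encoding: UTF-8
Imports:
    signal,
    EBImage,
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
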