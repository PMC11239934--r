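Package: radmig
Title: Quantification of Radial Neuronal Migration and Subplate Reporter
    Dynamics in Cortical Slice Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying radial neuronal migration in embryonic
    cortical slice time-lapse movies: grid-based temporal Fourier
    quantification of bioluminescent signaling-reporter activity with
    cosmic-ray spike correction and subplate-row selection, cell detection
    and nearest-neighbour track linking with radial migration-velocity
    estimation, multipolar/bipolar morphology classification from cell
    masks, laminar BIN-distribution scoring of labeled neurons, zone-wise
    zymography signal quantification, and a ground-truthed synthetic-movie
    generator that makes every stage testable without external data.
    Summary statistics follow the conventions of the source experiments
    (mean +/- SEM, unpaired two-tailed t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    ggplot2,
    rlang,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
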