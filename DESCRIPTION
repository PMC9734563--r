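Package: aerotest
Title: Virtual Aerosol Room Experiments and Mask Efficacy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A software-only toolkit for designing, simulating and analysing
    aerosol countermeasure experiments of the kind used to assess face mask
    filtration efficacy in closed rooms. Provides a declarative experiment
    protocol engine with a 6-second sampling loop, a well-mixed virtual
    aerosol room with simulated laser aerosol spectrometers (size-binned
    counts, PM2.5/PM10 mass conversion, per-donning mask fit variation,
    Poisson counting noise), CSV run logging and replay, the analysis layer
    (mask efficacy with bootstrap confidence intervals, median-ratio
    instrument cross-calibration, exponential purifier-decay and linear
    background-rise model fitting, repetition statistics, paired condition
    comparison), and a laser-sheet image-processing chain (still-frame
    subtraction with Canny edge overlay) with a synthetic frame generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    data.table,
    minpack.lm,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
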