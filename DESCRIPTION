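Package: msidda
Title: Annotation and Ion Imaging for Data-Dependent Acquisition Mass
    Spectrometry Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for MALDI mass spectrometry imaging runs acquired with
    data-dependent acquisition (DDA). Reads centroided mzML scan streams and
    stage position/laser logs, maps scans onto the raster pixel grid, applies
    a two-criterion quality filter to MS2 spectra (laser activity and
    precursor consistency at ppm tolerance), annotates valid spectra against
    MS2 spectral libraries via adduct-resolved neutral-mass hypotheses,
    ppm exact-mass matching and cosine similarity with best-hit retention,
    and reconstructs per-pixel total-ion and extracted-ion images with
    optional TIC normalization. Includes a DDA instrument simulator
    (phantom tissue, matrix background, TopN cycles, dynamic exclusion,
    exclusion lists) that emits mzML, position logs, libraries and ground
    truth so every pipeline stage can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    mzR,
    xml2,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: MassSpectrometry, ImagingMassSpectrometry, Metabolomics,
    Software
RoxygenNote: 7.3.3
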