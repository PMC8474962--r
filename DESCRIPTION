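Package: petmrq
Title: Quantitative Preclinical PET and MRI Tumor Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of small-animal tumor imaging studies
    combining dynamic FDG-PET and MRI. Provides ADC parametric mapping from
    diffusion-weighted MRI, anatomic tumor volumetry, SUV scaling and static
    metabolic metrics (SUVmax/mean, MTV, TLG) under isocontour and fixed-
    threshold segmentation rules, Patlak graphical analysis of dynamic PET
    with an image-derived input function from the vena cava yielding the
    metabolic rate of FDG, nuclei counting for histological cell density,
    and exact small-sample cohort statistics. Includes digital 4D phantom
    generators with known ground truth (tri-exponential bolus input,
    irreversible two-tissue-compartment kinetics, Rician DWI noise,
    count-based PET noise) for end-to-end validation, plus a reproducible
    pipeline that runs phantom generation, per-scan quantification, cohort
    assembly and statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
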