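Package: censis
Title: Vowel Centering and Speaking-Induced Suppression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studies of the speech detection-correction
    circuit: vowel-formant centering metrics on the mel scale (windowed
    formant summaries, distances to per-vowel medians, center/peripheral
    trial partitions, variability, centering and its time-reversed control),
    speaking-induced suppression (SIS) of the M100 auditory evoked response
    from source-space epochs (functional ROI growth on a vertex graph,
    baseline z-scored RMS waveforms, peak detection, SIS fall-off, laterality
    indices), lesion percent-spared profiling of atlas regions from binary
    volumetric masks, and the study-level statistical layer (type-III mixed
    ANOVA with subject nested in group, Pearson/Spearman/partial
    correlations, t tests, pure-tone averages). Includes a synthetic cohort
    generator with known ground truth so every analysis stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
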