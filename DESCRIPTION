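Package: vasculm
Title: Ultrasound Localization Microscopy Analysis of Tumor Microvasculature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for super-resolution ultrasound localization
    microscopy (ULM) quantification of tumor microvasculature: spatiotemporal
    SVD clutter filtering of contrast-enhanced IQ ensembles with adaptive
    cutoff selection and depth-dependent noise equalization, Fourier-domain
    microbubble subset separation, normalized cross-correlation localization,
    trajectory linking with persistence filtering, super-resolved density and
    velocity maps, and downstream morphological read-outs (long-axis diameter,
    contrast power, blood volume, intervessel distance, tortuosity metrics,
    box-counting fractal dimension). Includes a synthetic-scene generator
    (branching vessel networks, recirculating microbubbles, low-rank tissue
    clutter, depth-dependent noise, diffusion-limited aggregation clusters),
    DAB immunohistochemistry H-score quantification, and cohort statistics
    (one-way ANOVA with Tukey HSD, longitudinal ANCOVA).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    EBImage,
    png,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
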