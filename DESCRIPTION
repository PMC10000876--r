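Package: odontomorph
Title: Tooth Crown Outline Morphometrics, Morphotype Statistics and 3D
    Crown Morphing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of tooth crown shape. Provides elliptic
    Fourier analysis of closed crown outlines (equal-arc-length resampling,
    harmonic decomposition, size/orientation/start-point normalization and
    outline reconstruction), principal component morphospaces with a
    rank-transformed two-group Wilks' lambda MANOVA, morphotype frequency
    and linear-measurement statistics (Student's t, variance F, Fisher's
    exact enrichment, differential-expression marking, delta-Ct
    quantification), synthetic generators for outlines, crown meshes,
    morphotype records and count matrices, and a landmark-guided 3D mesh
    morphing procedure that builds a dense source-to-target displacement
    field and transfers it onto a homologous crown surface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
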