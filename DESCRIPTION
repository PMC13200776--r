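Package: dfigrade
Title: Smartphone-Based Facial Palsy Grading with the Digital Facial Index
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Grades unilateral facial palsy from 3D facial-landmark
    recordings using the Digital Facial Index (DFI): per-region movement
    amplitudes are extracted after rigid head-motion removal, the affected
    hemiface is normalized against the contralateral side, and the three
    regional symmetry ratios are combined with a fixed 10/40/50
    forehead/eye/mouth weighting into a 0-100 percent score.  Includes
    conversion between the DFI and the Stennert Index, House-Brackmann
    Scale, and Sunnybrook Facial Grading System on a common standardized
    scale; scoring of the Facial Disability Index, System Usability Scale,
    and Likert questionnaires; an agreement-statistics battery (Spearman
    correlation, Bland-Altman limits of agreement, two-way mixed-model
    intraclass correlation, Cronbach alpha, normality-gated paired tests);
    and a synthetic-data simulator with planted palsy severities for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
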