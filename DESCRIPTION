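Package: cupcoverage
Title: Acetabular Cup Coverage Simulation for Severe Hip Dysplasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates placement of a 44-mm hemispherical acetabular cup in the
    small, shallow true acetabulum characteristic of Crowe type-IV developmental
    dysplasia of the hip, and quantifies host-bone coverage of the implant.
    Builds the anterior-pelvic-plane coordinate frame from bony landmarks,
    seats the cup by medialization under anterior-wall and transverse-ligament
    tangency rules at 45 degrees abduction and 20 degrees anteversion,
    classifies each facet of a thin measurement shell as covered or uncovered
    by bone, partitions the cup into anterior/posterior x superior/inferior
    quadrant segments, and reports total and segmental uncoverage ratios
    together with acetabular height, anterior-posterior diameter and a volume
    proxy. Includes a parametric synthetic hemipelvis generator with known
    ground-truth coverage for validation, and a cohort statistics stage
    (normality screening, Pearson correlation with simple linear regression,
    and two-group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
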