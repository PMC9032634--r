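Package: hegbayes
Title: Bayesian Compliance Testing for Occupational Exposure Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lognormal Bayesian exposure assessment for homogeneous exposure
    groups (HEGs) of workers, aimed at compliance testing against an
    occupational exposure limit (OEL). Fits a lognormal exposure model per
    HEG by Gibbs sampling over truncated full conditionals, under either a
    non-informative uniform prior or an informative normal/inverse-gamma
    prior elicited from historical monitoring data. Reports posterior
    geometric mean, geometric standard deviation and the 95th percentile
    with equal-tailed credible intervals, posterior probabilities of the
    four regulatory exposure-control categories, split-R-hat and bulk/tail
    effective-sample-size diagnostics, and the point-estimate P90 comparator
    used by the South African Mining Industry Code of Practice. Includes a
    synthetic-data generator that reproduces published summary statistics
    exactly, so the full pipeline runs without access to raw measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
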