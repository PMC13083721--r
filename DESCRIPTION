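Package: ubiqtree
Title: Uncertainty-Decomposed SHAP Explanations for Bagged Tree Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Turns point-estimate SHAP attributions from bagged tree
    ensembles into uncertainty-decomposed explanations. Trees are treated as
    competing hypotheses about feature attribution: out-of-bag performance
    defines a softmax base measure, Dirichlet draws over that measure yield
    accuracy-weighted sub-ensembles, and the resulting SHAP distributions are
    decomposed into aleatoric, epistemic, and entanglement variance
    components. A Dempster-Shafer layer reports belief, plausibility, and
    explanation conflict over a partition of the SHAP range, and an
    uncertainty-distribution layer provides differential entropy, sign
    stability, credible intervals, and data-acquisition rankings. Includes an
    exact brute-force Shapley oracle, a synthetic tabular data generator with
    known ground truth, and an end-to-end pipeline with report and figure
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite, ranger
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
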