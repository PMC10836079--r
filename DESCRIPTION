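Package: maxperm
Title: Multivariate Permutation Testing with Max-Statistic Correction and
    Bootstrapped Effect Sizes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resampling-based inferential statistics for multivariate data.
    Provides permutation tests based on the t-, F-, Z-, correlation and
    one-/two-way ANOVA statistics, with empirical p-values and confidence
    intervals taken from the permutation distribution, and strong family-wise
    error control via max-statistic (tmax) correction across variables.
    Standardised effect sizes (Cohen's d, Glass' delta, Cliff's d) and
    unstandardised measures are estimated with small-sample bias correction
    (Hedges' g) and percentile bootstrap confidence intervals using a
    dependence-preserving multivariate bootstrap. Includes a synthetic data
    generator for two-sample Gaussian-shift, equicorrelated-null and ordinal
    designs, tabular readers/writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
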