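Package: loadfit
Title: Mutational Load, Heterozygosity and Fitness in Small Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify expressed (homozygous) and masked (heterozygous)
    mutational load from impact-annotated multi-sample VCFs, compute per-class
    site-frequency spectra and genome-wide heterozygosity, and relate these to
    fitness traits (lifetime reproductive success, longevity, litter size,
    juvenile survival) with linear models, binomial GLMs, linear mixed models
    and non-parametric group tests. Includes zygosity-pattern screens for
    candidate loss-of-function variants, a Fisher-exact overrepresentation
    test, and a forward-in-time diploid population simulator with class-specific
    purifying selection and an admixture event, so the whole analysis can be
    exercised and validated on synthetic data at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    lme4,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
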