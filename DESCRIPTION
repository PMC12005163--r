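Package: mkodds
Title: Nested Likelihood-Ratio Testing of Nonsynonymous:Synonymous Odds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Likelihood-based extensions of the McDonald-Kreitman framework
    for comparing nonsynonymous:synonymous (N:S) odds of polymorphism and
    divergence across species and gene classes.  Per-gene variant counts
    (Dn, Ds, Pn, Ps) are modelled with a binomial likelihood in which a
    global baseline odds alpha is scaled by partition-specific modifiers
    beta; nested partition models are compared with likelihood-ratio tests,
    and between-species contrasts of the chi (divergence/polymorphism
    odds-ratio) and zeta (divergence odds-ratio) statistics are assessed
    with a stratified gene-wise bootstrap.  Also provides the weighted
    inverse neutrality index 1/NI_TG and a synthetic count-table generator
    for calibration, power studies and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
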