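Package: anaemiaCEA
Title: Cost-Effectiveness-Based Anaemia Reduction Targets for Women of
    Reproductive Age
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Country-level health-economic model for setting anaemia
    reduction targets among women of reproductive age (15-49 years).
    Four interventions (staple-food iron fortification, oral iron
    supplementation in pregnant and in non-pregnant women, and
    intermittent preventive treatment of malaria in pregnancy) are
    applied iteratively in order of increasing incremental
    cost-effectiveness ratio (ICER) until no remaining intervention is
    cost-effective against the country's willingness-to-pay threshold.
    Burden is measured in years lived with disability over a one-year
    horizon with no discounting and no anaemia-attributable mortality.
    Parameter uncertainty is propagated by Monte Carlo simulation and
    summarised as per-country and global median reductions with 95
    percent uncertainty intervals. A synthetic-world generator produces
    country profiles and intervention parameter tables with realistic
    structure so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
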