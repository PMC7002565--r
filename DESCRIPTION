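Package: paedpbpk
Title: Paediatric Physiologically Based Pharmacokinetic Simulation of
    Imatinib and CYP-Mediated Drug Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-body, perfusion-limited physiologically based
    pharmacokinetic (PBPK) modelling for imatinib with extrapolation to
    children and adolescents (2-18 years).  Provides in-vitro-to-in-vivo
    extrapolated hepatic clearance (recombinant CYP and human liver
    microsome kinetics, intersystem extrapolation factors, hepatobiliary
    transporter efflux), Rodgers-Rowland tissue partitioning for bases,
    age-driven ontogeny of CYP3A4/CYP2C8, alpha-1-acid glycoprotein and
    liver volume, mechanism-based CYP3A4 autoinhibition via an enzyme
    turnover model, a seeded virtual-population generator, virtual-trial
    simulation with non-compartmental analysis and body-surface-area dose
    banding against a trough-concentration target window, and dynamic
    drug-drug interaction prediction with CYP3A/CYP2C8 modulators
    (carbamazepine, ketoconazole, rifampicin).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
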