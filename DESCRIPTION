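Package: npradbio
Title: Compartmental Pharmacokinetics and DNA-Damage Modeling for
    Nanoparticle-Aided Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling gold-nanoparticle-aided radiotherapy:
    a whole-body first-order compartmental model of nanoparticle
    biodistribution in the mouse with simulation and transfer-rate fitting,
    a cellular binding/internalization compartment model, concentric-shell
    scoring of radial energy deposition with per-shell dose-enhancement
    ratios, DNA strand-break calling and double-strand-break complexity
    classification, DSB-based linear-quadratic cell-survival models with
    parameter fitting, radiosensitization enhancement factors, and seeded
    synthetic-data generators so the full pipeline runs without external
    Monte Carlo codes or animal data.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    withr,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
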