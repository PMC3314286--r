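Package: tgfsmad
Title: Dynamic Modeling of TIF1gamma-Regulated TGF-beta/Smad Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action ordinary-differential-equation models of canonical
    TGF-beta/Smad signal transduction under regulation by the nuclear factor
    TIF1gamma (TRIM33). A receptor-trafficking module and a Smad
    nucleocytoplasmic-shuttling module are merged through the endosomal
    ligand-receptor complex, and three mechanistic hypotheses for TIF1gamma
    action (pure repressor via Smad4 mono-ubiquitination, pure competition for
    phospho-Smad2, and an integrated transient-ternary-complex mechanism with
    FAM/USP9x-mediated Smad4 recycling) are built on the shared core. The
    package provides stiff integration under sustained, windowed, or pulsed
    ligand protocols with optional ligand depletion, TIF1gamma and kinetic
    one-at-a-time sensitivity scans, dose/duration response surfaces, an
    affine fit of transcriptional fold-change data against the predicted
    relative nuclear phospho-Smad2/Smad4 signal, a seeded synthetic-data
    generator emulating knockdown-recovery experiments, and SBML Level 3
    import/export of every model variant.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
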