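Package: ploopscan
Title: Geometric Annotation of Mg-NTP Catalytic Sites in P-loop NTPase Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and annotates nucleoside-triphosphate catalytic sites in
    crystal structures of P-loop fold NTPases in a near sequence-agnostic,
    purely geometric way. Locates bound NTP/NDP ligands and gamma-phosphate
    mimics (AlF4-, AlF3, MgF3-, BeF3, VO43-, Pi), identifies the Walker A
    lysine and its K+1 serine/threonine, the Walker B aspartate, the optional
    Switch I threonine and the apical catalytic water, resolves the octahedral
    Mg2+ coordination shell with the canonical ligand numbering, measures the
    catalytically diagnostic distances (Asp[WB]-Ser/Thr[K+1] hydrogen bond,
    HN[K-3] to gamma-phosphate, Mg2+ shell geometry), classifies hydrogen
    bonds, estimates the donor/acceptor pKa mismatch from bond length, computes
    Shrake-Rupley solvent accessibility of the Walker B aspartate, partitions
    sites into ligand classes and summarises distance distributions per class.
    Includes a synthetic catalytic-site generator with full ground-truth labels
    so the whole pipeline is testable without downloading structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
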