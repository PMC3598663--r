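Package: pcbDechlor
Title: Congener-Resolved Modeling of Microbial PCB Reductive Dechlorination
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for congener-resolved analysis of microbial reductive
    dechlorination of polychlorinated biphenyl (PCB) mixtures such as
    Aroclor 1260. Provides canonical PCB congener structures and naming,
    enumeration of all 209 congeners, chlorine-site classification
    (ortho/meta/para, flanking), declarative dechlorination process rule
    sets (Processes H, N, T and a doubly-flanked-meta/partial-ortho
    pattern), reaction-pathway DAG enumeration, mixture profile statistics
    (weight/mole percent conversion, homolog distributions, profile
    deltas, chlorine-release and growth-yield bookkeeping), first-order
    kinetic simulation of congener dynamics, classification of observed
    profile changes against candidate dechlorination processes, and a
    seeded generator of Aroclor-1260-like synthetic mixtures and noisy
    dechlorinated replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Matrix, igraph
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
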