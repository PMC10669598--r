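Package: glycodock
Title: Semi-Rigid Docking and Pose-Consistency Analysis for Sulfated
    Glycosaminoglycans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic-algorithm pose search for heparin/heparan-sulfate
    oligosaccharides against rigid cationic binding sites, with three
    glycosidic-torsion regimes (rigid, semi-rigid bounded histograms,
    fully flexible), bounded torsional probability histograms built from
    curated Phi/Psi observations, a pose-consistency metric triad
    (average, lowest and intra-pose RMSD), per-linkage torsional
    deviation profiles, a score-to-RMSD selectivity ratio, and a
    synthetic fixture generator producing idealized sulfated
    oligosaccharide chains and toy groove receptors with planted native
    poses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
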