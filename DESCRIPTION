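Package: ugtcap
Title: Predicting Glucuronidation Capacity of UGT1A1 Variants from Docking Poses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes molecular docking poses of UDP-glucuronosyltransferase
    1A1 (UGT1A1) variants to predict their glucuronidation capacity. Reads
    receptor and multi-model ligand structures (PDB/PDBQT), infers covalent
    connectivity, locates substrate hydroxyl groups and the glycosidic C-O bond
    midpoint of the coenzyme UDP-glucuronic acid, and classifies poses by a
    distance-threshold hydroxyl-orientation criterion. Fits a sigmoid capacity
    model linking the oriented-pose fraction to in vitro conjugation capacity by
    bounded multi-start nonlinear least squares, scales predictions by promoter
    (*28) genotype, and validates predictions by leave-one-out cross-validation
    with Pearson correlation statistics. Includes a synthetic-data generator
    producing pose fixtures with planted orientation labels and variant panels
    with known model constants, so the full pipeline is testable without
    docking software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    minpack.lm,
    ggplot2,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
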