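Package: nbescore
Title: Normalized Bond Energy Scoring for Small Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes the normalized bond energy (NBE) of small molecules:
    the sum of average bond energies (kJ/mol) over all bonds of a molecule,
    divided by its molecular weight (g/mol). Molecules are read from SDF
    (V2000) or SMILES, hydrogens are made explicit and aromatic systems
    kekulized before bond enumeration. Ships a curated table of average bond
    enthalpies at 298 K with support for user-supplied tables, batch scoring
    with an explicit policy for bonds missing from the table, the solubility
    and intestinal-absorption classification rules used in druggability
    screening, and the nonparametric statistics (Spearman correlation,
    Wilcoxon rank-sum, Welch t, one-way ANOVA) used to relate NBE to
    molecular property data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
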