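# nbescore

Normalized bond energy (NBE) scoring for small molecules, with the property
classification rules and group-comparison statistics used to relate the
score to druggability-related molecular properties.

Screening chemical small molecules for druggable potential relies on cheap
structure-derived descriptors (logP, pKa, polar surface area, ...). NBE is
such a descriptor built from bond strengths:

```
NBE = ( Σᵢ E(bondᵢ) ) / MW        [kJ/g]
```

the sum of average bond energies (kJ/mol) over all *n* bonds of the
molecule, divided by its molecular weight (g/mol, all atoms including
hydrogens). Normalizing by MW removes the trivial "bigger molecules have
more bonds" effect, leaving a per-mass measure of covalent framework
strength that tracks properties such as solubility class, melting point,
membrane permeability, blood–brain-barrier penetration and human intestinal
absorption across drug and metabolite collections. The package is for
cheminformaticians and medicinal chemists who want to compute NBE over SDF
or SMILES libraries, swap in their own bond-energy tables, and run the
associated statistics reproducibly.

What the package provides:

* **Bond-energy tables** — a shipped default of average bond enthalpies
  (298 K) covering H, C, N, O, S, P, Si and halogens; user tables in plain
  delimited text; symmetric, validated lookups where a missing bond is `NA`,
  never 0.
* **Molecule input** — multi-record SDF (V2000) and SMILES files via
  OpenBabel/ChemmineR, with explicit-hydrogen addition and kekulization so
  every enumerated bond has order 1, 2 or 3.
* **Scoring** — single and batch NBE with an explicit skip-or-error policy
  for bonds absent from the table, and per-molecule unmatched counts.
* **Statistics** — the solubility term lists, the 30% fraction-absorbed
  dichotomization, Spearman correlation (midranks), Welch/Student t,
  Mann–Whitney rank-sum, one-way ANOVA, and id-joined NBE-vs-property
  helpers.
* **Fixtures and simulation** — 13 hand-enumerated fixture molecules and a
  Gaussian-copula generator for property data with a controlled Spearman
  correlation and group shift.

## Worked example

```r
library(nbescore)

mols <- parse_smiles(text = c(
  "CC(=O)Oc1ccccc1C(=O)O aspirin",
  "CN1C=NC2=C1C(=O)N(C(=O)N2C)C caffeine",
  "CC(=O)Nc1ccc(O)cc1 paracetamol",
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O ibuprofen"))
batch_compute(mols)
#>            id     nbe total_bond_energy_kj_mol      mw n_bonds n_unmatched
#> 1     aspirin 52.7256                     9499 180.159      21           0
#> 2    caffeine 52.7617                    10246 194.194      25           0
#> 3 paracetamol 57.5001                     8692 151.165      20           0
#> 4   ibuprofen 67.3970                    13903 206.285      33           0
```

Aspirin's 21 bonds (7 C–H, 1 O–H, 5 C–C, 3 C=C, 2 C=O, 3 C–O) sum to
9499 kJ/mol; dividing by MW 180.159 g/mol gives 52.73 kJ/g. All four drugs
land in the 50–70 kJ/g range typical of approved small-molecule drugs.
`n_unmatched = 0` says every bond was found in the default table — a nonzero
count would flag bonds silently contributing nothing to the sum.

The statistics layer works on any property table joined by molecule id;
here, on synthetic data with a known rank correlation of −0.3 and a
4-unit group shift:

```r
set.seed(7); nbe <- rnorm(200, 55, 8)
d <- generate_property_data(nbe, rank_correlation_target = -0.3,
                            group_shift = 4, seed = 42)
spearman(nbe, d$property)
#> Spearman rank correlation: rho = -0.1982, p-value = 0.004914, n = 200

two_group_test(d$group_value[d$group == "b"], d$group_value[d$group == "a"],
               kind = "t_test", labels = c("b", "a"))
#> t_test_welch: statistic = 26.5720, p-value = 4.139e-67
#>   b: n = 100, mean = 3.8412
#>   a: n = 100, mean = -0.1799
```

The recovered rho (−0.20) sits within sampling error of the target at
n = 200, and the recovered group means differ by ≈ 4, the injected shift.

## Command line

A thin CLI over the same functions ships in `inst/cli/nbe.R`
(subcommands `compute`, `compare`, `correlate`, `table-validate`; exit codes
0 success / 2 usage / 3 input / 4 validation):

```sh
NBE_CLI=$(Rscript -e 'cat(system.file("cli", "nbe.R", package = "nbescore"))')
Rscript "$NBE_CLI" compute --smiles molecules.smi -o scores.tsv
Rscript "$NBE_CLI" correlate --results scores.tsv \
        --properties props.csv --property melting_point
```

Every run logs the bond-table `source_name`, so scores are always
attributable to the table that produced them.

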