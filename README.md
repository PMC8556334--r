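# bbbcurate

Tools for building a clean, deduplicated, provenance-annotated database of
molecular blood-brain-barrier (BBB) permeability from heterogeneous,
redundant, partially erroneous multi-source records.

Experimental BBB data comes in two forms: the numeric quantity

```
log BB = log10( C_brain / C_blood )
```

(the log-ratio of a compound's brain and blood concentrations) and a binary
label, **BBB+** / **BBB−**, thresholded on log BB (most commonly at −1).
Sources report the same compound under different names, salt forms,
protonation states and SMILES dialects, with values that agree, disagree
slightly, or are simply wrong. `bbbcurate` is for cheminformaticians and
ML practitioners who need that pool turned into a modelling-ready table
with an explicit reliability grade per compound.

The pipeline: **ingest** (schema-mapped CSV/XLSX, row-level rejects with
reasons) → **resolve** (pluggable compound-registry resolver: offline
table, persistent cache, or live PubChem) → **standardize** (whitespace
repair, salt stripping, charge neutralization, element filter,
canonical/isomeric SMILES + InChI via OpenBabel) → **merge** (byte-identical
InChI as identity; enantiomers stay distinct) → **curate** (consensus with
reliability groups A-D, below) → **extend & validate** (descriptors,
Rule-of-5 profiles, independent RDKit re-parse, multiplicity analytics).

Numeric consensus: per-instance outlier removal (log BB ≤ −9), discard of
molecules whose values span > 1 log unit, then grade **A** (one unique
value), **B** (all values within 5 % of their mean → mean), **C** (exactly
two distinct values → multiplicity-weighted mean), **D** (more than two →
modal value; modal tie discards). Categorical consensus: **A** (label
derived from curated numeric log BB at threshold −1), **B** (unanimous,
all thresholds explicitly −1), **C** (unanimous, threshold metadata
incomplete), **D** (majority under conflict; exact tie discards).

## Worked example

Generate a messy 80-molecule multi-source fixture with known ground truth,
run the full offline pipeline on it, and score recovery:

```r
library(bbbcurate)

gen <- generate_synthetic(synthetic_config(n_molecules = 80, seed = 42))
dir <- file.path(tempdir(), "fx"); write_synthetic(gen, dir)

sources <- lapply(names(gen$tables), function(s)
  list(path = file.path(dir, paste0(s, ".csv")), source_id = s,
       schema_map = gen$schema_map))
cfg <- run_config(sources, out_dir = file.path(tempdir(), "curated"),
                  resolver = resolver_offline(gen$resolver_table))
res <- run_pipeline(cfg)
#> collected 168 rows from 12 sources (168 accepted, 0 rejected)
#> resolved identities: 0 records still lack a structure
#> standardized structures: 168 accepted, 0 rejected
#> merged into 80 unique molecular identities
#> curated: 39 numeric records, 79 categorical records, 2 discards
#> extended with 8 descriptors (provider openbabel)
#> parse validity (rdkit): 1.0000 over 79 structures
```

The 168 raw records (some with whitespace-corrupted SMILES, salt or
charged forms, name-only or CID-only rows, injected outliers and label
conflicts) collapse to 80 unique identities; 39 get a consensus log BB and
79 a consensus label, with 2 molecules discarded for irreconcilable data.
Each curated row keeps its provenance and grade:

```r
head(res$numeric[, c("compound_name", "smiles", "logbb", "group", "reference")], 4)
#>   compound_name           smiles           logbb group reference
#> 1 nitrile homolog C9      CCCCCCCCCC#N     -1.41 A     S09
#> 2 methyl ether homolog C9 CCCCCCCCCOC      -0.56 A     S11
#> 3 naphthalene             c1ccc2c(c1)cccc2  0.69 A     S04
#> 4 acetonitrile            CC#N             -0.22 A     S08

score_recovery(res$numeric, res$categorical, gen$truth)[c("identity_merge", "label_recovery")]
#> $identity_merge
#> [1] 1
#> $label_recovery
#> [1] 1
```

Every molecule merged to exactly one identity and every curated group,
value and label matches what the rules demand — the expectation is
recomputed independently by the generator.

Real source tables are described in a YAML file (paths, per-source column
maps, resolver mode, thresholds, rule parameters) and run with
`run_pipeline(run_config_from_yaml("run.yaml"))`, or from a shell via the
thin CLI in `inst/cli/bbbcurate` (`run-all`, `fixtures`, `qc`
subcommands). Outputs are two curated CSVs in the published two-track
column layout (the numeric track omits the label and threshold columns),
descriptor-extended variants, rejects/discards ledgers with reasons, and a
JSON QC report.

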