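---
title: "Curating multi-source blood-brain-barrier permeability data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating multi-source blood-brain-barrier permeability data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Experimental blood-brain-barrier (BBB) permeability data is scattered over
dozens of publications and public datasets with incompatible layouts. Two
kinds of measurements circulate: the numeric quantity

$$\log BB = \log_{10} \frac{C_{\mathrm{brain}}}{C_{\mathrm{blood}}},$$

the log-ratio of a compound's brain and blood (plasma) concentrations, and a
binary label, BBB+ (permeable) or BBB− (non-permeable), that each source
derived from its own threshold on log BB (commonly −1, sometimes 0 or 0.1,
often unreported). The same compound may appear in twenty-odd sources under
different names, salt forms, protonation states, and SMILES dialects, with
values that may agree, disagree slightly, or be outright transcription
errors. Any machine-learning model trained on such a pool inherits all of
that noise.

`bbbcurate` turns this raw material into a clean, deduplicated,
provenance-annotated database in which every compound carries a consensus
value and/or label plus an explicit *reliability grade* (A-D), so that users
can trade dataset size against experimental certainty.

## The workflow

The pipeline runs in six stages; at every stage input count = output count +
rejected count, and rejects are values with reasons, never silent drops.

1. **Ingest.** Each source table (CSV or XLSX) is mapped onto a unified
   record schema by an explicit, per-source column map. Rows without any
   identity field (name, SMILES, CID), without any measurement, or with
   unparsable numeric cells land in a rejects ledger. Automated consistency
   checks (non-finite values, out-of-alphabet labels, duplicate rows within
   a source) are reported, not silently repaired.
2. **Resolve.** Records missing structure fields are completed through a
   compound-registry resolver (offline table, persistent cache, or live
   PubChem client behind a common interface). When a name matches several
   registry entries the first is used and the ambiguity is flagged in the
   output comment — never silently resolved.
3. **Standardize.** SMILES strings are repaired (whitespace, typographic
   dashes), parsed, desalted to the largest organic covalent fragment,
   charge-neutralized where chemically possible, filtered by element
   content, and canonicalized (isomeric form when stereo is present), with
   a standard InChI derived from the final structure.
4. **Merge.** The byte-identical InChI is the identity key: resonance and
   kekulization variants of one molecule collapse to one key, while
   enantiomers with explicit stereo stay distinct — stereochemistry matters
   for carrier-mediated transport across the barrier.
5. **Curate.** Per identity, the surviving values and labels are collapsed
   to a consensus with a reliability grade (next section).
6. **Extend and validate.** Curated tables are extended with molecular
   descriptors and Rule-of-5 profiles, and the whole output is re-checked:
   every SMILES is re-parsed with an *independent* toolkit (RDKit via a
   python subprocess, disjoint from the OpenBabel backend used for
   cleaning), and redundancy/multiplicity tables are cross-tabulated by
   group.

## The consensus rules

**Numeric track.** Values at or below −9 log units are physically
implausible (a concentration ratio below 10⁻⁹) and are removed per
instance. Molecules whose surviving values span more than 1 log unit are
irreconcilable and discarded whole. The rest are graded:

| group | condition | consensus value |
|---|---|---|
| A | one unique value | that value |
| B | several values, every one within 5 % of their mean | the mean |
| C | exactly two distinct values (failing B) | multiplicity-weighted mean |
| D | more than two distinct values (failing B) | modal value |

A tie for the mode discards the molecule. "Distinct" is judged after
rounding to 2 decimal places — the precision at which log BB is typically
reported — and the rounding is configurable.

**Categorical track.** Molecules with curated numeric data form group A;
their label is *derived* from the consensus log BB at the −1 threshold, and
conflicting source labels are noted in the comment but not used. Among the
label-only molecules: group B requires unanimous labels with every source
explicitly using the −1 threshold; group C is unanimous labels with
incomplete or non-standard threshold metadata; group D takes the majority
label under conflict, and an exact tie discards.

### Numerical choices and edge cases

* The 5 % band is implemented as $|v - \bar v| \le 0.05\,|\bar v|$ for every
  value $v$. When the mean is within $10^{-8}$ of zero a relative tolerance
  is undefined; group B then demands all values identical after rounding
  (which group A has already absorbed), so near-zero disagreeing value sets
  fall through to C/D. This is a deliberate decision for a degenerate case
  the rules do not address.
* The boundary value log BB = threshold is classified BBB+ (the `>=`
  convention). The convention is applied uniformly — the derived group-A
  labels and the synthetic generator's truth use the same rule.
* The outlier boundary is inclusive (−9.0 is dropped); the spread boundary
  is strict (a spread of exactly 1.0 is kept). Both cutoffs, the tolerance,
  the rounding, and the threshold are configuration, with these defaults.
* Group C's "weighted mean" weights each distinct value by its multiplicity
  among sources, which equals the plain mean of the raw value list; with no
  replicates it reduces to the unweighted mean.

## Standardization decisions

* **Stage order.** Desalting runs *before* the element filter and before
  neutralization. A sodium or calcium counterion must not doom an organic
  parent, and neutralizing before desalting would re-protonate an anion
  while the intact counterion still holds the opposite charge (the
  neutralizer operates per charge centre, not per record).
* **Element filter.** The default predicate rejects any atom with atomic
  number above 20 *or* any metal atom (Li, Be, Na, Mg, Al, K, Ca are the
  metals not already covered by the Z cutoff), and more than 7 boron atoms.
  The literal Z > 20 rule excludes bromine- and iodine-bearing drugs, which
  is chemically surprising but kept as the default; `max_z` is configurable
  for users who want to relax it.
* **Charges that cannot be neutralized** (quaternary ammonium and similar
  fixed cations) are kept, with a comment, rather than rejected — such
  drugs legitimately occur in permeability datasets.
* **Tautomers are not canonicalized.** InChI cannot resolve tautomeric
  forms; no tautomer normalizer is applied, so tautomer pairs drawn
  differently remain distinct identities. This is a known limitation.
* **Backend.** Canonical SMILES and InChI are produced by OpenBabel. The
  canonicalization contract is determinism and stereo preservation, not
  byte-agreement with any particular toolkit; identity comparisons are
  always within one backend. The independent re-parse in the QC stage
  deliberately uses a different toolkit (RDKit).

## Descriptors and the Rule of 5

The descriptor provider is pluggable. The default computes OpenBabel's
physicochemical block (MW, logP, TPSA, molar refractivity, hydrogen-bond
counts, ...) in-process; a `mordred` provider drives the full 2D set (1613
descriptors at version 1.1.1) through python when that module is installed,
and fails with an installation instruction otherwise. Per-molecule failures
become NA rows and never abort a batch.

Rule-of-5 profiling uses Lipinski's original counting convention: donors
are the hydrogens on N or O (an NH₂ counts twice), acceptors are the N and
O atoms themselves. Both patterns are configurable SMARTS for users who
prefer stricter pharmacophore definitions. log P comes from the backend's
atom-contribution estimator and the estimator name is recorded in the
profile metadata; published fractions computed with proprietary estimators
(e.g. ALOGPS) are not directly comparable and are not asserted anywhere in
the test suite.

## The synthetic generator: what it emulates, and what it does not

Real source heterogeneity cannot be redistributed, so the package ships a
generator that fabricates it with known ground truth:

* a built-in library of 50 hand-listed simple organics (with salt and
  charged variants for a dozen of them, and one enantiomer pair), extended
  programmatically with alkyl homolog series (alcohols, acids, amines,
  nitriles, thiols, ethers from chain length 5 upward) when more distinct
  structures are requested than the hand list holds;
* true log BB drawn from a normal mixture centred at 0.0 and −1.2 (sd 0.5
  each), which concentrates values on [−2, 2] and populates both label
  classes at the −1 threshold;
* per-molecule record counts from a truncated Poisson (mean 2, maximum 23);
* reported values = truth + Gaussian noise (default sd 0.02 log units),
  quantized to 2 decimals as sources typically report; outliers injected
  below −9 at a configurable rate; labels flipped at a configurable
  conflict rate; thresholds reported with configurable probability
  (default 0.6); about 30 % of records numeric by default, echoing the
  roughly 1:3 numeric-to-categorical ratio seen in the literature pool;
* structural corruption: whitespace insertion, salt forms, charged forms,
  and missing-field patterns (name-only and CID-only records) that force
  the resolver path.

The expected curation outcome for every molecule is recomputed inside the
generator from the generated records using `oracle_group()`, a literal,
independently coded restatement of the grouping rules. End-to-end recovery
is then scored against that expectation (exact) and against the true log BB
(statistical).

What passing these tests shows: the rules are implemented exactly, identity
resolution survives the modelled corruptions, and recovery degrades
gracefully with noise. What it does not show: robustness to real assay
chemistry, realistic structural diversity, or error modes outside the
corruption model (e.g. wrong-compound transcription, unit confusion).

Under the default noise model, a single-measurement molecule's reported
value lands within 0.05 log units of the truth about 98.7 % of the time
(|N(0, 0.02)| plus reporting quantization), so whole-dataset value recovery
at that tolerance sits near 99 %, varying by a point or so with the seed —
multi-source molecules recover better because their consensus averages the
noise.

## Problem sizes

The shipped test-suite and acceptance runs use 10,000 random value lists
for the rule-oracle comparison, the 50-molecule library for idempotence,
500 molecules for the clean-channel end-to-end run, 200 for the
noisy-channel run, and 150 for the fully corrupted run — sizes at which
every stage's behaviour is exercised (all reliability groups, all
corruption kinds, all resolver paths occur) while a complete run stays
within a couple of minutes on one CPU.

## Known limitations

* Name- and structure-only compounds that the registry cannot resolve are
  surfaced as rejects; no manual structure drawing is attempted.
* Tautomer ambiguity is inherited from InChI (see above).
* The Z > 20 default excludes halogenated drugs beyond chlorine; relax
  `max_z` deliberately if that is not what you want.
* The default descriptor block is compact; the full 2D set requires the
  optional python module.
* Published aggregate figures computed with estimators that are not freely
  scriptable cannot be reproduced bit-for-bit and are reported, when
  recounted, without asserting agreement.
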