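---
title: "Auditing the consistency of systematic chemical identifiers"
author: "molconsist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the consistency of systematic chemical identifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A record in a small-molecule database typically stores one structure
several times over: as a MOL connection table, a SMILES string, an InChI
string and an IUPAC name. These systematic identifiers are algorithmically
derivable from the structure and ought to be interchangeable; in practice
they drift apart as databases integrate data from different sources,
regenerate identifiers with different software, or standardise structures
with different rules. When a systematic identifier is used as a merge key
or a novelty-check index, such drift silently corrupts downstream work.

`molconsist` quantifies that drift. It takes the MOL block as the
reference representation of each record, converts every identifier channel
to a Standard InChI — the one identifier with a single canonical algorithm,
so string equality is structure equality — and reports percentage
agreement per channel. The same comparison is run across cross-reference
edges between two databases, where the linked records' MOL blocks should
encode the same structure.

## The comparison model

For record $r$ with channels $c \in \{\mathrm{smiles}, \mathrm{inchi},
\mathrm{iupac}\}$, let $I_{\mathrm{mol}}(r)$ and $I_c(r)$ be the Standard
InChIs derived from the MOL block and from channel $c$. A channel cell's
agreement under a standardisation variant $v$ is

$$ A_c(v) = 100 \cdot
   \frac{\#\{r : S_v(I_{\mathrm{mol}}(r)) = S_v(I_c(r))\}}
        {\#\{r : \text{both sides convert and standardise under } v\}} $$

Records where either side fails conversion or standardisation are excluded
from that cell's denominator — no comparison is done — but remain in the
conversion statistics, which are reported separately. The comparison is
exact string equality: there is no layer-wise partial credit, though a
read-only diagnostic (`diagnose = TRUE`) names the first differing InChI
layer of each mismatch as a curation aid.

## FICTS standardisation

$S_v$ applies up to five structure-level operators, named by the FICTS
scheme: **F**ragment (keep only the largest organic fragment), **I**sotope
(clear isotopic labels), **C**harge (neutralise protonation-state
charges), **T**automer (replace by a canonical tautomer), **S**tereo
(remove stereochemistry). A variant label lower-cases a position to "u"
when that aspect is standardised away: `FICTS` is the fully sensitive
baseline (the identity), `FICTu` compares structures ignoring
stereochemistry, `uuuuu` ignores all five aspects. Because every operator
merges equivalence classes and never splits them, agreement is
non-decreasing along nested variant chains — a property the test suite
asserts as a theorem rather than an observation.

Design choices that the operator definitions leave open were fixed as
follows:

* **Operator order** is F → I → C → T → S. Fragment stripping comes first
  so counterions cannot influence the charge and tautomer steps; stereo
  removal comes last because tautomer moves can create or destroy
  stereocentres.
* **"Largest fragment"** means most heavy atoms, with ties broken by the
  lexicographically smaller Standard InChI, which makes the operator
  deterministic without a salt dictionary.
* **Charge neutralisation** is proton-transfer only (carboxylates gain a
  proton, protonated amines lose one); permanent charges such as
  quaternary ammonium are retained, and no counterions are ever added.
* **Tautomer canonicalisation** uses RDKit's scoring-rule canonicaliser;
  the toolkit version is recorded in every report because canonical
  tautomer choice is implementation-defined and cross-toolkit agreement
  cannot be expected. If the enumeration cap is hit the structure passes
  through unchanged and the event is counted.
* **Standardisation operates on structures, not on InChI strings**: the
  input InChI is parsed, the structure edited, and the Standard InChI
  regenerated. The stereo rule is therefore verified by the absence of
  the `/t`, `/m`, `/s`, `/b` layers rather than implemented as layer
  deletion.

### A numerical subtlety: tautomer fixed points

Standard InChI performs its own mobile-hydrogen normalisation, so writing
a canonical tautomer to InChI and re-parsing it can hand a *different*
tautomer back; naively composing "canonicalise, regenerate InChI" is then
not idempotent (testosterone is a concrete offender). For variants that
include T, the implementation iterates the standardisation map until the
InChI stops changing, breaking the rare two-cycles deterministically by
the lexicographically smallest InChI. Idempotence of every variant over
the whole packaged library is an acceptance test, not an assumption.

## Conversion failure taxonomy

Every converter is total and deterministic: each input yields exactly one
of a Standard InChI or a failure class — `query_atom` (wildcard "R"/"*"
atoms, which denote structure classes and block identifier generation),
`parse_error` (including V3000 connection tables, which are out of
scope), `name_unresolvable`, `empty_structure`, `other`. IUPAC names are
resolved through a pluggable interface; the shipped resolver is a lookup
table over the fixture names, since full IUPAC nomenclature parsing is
explicitly out of scope. A crashing resolver is caught and surfaces as
failure class `other` without aborting the audit.

## The synthetic generator

Real database snapshots are versioned, unarchived downloads; their exact
inconsistency percentages are not reproducible at desk scale. The
generator instead builds paired snapshots with *known* inconsistencies so
the audit's recovery behaviour can be validated end-to-end:

* Records draw structures from a packaged library of 177 curated
  drug-like molecules (drugs, metabolites, amino acids, natural products)
  chosen to cover defined stereocentres, ionisable groups,
  tautomer-capable motifs and salt-formable acids and bases.
* Each record-channel independently draws one corruption class — stereo
  flip, alternative tautomer, appended salt fragment, (de)protonation,
  isotope label, wrong compound, unconvertible string — or stays clean.
  Classes are mutually exclusive per record-channel to keep recovery
  identifiable; compound corruptions would be a future extension.
* The generator is **self-verifying**: every emitted corruption is checked
  at generation time, against the same standardisation operators the
  audit uses, to mismatch at baseline, to be healed by exactly its own
  single u-rule, and by no other. A base molecule lacking the needed
  feature (no stereocentre, no distinct tautomer, ...) is resampled —
  never silently emitted clean under a corrupted label. Wrong-compound
  targets must differ even under `uuuuu`, which by monotonicity
  guarantees they differ under every variant.
* Cross-references link each A-record to its clean B-copy; a configurable
  fraction of single edges is retargeted to a structurally different
  compound, and a configurable fraction of compounds receives 2..`multiMax`
  edges of which exactly one is correct. The derived quantities (overall
  vs single-reference agreement, multiplicity mean/median) exercise the
  between-database report. The total edge count is derived from these
  two probabilities rather than set directly, since every record needs
  its partner edge for the audit to be meaningful.
* The IUPAC-name channel is emitted as opaque lookup keys together with a
  name table, so the name pathway is exercised without a nomenclature
  parser; unconvertible-name corruption is a key absent from the table.
* The spec's integer seed fully determines the output, byte for byte.

Default rates (stereo 0.10, tautomer 0.05, fragment/charge 0.02, isotope
0.01, wrong compound 0.02, unconvertible 0.01) emulate the error structure
observed in public databases, where stereochemistry discrepancies dominate
and tautomer discrepancies come second, with salt/charge/isotope issues
minor. What the generator deliberately does **not** emulate is the
chemical-space distribution of any real database, drawing errors
uniformly over a small curated library instead; passing tests therefore
demonstrate correctness of the audit machinery and recoverability of
injected error classes, not the inconsistency rates of any particular
resource.

## Problem sizes and test design

The validation suite runs the operator-idempotence check over the full
library under all 32 variants, the monotonicity theorem on a generated
database of 500 records, rate recovery on 1000 records (rates
0.15/0.10/0.05/0.05 with 99% binomial acceptance intervals around the
implied agreements of 65%, 80% and 95%), per-record class healing on 180
records, and oracle equivalence of the audit aggregation against a naive
counting loop on 50 independently generated 20-record databases. These
sizes give tight binomial intervals while keeping a complete run of the
suite in single-digit minutes on one CPU. `scripts/acceptance.R`
reproduces the headline numbers from scratch at the same sizes.

## Known limitations

* Chemistry primitives are delegated to RDKit (which embeds the IUPAC
  InChI code); a different toolkit would produce slightly different MOL
  parsing on edge cases and a different canonical tautomer, so absolute
  agreement values are toolkit-conditional. The toolkit version is
  recorded in every report.
* Charge neutralisation never adds counterions, so salts of permanently
  charged species do not neutralise to a literal parent acid/base pair.
* V3000 connection tables are rejected rather than parsed.
* The audit flags inconsistencies; adjudicating *which* channel is wrong
  is curation work outside its scope.
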