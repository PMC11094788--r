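---
title: "Curating reaction data: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating reaction data: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxncurate)
```

This vignette explains the science behind `rxncurate`: the role-assignment
model and its assumptions, the cleaning ladder and its tunable parameters,
what the synthetic fixtures do and do not emulate, and the numerical and
design choices made where the design was genuinely open.

## The role-assignment model

A reaction SMILES string has the shape `left>middle>right`, with
dot-separated molecule fragments on each side. Atom maps are integer
indices linking atoms across the arrow: `[CH3:1][OH:2]>>[CH3:1][Cl:3]`
says that carbon 1 of methanol persists into the product.

The model classifies every fragment into exactly one of four roles:

* **Product** — any right-side fragment. A right-side fragment with no
  mapped atoms at all is kept as a product: an unmapped by-product is
  still a product, and dropping it silently would hide multi-product
  reactions from the component filters.
* **Reactant** — a non-right fragment sharing at least one *heavy-atom*
  (non-hydrogen) map index with a product. Map indices sitting on
  hydrogens are ignored: hydrogen bookkeeping in SMILES is unreliable
  because hydrogens are usually implicit. Contribution overrides
  position: a fragment in the middle ("agent") segment that maps into a
  product is a reactant — the atom mapping is the chemically stronger
  signal than where the data depositor placed the molecule.
* **Molecular hydrogen exception** — H₂ on the non-product side is always
  a reactant. In a hydrogenation the hydrogens it contributes are
  implicit in the product SMILES, so the heavy-atom rule cannot see the
  contribution; without the exception every hydrogenation would file its
  key reagent under agents.
* **Spectator** — everything else, partitioned into **solvents**
  (membership in a solvent lexicon) and **agents** (all others:
  catalysts, reagents, ligands, acids, bases). We do not attempt a finer
  sub-classification; the same molecule plays different roles in
  different contexts, and that distinction is not recoverable from a
  single record.

One degenerate shape needs a policy: a molecule appearing unchanged on
both sides (identical map-stripped structure, maps only onto itself).
Classifying it as reactant *and* product would leak the prediction target
into the input, so the two instances collapse into a single agent entry.
If this empties the product side the reaction is rejected as product-free.

Two assumptions matter. First, the maps are trusted as given — the package
deliberately does not generate or repair atom mappings; a record without a
usable mapped string must use label-derived roles instead. Second, the
solvent lexicon is authoritative for the solvent/agent boundary: the
packaged list covers ~50 common laboratory solvents, and users with
domain-specific solvents should supply their own file.

## Canonicalization and name resolution

All stored SMILES are sanitized and canonicalized with OpenBabel, so one
molecule has one spelling and frequency counts and duplicate keys are
well-defined. Canonicalization is idempotent and stable under atom-order
rewrites; unparsable strings are flagged, never passed through.
Canonicalization is applied to map-stripped structures only — role logic
reads map indices directly off the raw reaction string, which avoids
needing a map-preserving canonical form altogether.

Molecule names are resolved by exact match (lower-cased,
whitespace-trimmed) against a name dictionary. No fuzzy matching: a fuzzy
resolver would silently convert "methylamine" ↔ "methanamine" correctly
but also invent matches for typo'd reagent names, and a wrong structure is
worse than a dropped record. Catalysts drawn with different ligand counts
are unified to one representative via an explicit variant table, applied
after resolution; the mapping is validated to be idempotent on load.

By default a reaction containing any unresolved component is dropped
whole (strict mode): a record that misidentifies one of its species is
evidence of transcription trouble in the record as a whole. The
alternative — dropping only the offending spectator — is available but
changes the reaction's condition fingerprint, so it is opt-in.

## The cleaning ladder

Steps run in a fixed order, each logged in the funnel audit:

1. **Component maxima** (reactants, then products, solvents, agents).
   Counting is by top-level dot-separated fragments, so `[Na+].[Cl-]`
   counts as two — a model consuming fixed component slots sees ions,
   not formula units. Limiting products to one filters out multi-step
   entries.
2. **No reactants/products.** Reactions lacking either side are
   meaningless for any of the three tasks.
3. **Yield sanitization** (optional, default off). Each yield and the
   yield sum must lie in 0–100 %. Violating reactions keep their row with
   yields set to missing rather than being dropped: yield noise should
   not shrink structure-only benchmarks. Units: percent.
4. **Deduplication.** The key is the sorted reactant/product/solvent/
   agent sets; temperature, time, yields, dates and procedure text are
   excluded. Patent data repeats the same transformation across filings
   with differing metadata; for structure-and-condition tasks those are
   the same reaction. First occurrence wins, so the pass is stable and
   idempotent.
5. **Frequency filtering** (condition recipe only). Spectators occurring
   fewer than `frequency_threshold` times are rare. The default
   threshold is 100 occurrences, counted once per occurrence on the
   post-deduplication set — a single pass, not an iterated fixpoint,
   because re-counting after deletions would cascade and silently shrink
   the set beyond the stated rule. Counts are kept separately per role
   (the same molecule as solvent and as agent feeds two different
   prediction targets). Two strategies: `delete_rxn` removes the whole
   reaction (rare conditions are plausibly mistranscriptions);
   `map_to_other` keeps it and replaces the rare molecule with the
   literal token `"other"`, preserving training signal at the cost of a
   catch-all class. The token is an ordinary literal during evaluation —
   under this strategy the model genuinely predicts the category.
6. **Grouped split.** Distinct grouping keys (the model-input tuple:
   sorted reactants + products for condition prediction, the source side
   for forward, the product for retrosynthesis) are shuffled with the
   configured seed and filled greedily into train/val/test to their
   target reaction counts (default 80/10/10). All reactions sharing a key
   land in one partition, so measured accuracy cannot be inflated by the
   same input appearing on both sides. In the one-reaction-per-group
   limit the greedy fill is exact to within two groups of the targets.
   We use the grouped split for all three recipes; a plain random split
   remains available by passing per-row unique keys.

## Benchmark recipes

| recipe | products | reactants | solvents | agents | frequency filter |
|--------|----------|-----------|----------|--------|------------------|
| condition | 1 | ≤2 | ≤2 | ≤3 | threshold 100 |
| forward | ≤2 | ≤3 | ≤3 | ≤3 | none |
| retro | 1 | ≤2 | — | — | none |

The condition recipe's five predicted slots (two solvents + three agents)
motivate both the per-role frequency counting and the multiset comparison
semantics below. The shipped default rare strategy is `delete_rxn`.

## Sequence formatting, augmentation, tokenization

Forward examples come in two modes: *mixed* (reactants, solvents and
agents dot-joined in random order) and *separated* (reactants `>`
spectators, solvents before agents, each block shuffled). An empty
spectator block keeps the trailing `>` so the positional contract stays
parseable. Augmentation doubles the set: each fragment is rewritten as a
random equivalent SMILES (OpenBabel, random start atom) and the molecule
order is re-randomized in the copy — re-randomizing, rather than reusing
the original order, maximizes the ordering diversity the augmentation
exists to provide. Every augmented fragment canonicalizes back to its
original's canonical form, so augmentation never changes the chemistry.

The tokenizer uses the de-facto reaction-transformer grammar — bracket
atoms, `Cl`/`Br`, `%nn` ring closures and `>` as single tokens, all other
characters one token each — and guarantees only the contract that matters
downstream: concatenating the tokens reproduces the string byte-exactly.

## Evaluation semantics

Condition targets are compared as **multisets of non-null slot entries**:
slot order and null placement never matter (the problem is a set
prediction), and duplicate molecules must match in multiplicity. Top-k
accuracy asks whether any of the first k beam entries matches; it is
monotone in k by construction. The frequency baseline predicts the k most
common train-set combinations for the requested component group, ties
broken lexicographically so results are reproducible.

AIB, the average improvement over baseline, is by default the normalized
gain `100·(A_m − A_b)/(100 − A_b)`: 0 at parity, 100 for a perfect model,
undefined at a saturated baseline (reported as missing). The convention
is a named, swappable policy (`"difference"` gives the raw gap) because
reasonable normalizations differ and a pinned-but-replaceable default
keeps reported numbers comparable.

Sequence predictions match when the canonical forms of their dot-fragment
multisets agree; the stereo-blind variant strips tetrahedral and
double-bond marks from both sides and re-canonicalizes, so it can only
merge equivalence classes — stereo-blind accuracy is never below
stereo-aware accuracy.

## What the fixtures emulate — and what they do not

The generator instantiates four template chemistries (Fischer
esterification, amide coupling, aryl cross-coupling, alkene
hydrogenation) over a grid of alkyl R-group lengths (1–12 carbons),
solvents and agents, with exact atom-map bookkeeping; configurations are
drawn without replacement while the grid lasts, so base reactions are
pairwise distinct and deduplication counts are exact by construction.
Noise channels mirror the failure modes of real patent data: agents
mislabeled as reactants, frequency-one reagents, duplicate filings,
impossible yields, missing atom maps, and components recorded as names.

The fixtures validate the *pipeline*, not chemistry at scale: they do not
reproduce the reaction-class distribution, the long-tailed spectator
vocabulary (tens of thousands of unique agents), stereochemistry-rich
substrates, or genuinely ambiguous mappings found in patent corpora.
Passing tests demonstrate that the curation logic implements its stated
contracts exactly; they do not certify model accuracy numbers on real
data, which additionally depend on corpus composition.

Default problem sizes in the test-suite and the acceptance script —
500–5,000 fixtures, 10,000 augmented examples, 5,000-example baseline
checks, 20 split seeds — were chosen as the smallest sizes at which every
property is measured well away from its sampling noise.

## Numerical choices and degenerate inputs

* Split fractions must sum to 1 within 1e-9; fewer distinct grouping keys
  than partitions is an error rather than a silent empty partition.
* A frequency threshold of 0 or 1 makes the filter the identity (no
  count can be below it); threshold 100 on a desk-scale input deletes
  everything under `delete_rxn` — the audit makes this visible rather
  than guarding against it.
* Malformed JSONL lines are quarantined to an error report (optionally a
  sidecar file) and never abort a run; patent-scale inputs always contain
  a few.
* Funnel audits enforce their declared size classes: shrinking steps may
  not grow the count, rare-to-"other" must preserve it exactly,
  augmentation must double it exactly.
* All randomness (splits, fixture generation, molecule-order shuffles,
  augmentation rewrites) flows through explicit integer seeds; identical
  seeds give byte-identical outputs.

## Known limitations

* OpenBabel's sanitization accepts some valence-inconsistent structures
  that stricter toolkits reject; the invalidity contract covers
  unparsable strings, not full chemical validation.
* No reaction balancing, tautomer canonicalization, salt stripping or
  functional-group standardization: structure normalization beyond
  sanitization is out of scope.
* Agents are one undifferentiated class; catalyst/reagent/ligand
  sub-roles are not predicted or evaluated.
* The name dictionary and catalyst-unification table are exact-match and
  necessarily incomplete; coverage of a new corpus requires extending
  them.
* Date-based (temporal) splits are not implemented; the grouped random
  split is the only leakage control offered.
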