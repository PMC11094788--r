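# rxncurate

Curation and benchmarking of chemical reaction data in R.

Large open collections of chemical reactions — above all the reactions
extracted from US patents — are a key training resource for machine-learning
models of forward prediction, single-step retrosynthesis and reaction
condition prediction. The raw records are noisy: reaction roles are
frequently mislabeled (reagents and solvents recorded as reactants),
molecules appear under names instead of structures, the same catalyst is
drawn with different ligand counts, yields fall outside 0–100 %, and the
same reaction is filed many times. `rxncurate` implements a curation
pipeline that turns such records into clean, ML-ready benchmark datasets,
plus the order-invariant metrics used to evaluate condition-prediction
models against a frequency-informed baseline.

## What it does

**Role assignment from atom maps.** Given an atom-mapped reaction SMILES
`reactants>agents>products`, a *reactant* is a molecule that contributes at
least one heavy (non-hydrogen) atom to a product — i.e. shares a heavy-atom
map index with the product side. Molecular hydrogen is an explicit
exception (its contribution is invisible because hydrogens are implicit in
SMILES), so H₂ on the left side is always a reactant. Every other molecule
is a *spectator*, split into *solvents* (members of a packaged ~50-entry
solvent lexicon) and *agents* (catalysts, reagents, ligands, acids and
bases collapsed into one class). Roles can alternatively be taken from the
record's labels, and the two provenances can be compared to quantify label
contamination.

**A cleaning ladder.** In funnel order: per-role component-count maxima
(a binary salt `[Na+].[Cl-]` counts as two components), removal of
reactions without reactants or products, optional yield sanitization
(each yield and the yield sum within 0–100 %; off by default), stable
deduplication on sorted component sets, and frequency filtering of rare
spectators (threshold 100 occurrences by default) under two strategies:
delete the whole reaction, or keep it and map the rare molecule to the
literal token `"other"`. Every run logs a funnel audit of reactions
remaining per step.

**Benchmark recipes.** Three shipped recipes: *condition* (1 product,
≤2 reactants, ≤2 solvents, ≤3 agents, frequency filtering), *forward*
(≤2 products, ≤3 each of reactants/solvents/agents, no frequency
filtering) and *retro* (1 product, ≤2 reactants, no frequency filtering),
each with a grouped 80/10/10 split that keeps every model input on one
side of the train/test boundary (zero leakage). Sequence-model exports
support mixed and `>`-separated forward inputs, random equivalent-SMILES
augmentation (exact doubling) and lossless SMILES tokenization.

**Evaluation.** Condition predictions are five-slot targets (two solvents,
three agents) compared as multisets — slot order and null padding never
matter. The package computes top-k exact-match combination accuracy per
component group, the frequency-informed baseline (predicting the k most
common train-set combinations), and the average improvement over baseline

```
AIB = 100 · (A_m − A_b) / (100 − A_b)
```

where `A_m` and `A_b` are the model and baseline exact-match combination
accuracies. Sequence predictions get invalid-SMILES rates and top-1
accuracy with and without stereochemistry.

**Synthetic fixtures.** A generator instantiates four template chemistries
(esterification, amide coupling, aryl cross-coupling, hydrogenation) with
exact atom-map bookkeeping and known ground-truth roles, plus controllable
noise channels (agent-as-reactant mislabeling, frequency-one rare agents,
duplicates, invalid yields, map stripping, name-only components), so the
whole pipeline is testable without downloading anything.

SMILES sanitization and canonicalization run through OpenBabel
(`ChemmineOB`); records travel as JSONL, datasets as Parquet or CSV.

## Worked example

```r
library(rxncurate)

fx <- generate_fixtures(fixture_spec(n_reactions = 200, seed = 1,
                                     duplicate_rate = 0.1))
roles <- assign_roles(fx$records, "rxn_string")
bench <- build_benchmark(roles, benchmark_recipe("condition",
                                                 frequency_threshold = 2))
bench$audit
#> <funnel_audit>
#>   full data set                220
#>   too many reactants           220
#>   too many products            220
#>   too many solvents            220
#>   too many agents              220
#>   no reactants/products        220
#>   dropping duplicates          200
#>   frequency filtering          200
```

The funnel reads top to bottom: 220 records enter (200 base + 20
duplicates), the component filters remove nothing (the fixtures respect
the condition maxima), deduplication removes the 20 repeats, and no
spectator falls below the threshold of 2 in this draw.

A predictor plugs in as one beam (a ranked tibble of five-slot condition
targets) per test example. Evaluating an oracle that always ranks the
true conditions first shows the metric layout — baseline top-3 accuracy,
model top-3 accuracy and AIB per component group:

```r
parts <- split_partitions(bench$data)
train <- condition_targets(parts$train)
test  <- condition_targets(parts$test)
beams <- lapply(seq_len(nrow(test)), function(i) test[i, ])  # oracle
m <- evaluate_condition_predictions(beams, test, train)
m
#> <condition_metrics> top-3 on 18 examples (baseline//model//AIB)
#>   solvents 50//100//100%
#>   agents   56//100//100%
#>   S + A    11//100//100%
```

The frequency-informed baseline alone already matches half the solvent
sets on this small draw, but only 11 % of full solvent+agent
combinations; the oracle's perfect accuracy gives AIB = 100 by
construction. `tidy(m)` returns the same numbers as a tibble and
`autoplot(m)` as a bar chart.

## Command line

A thin CLI over the package functions lives at `inst/cli/curate.R`
(after installation: `system.file("cli", "curate.R", package = "rxncurate")`):

```sh
Rscript curate.R gen-fixtures --n 500 --seed 1 --out fixtures.jsonl
Rscript curate.R extract --input fixtures.jsonl --roles rxn-string --out out/
Rscript curate.R build --input fixtures.jsonl --benchmark condition --out out/
```
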