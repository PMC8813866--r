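# dpfold

Component-based dynamic-programming engines for pseudoknot-free RNA
secondary structure prediction.

## The problem

A single-stranded RNA molecule folds back on itself: residues form
Watson–Crick (`G–C`, `A–U`) and wobble (`G–U`) base pairs, and the set of
pairs — the *secondary structure* — determines much of the molecule's
function. Classical prediction methods share one computational skeleton:
a triangular dynamic-programming table over subsequences `[i, j]`, filled
in increasing span order, followed by a traceback. They differ only in
the recurrence. `dpfold` makes that skeleton an explicit, audited engine
contract and plugs four classical strategies into it:

| strategy | objective | tables |
|---|---|---|
| `nussinov` | maximize the number of base pairs | `M` |
| `zuker` | minimize free energy over a loop decomposition | `W`, `V`, `WM` |
| `helix` | minimize total stem energy over a stem pool | `E` + stem pool |
| `partition` | Boltzmann ensemble: partition function `Q` and pair probabilities `P` | `Q`, `Qb` |

All four operate on the same structure space: every position pairs at
most once, pairs never cross (no pseudoknots), and every pair `(i, j)`
satisfies `j − i ≥ min_span` (default 4, i.e. at least 3 unpaired hairpin
bases). A structure emitted by any engine therefore validates under
`check_structure()`.

The core recurrences, in the field's standard notation (`θ(i,j) = 1` iff
residues `i`, `j` may pair and `j − i ≥ min_span`):

- **Maximum pairing** — `M(i,j) = max{ M(i+1,j); M(i,j−1);
  M(i+1,j−1) + θ(i,j); max_k M(i,k) + M(k+1,j) }`.
- **Minimum free energy** — `V(i,j)` (energy given `(i,j)` paired) is the
  minimum of a hairpin term, a stacking term `E_s + V(i+1,j−1)`, an
  interior/bulge term `min E_L + V(i′,j′)`, and a multibranch term built
  from an auxiliary table `WM`; `W(i,j)` relaxes over `V`, unpaired ends
  and bifurcations.
- **Helix-based** — enumerate every stem region `H(i,j,k)` (`k ≥ 3`
  stacked pairs) into a pool, then
  `E(i,j) = min{ 0 (window too small); energy(H) + E(i+k, j−k); E(i,k) +
  E(k+1,j) }`.
- **Partition function** — `Q(i,j) = Q(i,j−1) + Σ_k Q(i,k−1)·Qb(k,j)`,
  `Qb(k,j) = e^{−E_pair(k,j)/RT}·Q(k+1,j−1)`; base-pair probabilities by
  the standard outside completion; structure output by thresholding
  `P(i,j) > 0.5`.

Prediction accuracy is scored at base-pair level: sensitivity
`X = TP/(TP+FN)`, specificity `Y = TP/(TP+FP)`, the full Matthews
correlation coefficient, and its common simplification `MCC = √(X·Y)`.

## Worked example

```r
library(dpfold)

seq <- validate_sequence("GGGAAAACCC", id = "toy")
res <- predict_structure(seq, algorithm = "nussinov")
res
#> <prediction_result> toy | nussinov | score = 3 | 3 pair(s)
#>   (((....)))
```

The score `3` is the maximum number of base pairs; the dot-bracket line
shows the nested helix `(1,10), (2,9), (3,8)` closing a 4-base hairpin
loop. The same sequence under the energy-based engines:

```r
em <- toy_energy_model(hairpin = -1, stack = -1)
predict_structure(seq, "zuker", em = em)$score    # -3  (1 hairpin + 2 stacks)
predict_structure(seq, "helix", em = em)$score    # -2  (one 3-pair stem, 2 steps)

p <- predict_structure("GAAAC", "partition", em = toy_energy_model(pair_energy = 0))
p$q                    # 2     : the empty structure and {(1,5)}
p$probabilities[1, 5]  # 0.5   : (1,5) appears in 1 of 2 equally weighted structures
```

Comparing a prediction against a reference structure:

```r
ref  <- read_dotbracket("(((....)))")
pred <- secondary_structure(10, rbind(c(1, 10), c(2, 9)))
evaluate_structures(pred, ref, seq = seq)
#> name  n  X       Y       MCC_full  MCC_simple
#> toy   10 0.6667  1.0000  0.7559    0.8165
```

## Command line

```sh
exec/dpfold simulate --n 5 --length 60 --gc 0.5 --seed 7 --out sim.fasta
exec/dpfold predict  --in sim.fasta --algorithm zuker --format dotbracket --out pred.txt
exec/dpfold evaluate --pred a.ct --ref b.ct --format ct
```

Subcommands: `predict` (flags `--algorithm`, `--min-span`,
`--energy-params FILE` (JSON), `--min-stem-len`, `--pair-prob-threshold`,
`--dotplot`, `--format pairs|dotbracket|ct`, `--mode
pair_count|pair_intervals`, `--config FILE`), `evaluate`, `simulate`.
Illegal flag combinations (for example `--pair-prob-threshold` outside
partition mode) are rejected before any computation; identical inputs and
configuration give byte-identical outputs.

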