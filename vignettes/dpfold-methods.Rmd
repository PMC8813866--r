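---
title: "Models, parameters and design choices in dpfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in dpfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpfold)
```

# The structure space

All four folding engines in `dpfold` search one and the same space of
pseudoknot-free secondary structures over a sequence
$S = S_1 S_2 \dots S_n$, $S_i \in \{A, C, G, U\}$:

1. **unique pairing** — no position belongs to two pairs;
2. **nestedness** — for pairs $(i,j)$ and $(g,h)$, the patterns
   $i < g < j < h$ and $g < i < h < j$ are forbidden;
3. **hairpin span** — every pair satisfies $j - i \ge$ `min_span`.

The two common statements of rule 3 — "$|j-i| \ge 4$" and "the hairpin
loop must hold $\ge 4$ bases" — differ by one. `dpfold` enforces
$j - i \ge$ `min_span` with default `min_span = 4`, which leaves at least
3 unpaired hairpin bases; the other convention is reachable by setting
`min_span = 5`. The pairing alphabet defaults to Watson–Crick plus the
`GU` wobble, read as unordered and closed under symmetry. Ambiguity
codes (`N`, `R`, ...) are rejected rather than skipped: every engine's
semantics for an unknown residue would be arbitrary.

Chemistry and span are folded together into one indicator
$\theta(i,j)$ shared by all engines. The maximum-pairing recurrence as
usually printed does not carry the span rule inside its pairing case; we
put it there deliberately, otherwise a traceback could emit structures
the validator rejects and the four engines would search subtly different
spaces.

# The engine contract

Every strategy runs inside one generic engine (`dp_run()`): allocation
of upper-triangular tables with unset cells explicit (`NA`), a single
fill schedule over spans $d = j - i = 0, 1, \dots, n-1$, final-score
extraction from cell $(1, n)$, traceback, validation of the traced
structure, and a re-scoring check (the traced structure, scored
independently of the DP, must reproduce the final score exactly for
integer objectives and within $10^{-9}$ for energies). Reading an unset
cell is an error, not a silent `NA`, and with `audit = TRUE` the state
records an ordered cell-level read/write log; a property test replays
the log and confirms no strategy ever reads before writing.

The sentinel for "forbidden" cells is $+\infty$ for minimization — safe
under `min()` — while the partition tables, whose cells multiply, never
use an infinite sentinel at all (impossible pairings carry weight 0).

Tie-breaking in every traceback is fixed: recurrence cases are tried in
the order they are written above, then the smallest split point $k$.
Source annotations are not stored; tracebacks re-derive the achieving
case, which keeps the state small and makes the tie-break rule the
single source of determinism.

# The four recurrences

**Maximum pairing.** $M(i,j) = \max\{M(i{+}1,j);\; M(i,j{-}1);\;
M(i{+}1,j{-}1) + \theta(i,j);\; \max_k M(i,k) + M(k{+}1,j)\}$. The split
range is taken as $i \le k < j$; the endpoint $k = j$ sometimes seen in
print adds only an empty right interval and is dropped as provably
redundant.

**Minimum free energy.** $V(i,j)$, the optimum given $(i,j)$ paired, is
the minimum of four loop terms: hairpin $E_H(i,j)$; stack
$E_s + V(i{+}1,j{-}1)$; interior/bulge
$\min E_L(i,j;i',j') + V(i',j')$ over closings with
$(i'-i) + (j-j') > 2$ (excluding the stack case) and unpaired size at
most `max_interior_size` (default 30, the standard $O(n^3)$ cap; set
`Inf` for exactness — the oracle suites do); and a multibranch term.
The multibranch helper table is not defined in older presentations that
still use it; we implement the standard affine form
$WM(i,j) = \min\{WM(i,j{-}1)+c;\; WM(i{+}1,j)+c;\; V(i,j)+b;\;
\min_k WM(i,k) + WM(k{+}1,j)\}$ with
$E_4 = a + \min_k WM(i{+}1,k) + WM(k{+}1,j{-}1)$, so that at
$a=b=c=0$ the term collapses to the bare two-segment split over paired
content — the literal printed form — while realistic closing/branch/
unpaired penalties remain available. $W(i,i)=0$; short spans are
forbidden *for pairing* ($V = \infty$) but $W = 0$ there, because the
empty structure is always admissible; this resolves the apparent
conflict between a base case that zeroes the diagonal and a guard that
marks short spans infinite.

**Helix-based.** Stem regions $H(i,j,k)$ — $k \ge$ `min_stem_len`
consecutively stacked pairs $(i{+}t, j{-}t)$ whose innermost pair still
respects the span rule — are enumerated into an auxiliary stem pool with
energy equal to the sum of their $k-1$ stacking steps (helix initiation
terms are deliberately omitted; no published initiation table is
bundled). Then
$E(i,j) = \min\{0 \text{ when } j-i < b_0;\;
\text{energy}(H) + E(i{+}k, j{-}k);\; \min_k E(i,k) + E(k{+}1,j)\}$.
The base-case threshold is $b_0 = 2(\text{min\_stem\_len}-1) +
\text{min\_span}$, exactly 8 at the defaults — the smallest window
admitting a minimum-length helix around a legal hairpin — and
generalizes consistently when either knob moves.

One boundary repair was forced by testing: with the split range read
literally as $i < k < j$, a stem starting at $i+1$ and ending exactly at
$j$ can never be isolated (the single-base *left* flank needs $k = i$,
excluded, while the mirrored right-flank trim $k = j-1$ is admissible).
The brute-force stem-subset oracle found the counterexample
`UCGCACGGCUCGCG` within twenty random sequences. The split range is
therefore $i \le k < j$, which makes $E(1,n)$ provably equal to the
optimum over all non-crossing, base-disjoint placements of pool stems.

**Partition function.** The ensemble mode is *pair-level*: a structure's
energy is the sum of per-pair energies $E_{pair}$, and
$Q(i,j) = Q(i,j{-}1) + \sum_k Q(i,k{-}1)\, Q_b(k,j)$ with
$Q_b(k,j) = e^{-E_{pair}(k,j)/RT}\, Q(k{+}1,j{-}1)$. This is a
deliberate scope decision: a full loop-decomposition partition function
is a different (and much heavier) object, whereas the pair-level scheme
ranges over exactly the structure space defined above and is therefore
fully checkable against enumeration — with $E_{pair} \equiv 0$,
$Q(1,n)$ *is* the count of valid structures. Base-pair probabilities
come from the standard outside completion, decomposing by the pair
directly enclosing $(i,j)$. Structure output selects pairs with
$P(i,j) >$ `pair_prob_threshold` (default 0.5) greedily by decreasing
probability; above 0.5 at most one partner per base can qualify, so only
crossings can ever be skipped. MEA/centroid decoding and stochastic
sampling are out of scope.

*Numerics.* For $n > 300$ the tables are computed in a per-nucleotide
rescaled form $Q'(i,j) = Q(i,j)\, s^{\,j-i+1}$ with $s = 0.5$; the
recurrences are invariant under the substitution (each pair weight
absorbs $s^2$, each unpaired base one factor of $s$) and every
probability ratio cancels the scale exactly. The result object reports
`log_q` always and natural-scale `q` when representable.

# Energy parameters

No published nearest-neighbor table (Turner, INN-HB) is bundled — those
values are external data. The energy model is a contract
(`energy_model()`) with three interchangeable sources:

- `toy_energy_model()` — constants per loop class; the oracle suites run
  under these because exact brute-force re-scoring must be possible;
- `default_energy_model()` — a documented heuristic: stacking energy is
  minus the mean "bond strength" of the two stacked pairs (GC 3, AU 2,
  GU 1 kcal/mol), hairpins cost $4.5 + 1.75\,RT\ln(\text{size}/3)$,
  interior/bulge loops $1.5 + 1.1\,RT\ln(1+\text{size})$, multiloops
  $a{=}3.4, b{=}0.4, c{=}0.1$; `RT = 0.616` kcal/mol at 37 °C. It
  produces sensible folds for exercising the machinery and makes no
  claim of thermodynamic calibration;
- `read_energy_params()` — a JSON file overriding any subset of: the
  stack table by pair type, hairpin/interior length tables (with
  logarithmic extrapolation past the last entry), multiloop $a,b,c$,
  per-pair energies, `RT`.

# What the synthetic data emulates — and what it does not

`random_sequences()` draws i.i.d. residues with a single `gc_content`
knob ($P(G)=P(C)=gc/2$, $P(A)=P(U)$ sharing the rest, default 0.5) and an
explicit seed; identical specs give byte-identical FASTA. Test batches
use GC contents 0.5–0.7, where random sequences of length 8–25 reliably
contain enough complementary content to exercise every recurrence case
(multibranch splits included), and lengths that keep the enumeration
oracle exact.

I.i.d. sequences have no covariation, no conserved helices, and none of
the length scales of real structured RNAs; `perturb_structure()`
likewise produces set-level corruptions, not the systematic slipped-helix
errors real predictors make. A green oracle suite therefore establishes
that each engine computes its stated optimum over the stated structure
space — it does not establish predictive accuracy on biological RNA,
which depends on the (pluggable) energy parameterization and is outside
what desk-scale synthetic data can certify. The published per-sequence
accuracy table shipped in `inst/extdata/` is used only for its internal
metric arithmetic, not re-derived from sequence.

# Evaluation conventions

True positives are exact $(i,j)$ identities — no slipped-pair credit.
The full Matthews coefficient needs a true-negative universe that the
pair-level setting leaves open; `dpfold` defaults to the admissible-pair
universe $\{(i,j): j-i \ge \text{min\_span},\ \theta\}$ when a sequence
is available (configurable to all $\binom{n}{2}$ pairs). This choice
touches only `mcc_full`; $X$, $Y$ and $\sqrt{XY}$ are universe-free.
Undefined metrics (empty reference or empty prediction) report `NA`,
never 0 and never NaN. A denominator variant of the full MCC that
circulates in print — $(TP{+}FP)(TP{+}FN)(FN{+}FP)(TN{+}FN)$ — is
available behind `printed_variant = TRUE` for comparison; note its
$(FN{+}FP)$ factor vanishes precisely at a perfect prediction, one
reason to regard it as a typesetting slip of the standard formula.

# Testing strategy and known limitations

Every engine is checked two ways: frozen tiny cases computed by hand or
by enumeration, and property suites against `enumerate_structures()` —
an interval-decomposition enumerator that is duplicate-free by
construction and itself cross-checked against the partition census. The
maximum-pairing engine is additionally verified *exhaustively* for all
sequences up to length 9: both the DP and the oracle depend on a
sequence only through which admissible positions can pair, so one
representative per pairability fingerprint (8,968 classes at $n = 9$)
covers all $4^9$ sequences at desk scale.

Known limitations, all deliberate: no pseudoknots; no dangling ends,
coaxial stacking or temperature rescaling in the energy model; no
suboptimal-structure enumeration beyond the single deterministic
traceback; the partition mode is pair-level, not loop-based; pure-R
tables mean quadratic memory and cubic time, comfortable to a few
hundred nucleotides but not genome scale.
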