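---
title: "Lightweight SCFGs for RNA secondary structure: models, training, decoding and grammar search"
author: "rnascfg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight SCFGs for RNA secondary structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnascfg)
```

## The model

A stochastic context-free grammar (SCFG) for RNA secondary structure is a
4-tuple: non-terminal symbols, the terminal alphabet, production rules, and a
start symbol, together with a probability distribution over each
non-terminal's rules. `rnascfg` restricts grammars to a *double emission
normal form* with exactly three rule shapes over the terminal alphabet
`(`, `)`, `.`:

* `T -> U V` — branching (bifurcation of the structure),
* `T -> .` — emission of one unpaired position,
* `T -> ( U )` — emission of both partners of a base pair in one production.

The form is expressive enough to build the standard structural motifs
(stacking via `V1 -> (V1)`, hairpins and bulges via combinations of branch
and unpaired rules), while excluding epsilon rules (`T -> ""`) and unit
rules (`T -> U`). Those two shapes permit cyclic productions — rule
sequences that return to the sentential form they started from — which give
some strings countably many derivations and break derivation counting.
Their exclusion means empty strings are never derivable, and a grammar like
Knudsen–Hein's KH99 (which contains `S -> L`) can only be represented after
normal-form conversion; the bundled `KH99p` is that conversion. The
conversion preserves the language but changes the parameterisation, so
trained probabilities and hence predictions can differ slightly from the
original grammar's.

The sequence model is deliberately light: one global 4-way distribution over
unpaired nucleotides and one global 16-way distribution over ordered
nucleotide pairs, shared by all rules. This matches a generative story in
which the grammar first emits a structure skeleton and nucleotides are then
allocated to sites by their frequency of occurrence at paired and unpaired
positions. Per-rule or stacking-context emission tables are intentionally
out of scope: the object of study is the space of *rule sets*, and a
heavier emission model would confound comparisons across grammars.

The grammar space over `m` non-terminals contains `m^3` branch rules, `m^2`
pair rules and `m` unpaired rules, hence `2^(m^3+m^2+m)` grammars:
16,384 at `m = 2` — exhaustively searchable — and about `5.5e11` at
`m = 3`, which is not.

## Inference

All dynamic programs operate on half-open spans and run in log space
(`-Inf` encodes impossibility); strings of realistic length (~200 nt)
underflow linear-space probabilities long before they stress log space. The
normal form is handled directly — a pair rule consumes both ends of its
span, an unpaired rule fills unit spans, a branch rule splits a span at
every interior point — rather than converting to Chomsky normal form, which
would change the parameterisation being studied. Complexity is
`O(|rules| * n^3)` time and `O(|N| * n^2)` space per sequence, with no
banding or heuristics.

* `structure_cyk()` parses a dot-bracket *string*: the most probable
  derivation of exactly that string.
* `count_derivations()` replaces (max, product) with (sum, product):
  the number of distinct derivation trees, saturating at a cap. A grammar
  is *ambiguous* when some structure counts at least 2.
* `sample_derivation()` draws uniformly among a string's derivations by
  backtracking through log-count tables (log space keeps astronomically
  ambiguous grammars sampleable).
* `sequence_inside()` / `sequence_outside_posteriors()` give the total
  sequence likelihood and the posterior base-pairing matrix `p(i, j)` with
  unpaired posteriors `q(i)`; for every position, `q(i)` plus the incident
  pair mass sums to 1, which the test suite asserts to `1e-9`.
* `sequence_cyk()` maximises the joint derivation-and-emission probability
  and reports the derivation's yield as the predicted structure.

CYK tie-breaks are deterministic (rule order as listed, then lowest split
point): identical inputs always reproduce identical structures, which the
search layer's reproducibility guarantees rely on.

## Decoding and gamma

Two predictors are provided. `predict_cyk()` reports the single most likely
derivation's structure. `predict_mea()` computes the posterior matrix and
then finds, by a Nussinov-style DP over non-crossing structures, the
maximiser of

```
sum over pairs (i,j) of gamma * p(i,j)  +  sum over unpaired i of q(i).
```

`gamma` trades base-pair recall against unpaired precision; the default
`gamma = 2` counts a correct pair as its two correct positions, i.e.
maximises the expected number of correctly predicted positions. The
weighting `gamma * p(i, j)` (rather than `2 * gamma * p`) was chosen so
that `gamma = 2` has exactly that interpretation. The decoded structure
need not be derivable by the grammar — posterior decoding is therefore
partially immune to grammar incompleteness, unlike CYK. Ties in the
objective prefer fewer pairs (then the unpaired-first option order), so
near-zero posteriors never introduce arbitrary pairs. A `min_hairpin`
option exists but defaults to 0: the decoder imposes no constraint the
model itself does not.

`gamma_sweep()` re-decodes cached posteriors over a grid (default 0.05 to
5.00 in steps of 0.05, 100 points) to trace the sensitivity/PPV trade-off
curve of a grammar.

## Training

* **Supervised (CYK-style)**: with trusted structures, rule probabilities
  are multinomial maximum-likelihood estimates of rule usage. For ambiguous
  grammars the derivation that produced a structure is unknowable, so one
  derivation is drawn *uniformly at random* per record — the sampling law
  is not dictated by the estimation principle, and uniform is the only
  choice that does not privilege any derivation; for unambiguous grammars
  the draw is vacuous. Emission tables count nucleotides at
  paired/unpaired sites of the trusted structures. A pseudocount (default
  0) is available; non-terminals never observed fall back to uniform.
  Maximum-probability-derivation training is intentionally not offered:
  for unambiguous grammars it coincides with the random draw, and for
  ambiguous ones it biases rule counts toward already-probable rules.
* **EM (inside–outside)**: trains on the record *sequences alone*,
  iterating expected-count collection and renormalisation. The trusted
  structures are deliberately ignored — this is the unsupervised
  counterpart used to ask what a grammar learns from sequence likelihood
  only. The log-likelihood trace is non-decreasing (asserted to `1e-8`
  slack); defaults are `tol = 1e-4`, `max_iters = 100`, uniform
  initialisation with a ±1% multiplicative jitter to break the symmetry of
  exchangeable non-terminals.

## Diagnostics: ambiguity and completeness

Both properties are undecidable in general, so the checks are heuristic and
their negative verdicts are explicitly `NEGATIVE_UP_TO_BOUND`, never
proofs. `check_ambiguity()` enumerates all structures up to length 10
exhaustively and then samples longer structures from the grammar itself
(uniform rule choice, rejection of over-length yields, default 1000 draws
to length 30), counting derivations of each candidate. A grammar is
*complete* when it derives every structure whose hairpin loops all have
length at least two; `check_completeness()` enumerates that universe up to
`max_len = 14` by default (the enumeration explodes combinatorially, so
lengths above 18 are refused).

Two bounds deserve justification. The exhaustive ambiguity bound of 10 is
comfortable: for all bundled grammars, ambiguity witnesses (when they
exist) already appear at lengths 2–4. The completeness check starts at
`min_len = 3`: strings of one or two positions cannot contain any
hairpin-legal pair, so they only probe whether the start symbol happens to
carry a *direct* unpaired rule — a notational accident rather than a
statement about structural coverage (a grammar may well derive `"..."` and
every longer all-dot string without deriving `"."`). Under these defaults
the seven bundled grammars split cleanly: `KH99p` unambiguous and
complete; `GG1`–`GG6` all ambiguous; `GG4` and `GG5` incomplete — both in
fact fail already on the length-4 structure `(..)`, and `GG4` also cannot
build four consecutive minimal hairpins, `(...)(...)(...)(...)`.

## The search layer

`run_evolution()` implements an evolutionary search over the normal-form
grammar space. The initial population is sixteen small two-symbol grammars:
the template `S -> SS | SB | BS | BB | (S) | .` with `B -> .`, minus each
of the 2^4 subsets of the four branch rules. Five mutation types (start
change, rule addition, rule deletion, fresh or duplicated non-terminal,
child rewiring) move through the space; the helper rule `B -> .` is never
removed, so every grammar retains a guaranteed unpaired emitter. Breeding
namespaces two parents apart (sharing `B`), renames both start symbols to a
common `S`, and unions the start rule sets — the child derives everything
either parent derives. Selection grows the population by the offspring and
then eliminates one grammar at a time with probability proportional to
`fitness - best + 1e-6` (lower fitness is better) until the target size is
restored; this shift-based rule is scale-free and cannot stall when
fitnesses tie. The incumbent best grammar is protected from elimination
(elitism of size one), making the champion trajectory monotone — a design
choice; nothing else in the machinery requires it.

Default rates (offspring 8 per generation, breeding probability 0.25,
mutation weights 0.05/0.4/0.1/0.25/0.2 for start/add/delete/new/rewire)
lean toward rule addition: deleting rules almost always hurts, while adding
too many mostly manufactures ambiguity, so addition outweighs deletion
4:1 and structural growth (new non-terminals, rewiring) gets the balance.
All rates are configurable in `evolution_config()`.

Fitness trains the candidate on the training records (supervised or EM),
predicts (CYK or MEA at `gamma = 2`), and scores: mountain-metric distance
(the L1 norm between nesting-height profiles — chosen over normalised
variants for additivity across positions), or negated
sensitivity/PPV/F-score, or a composite adding a failure penalty, a
complexity cost `w * |rules|`, and a longest-correct-structure reward. A
grammar that parses no training structure gets a large finite sentinel
(`1e12`) rather than an infinite value, keeping elimination probabilities
well-defined while guaranteeing first removal.

`brute_force_space()` sweeps all 16,384 two-non-terminal grammars (each
subset of the 14 possible rules, plus the untouchable `B -> .`);
`local_search()` enumerates add-one (32 around `KH99p`), add-two (496,
i.e. all unordered pairs of the 32 addable rules) and delete-one
neighbourhoods.

## Synthetic data

`sample_records()` draws structures by leftmost stochastic derivation and
then allocates nucleotides per site from the emission tables. Derivations
whose guaranteed minimal yield exceeds `max_len` are rejected and retried —
rejection (not renormalisation) keeps the sampled distribution exactly the
SCFG's, conditioned on the yield fitting. The reference source
(`kh99p_reference_params()`) is `KH99p` with hand-set, branch-light
probabilities giving a subcritical branching process with mean structure
length around 9 and Watson–Crick-dominated pair emissions — so 500-record
training sets at `max_len = 60` sample in seconds with low rejection rates.

What the generator emulates: pseudoknot-free structures of realistic
nucleotide composition with known ground-truth parameters. What it does
not: the family composition, length spectrum, thermodynamic consistency or
non-canonical pairs of curated RNA databases. Green tests therefore
certify the *algorithms* (estimators recover generating parameters;
decoders attain their objectives; search mechanics are sound), not
benchmark accuracy on real RNA — measuring the latter requires curated
datasets outside this package's scope, and the utilities in
`filter_dataset()` (duplicate removal, the 80% base-pair-similarity
redundancy cutoff with similarity defined conservatively as
`|shared pairs| / max(|pairs1|, |pairs2|)`, pseudoknot exclusion, rejection
of ambiguity codes at read time) exist to prepare such data.

## Problem sizes and numerical choices

The test suite works at deliberately chosen scales: oracle equivalence
against a brute-force derivation enumerator on all strings up to length 6;
parameter recovery on 500 sampled records up to length 60 (±0.05 on every
rule probability, comfortably above three binomial standard errors);
EM monotonicity on 50 sequences; the 100-point gamma sweep on 40 records;
and a 30-generation, population-16 evolution run on 40 records up to
length 40, executed twice to assert bit-level reproducibility. Probability
sums are validated to `1e-9` (parameters) and `1e-6` (parsed files);
derivation counts saturate at `1e15` by default, below the exact-integer
limit of doubles. `count_grammar_space()` returns a double, exact for all
`m <= 9` because pure powers of two carry no mantissa error; `m >= 10`
overflows to `Inf`.

## Known limitations

* Pseudoknots are out of scope end to end, as is standard for SCFGs.
* Emissions are global; stacking or per-context tables are not modelled.
* The ambiguity/completeness verdicts are bounded heuristics.
* Micro-averaging (pooled counts) is the default for dataset metrics; a
  `macro` flag offers per-sequence averaging, and the choice visibly moves
  numbers when structure sizes vary widely.
* The evolutionary defaults (offspring count, breeding fraction, elitism)
  are reasonable rather than tuned; the search is a tool for exploring
  grammar space, not a converged optimiser.
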