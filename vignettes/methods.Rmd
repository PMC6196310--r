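---
title: "Invariance-mined linguistic patterns and the smoothed partial tree kernel: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invariance-mined linguistic patterns and the smoothed partial tree kernel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkrex)
```

## The problem

Biomedical abstracts assert relations between entities — a chemical
up-regulating a protein, a drug inducing a disease — almost always inside a
single sentence. Supervised relation extraction must decide, for every
co-sentential heterogeneous entity pair, whether the sentence asserts a
relation and of which class. `tkrex` implements a pipeline whose two ideas
are (i) mining class-characteristic part-of-speech context patterns via an
algebraic invariance score, and (ii) classifying pattern-pruned dependency
trees with a smoothed partial tree kernel (SPTK) SVM.

## Candidate instances

Each entity pair gets its own *candidate instance*: a rewritten copy of the
sentence in which the focal pair is highlighted and everything else
genericized. This matters because one sentence can assert several relations
over overlapping entity sets; mining patterns from a single multi-relation
representation would smear class-specific context. The rewrite:

* focal chemical → `ChemicalR<r>T<c>` (PoS layer `CHEMICAL`), focal
  gene/protein → `GeneproR<r>T<c>` (`GENEPRO`; diseases analogously), where
  `r` indexes the gold relation within the sentence and `c` is the class
  number;
* every non-focal mention → its bare type symbol (`CHEMICAL`, `GENEPRO`,
  `DISEASE`) in both layers;
* for interacting pairs only, the *proximal verb* → `Relation<c>`
  (`RELATION`). The proximal verb is the verb minimizing summed token
  distance to the two spans; at equal distance an inflected form
  (VBD/VBZ/VBP/VBN/VBG) beats base VB — association statements are
  predominantly phrased with inflected verbs — and the leftmost wins last.
  Non-interacting pairs keep their verbs untouched and carry no RELATION
  anchor.

A mention participating in several gold relations yields one instance per
annotation (the contract does not say; one-per-annotation keeps the
instance count aligned with the gold set and lets each relation contribute
its own pattern evidence).

Normalization is reversible — each normalized token records the original
token span — and the keyword filter at test time matches *lemmas* of the
training proximal verbs rather than surfaces, so `induced` recalls
`induces` (surface matching would make the filter brittle for no gain).

## Frame scores, conics, and the invariant

For each referential group anchor and every offset `e_c = 0..n`, the
*context frame* is the window of `n + 1` PoS tags with the anchor at
position `e_c`, truncated (never padded) at sentence boundaries — a padding
symbol would enter the count tables and dilute every prefix statistic. The
frame score is a modified joint conditional probability over prefix counts
`Σc(·)` of all frames of all training instances:

* `0 < m ≤ n`: ρ = [Σc(x₀…x_m)/Σc(x₀…x_{m−1})] × [Σc(x₀…x_n)/Σc(x₀…x_m)];
* `m = 0` (frame conditioned on itself): ρ = Σc(x₀…x_n)/Σc(x_m…x_n) + δ_v.

With `m = 0` the suffix *is* the whole frame, so the ratio is identically 1
and the case evaluates to `1 + δ_v`; the fringe `δ_v = 1e-8` exists
precisely so that self-conditioned frames, which carry no conditional
information, get a floor score rather than a privileged one. Division by
zero cannot occur because every frame contributes to each of its own prefix
counts; scoring a frame against a counts table built from a different
instance set is an error by contract.

Per offset `e_c`, each role's scores are cumulated by summation into ρ\*
and *clubbed* into conic coefficients

p₂₀ = ρ\*₍E1₎ ⊙ ρ\*₍REL₎, p₀₂ = ρ\*₍E2₎ ⊙ ρ\*₍REL₎, p₁₁ = p₂₀·p₀₂,

where ⊙ is a product when both operands exist and passes the entity score
through unchanged when the instance has no relation anchor. The OR
semantics of the paired groups ("Entity1 ∨ Relation") motivates the
pass-through; "cumulates" and "joint probability" motivate sum and product
respectively, and the cross term couples the two axes — the source schema
is not fully reproducible from text, so these three choices are the
package's own, fixed here once. The instance's signature is the rotation
invariant

I(p) = p₂₀² + p₁₁²/2 + p₀₂²,

which equals the squared Frobenius norm of the quadratic-form matrix
[[p₂₀, p₁₁/2], [p₁₁/2, p₀₂]] and is therefore exactly invariant under
rotation of the feature plane — the property the tests verify to 1e-9 over
random conics and angles. Among the `n + 1` candidate offsets the
representation with the highest I wins; ties break to the smallest `e_c`
(the least-shifted window).

## Clustering and consensus

Within each class, instances are ranked by I descending (ties by instance
id) and chained: an instance joins the open cluster iff the ratio of the
cluster representative's I to its own lies within `ratio_tolerance`
(default 1e-6) of Δ^W = 1. Comparing against the *representative* rather
than the immediate predecessor was an open choice; the representative makes
the partition idempotent and permutation-invariant (a drifting chain would
let clusters depend on input order), which is also what the property tests
assert. The tolerance exists only because floating-point scores make exact
ratio-1 comparisons meaningless.

Each cluster's member frames are consolidated per role by progressive
global alignment — Needleman–Wunsch with the fixed penalties match +2,
mismatch −2, gap −2, traceback ties preferring diagonal, then up, then
left — guided in descending frame-frequency order (then instance id; the
contract gives no order, and frequency-first lets the modal frame anchor
the consensus). Columns take the majority symbol, ties resolving toward the
earliest-processed member, and all-gap columns are dropped. The result is
one triple-context pattern per cluster with support = cluster size.

## Trees, pruning, decoration

Dependency parses (CoNLL-U in, or the built-in fallback parser: first verb
is root, tokens attach to the nearest verb, coarse UD labels) are rebuilt
as grammatical-relation-centered trees: one SYNT node per dependency edge,
the dependents' subtrees and the head's POS→LEX chain as children ordered
by token position. The build contract states both "leaf order equals token
order" (twice, as invariant and property) and, in one example, "head chain
rightmost"; the two conflict whenever the head is not sentence-final, and
this package follows token order — it is the testable invariant, and it
matches the established GRCT representation. The head chain is rightmost
exactly when the head token is final.

Pattern matching aligns each pattern context against the instance's PoS
window anchored at the corresponding role position; the pattern's total
score is the sum over roles, and the covered tokens are those aligned to
non-gap pattern columns, always including the focal entities. Pruning
removes uncovered LEX leaves and any ancestor left without a LEX
descendant; decoration wraps the tree in a fresh root whose leftmost leaf
is the class node (`Class4`). The default minimum match score is 0: any
strictly positive alignment is allowed to prune, since the contract asks
only for the "best scoring" pattern.

## Kernel and classifier

The SPTK is computed by the standard subsequence dynamic program (C++ via
Rcpp, memoized over node pairs; the R-level `delta_sptk` is an independent
recursion used by the tests). Defaults μ = λ = 0.4 — customary tree-kernel
settings; the contract names no values — and kernel normalization
K̂ = K/√(K₁₁K₂₂) is on by default (standard for SVM use; configurable).
Node similarity is exact kind+label match, or a symmetric lexical table for
LEX–LEX pairs with values validated into [0, 1] to keep Δ bounded.

No precomputed-kernel SVM exists in the permitted dependency set, so the
soft-margin dual is solved by a deterministic SMO loop; problems here are
hundreds of instances, where SMO converges in a few passes and
reproducibility matters more than speed. Two tree views feed two stages:

* **binary gate** — class-hypothesis-free trees (negative-style
  normalization, no decoration, matched against all patterns), labels
  interacting/not; scores > 0 are interacting, < −0.3 non-interacting, and
  the dead zone [−0.3, 0] defaults to negative (the contract names the two
  cutoffs but not the interval; abstaining to negative is the conservative
  reading for a precision-oriented filter). Protein–protein mode instead
  accepts scores in [0, 1].
* **one-vs-all** — training trees decorated with their gold class; each
  test pair is replicated once per positive class, normalized and decorated
  under that hypothesis, scored by that class's model, and assigned the
  argmax. Only binary-positives are scored, as the two-stage description
  prescribes. How the original system built its test-time trees is not
  fully specified; the replica construction makes the class hypothesis
  explicit and symmetric across classes.

Per-class P/R/F1 use the standard contingency forms; the micro-average is
the data-size-weighted mean of per-set F1.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n` | 3 (CPI/PPI), 5 (CDR) | frame size; window is `n+1` tags; studied range 3–7 |
| `delta`, `W` | 1.00, 1 | zero-rotation premise; absolute representations |
| `ratio_tolerance` | 1e-6 | float tolerance around invariance ratio 1 |
| `fringe` | 1e-8 | self-conditioned frame floor δ_v |
| match/mismatch/gap | +2/−2/−2 | alignment penalties, fixed |
| `mu`, `lambda` | 0.4, 0.4 | SPTK depth/width decay, in (0, 1] |
| `C` | 1.0 | SVM cost (not reported by the source; exposed) |
| cutoffs | (0, −0.3) | binary decision; PPI uses range [0, 1] |
| `neg_ratio` | 1 | per-abstract negative:positive cap |

## The synthetic world

The generator emits the exact BioCreative file dialect with planted
two-class templates over disjoint lexicons, a neutral sentence tail,
negative sentences with non-interacting pairs, configurable class
imbalance, multi-pair (coordinated-chemical) sentences, and two noise
modes: *flanking* (noise appended after the tail, outside every template
context window, so planted patterns survive any rate) and *corrupting*
(noise at uniform positions inside the core, used for degradation curves).
Entity surfaces come from small fixed lexicons (`chemA…`, `geneB…`) so the
deterministic fallback tagger tags them without a model. Defaults — 1–4
sentences per abstract, 30% negative sentences, 15% multi-pair sentences,
uniform class proportions — are one plausible rendering of the skew and
multi-relation co-location reported for real chemical–protein corpora,
chosen once.

What a green synthetic run establishes: the pipeline's operations compose
correctly, planted structure is recovered exactly at zero noise, and
performance degrades monotonically under corruption. What it does not
establish: performance on real biomedical language — no lexical ambiguity,
no parser error, no annotation noise, vocabulary separability by
construction. Published corpus-level scores additionally depend on licensed
corpora and specific third-party tagger/parser builds, and are explicitly
out of scope.

## Numerical and degenerate-input choices

* Frame counts are keyed on exact tag tuples; normalized role tags
  participate as ordinary symbols.
* Clustering rejects non-positive invariants (they signal an upstream
  contract violation, not a numeric edge case).
* An empty keyword set disables the test filter with a warning rather than
  silently dropping everything.
* A one-class training set, a zero self-kernel under normalization, and
  decorating twice are errors; a class with fewer than two instances skips
  its OvA model with a warning and can then never be predicted.
* All randomness flows through per-call seeded streams that save and
  restore the caller's `.Random.seed`.

## Known limitations

The fallback tagger and parser are deliberately minimal (lexicon + suffix
rules; nearest-verb attachment) — adequate for the synthetic world,
unsuitable for real text, where CoNLL-U parses and a real tagger should be
supplied through the documented interfaces. Pattern matching assumes the
parse shares the instance's token sequence. Context size is fixed per run;
dynamic contexts and embedding-based node similarity are out of scope.
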