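# tkrex — linguistic-pattern tree-kernel relation extraction

`tkrex` extracts binary relations between biomedical entities mentioned in
the same sentence — chemical–protein interactions (CPR classes), chemical–
disease and protein–protein relations — from BioCreative-style annotated
abstracts. It is aimed at text-mining practitioners who want a fully
self-contained, deterministic implementation of a pattern-mined tree-kernel
classifier: no external tagger, parser or SVM library is required, and every
stage is exposed as an R function with a matching CLI command.

## The method

1. **Candidate instances.** Every co-sentential heterogeneous entity pair
   yields a derivative copy of its sentence: the focal pair is rewritten to
   normalized role tags (`ChemicalR1T3` / `GeneproR1T3`, PoS layer `CHEMICAL`
   / `GENEPRO`), other mentions become bare generic symbols, and for
   interacting pairs the *proximal verb* (the nearest inflected main verb)
   becomes `Relation#` with PoS `RELATION`.

2. **Invariance-based pattern mining.** For each referential group
   (entity 1, relation, entity 2), PoS *n*-gram context frames are scored
   with a modified joint conditional probability over the corpus frame
   inventory,

   ρ = [Σc(x₀…x_m)/Σc(x₀…x_{m−1})] · [Σc(x₀…x_n)/Σc(x₀…x_m)]  (0 < m ≤ n),

   ρ = Σc(x₀…x_n)/Σc(x_m…x_n) + δ_v  (m = 0, fringe δ_v = 1e−8),

   cumulated into conic coefficients P(x,y) = p₂₀x² + p₁₁xy + p₀₂y², and
   collapsed to the rotation invariant **I(p) = p₂₀² + p₁₁²/2 + p₀₂²**.
   Instances are ranked by I and chained into clusters wherever the
   invariance ratio is 1 (Δ = 1.00, W = 1); each cluster is consolidated by
   progressive global alignment (match +2, mismatch −2, gap −2) into a
   triple-context linguistic pattern such as
   `[CHEMICAL RELATION DT NN] → [RELATION DT NN IN] → [GENEPRO IN DT NN]`.

3. **Pattern-pruned GRCT trees.** Dependency parses are re-expressed as
   grammatical-relation-centered trees (SYNT/POS/LEX layers); the
   best-aligned pattern selects the tokens to keep, uncovered leaves and
   their emptied ancestors are pruned, and a class node (`Class4`, …) is
   prefixed.

4. **Smoothed partial tree kernel SVM.** Trees are compared with
   K(T₁,T₂) = ΣΣ Δ(n₁,n₂), where Δ for leaves is μλσ and otherwise
   μσ·(λ² + Σ λ^{d(I₁)+d(I₂)} Π Δ(children)) over equal-length child
   subsequences (defaults μ = λ = 0.4, exact-label σ or a lexical
   similarity table). A binary SVM (deterministic SMO over the precomputed
   Gram matrix) gates interacting pairs with cutoffs (> 0 interacting,
   < −0.3 non-interacting, dead zone → negative; protein–protein mode uses
   the 0–1 range rule), then one-vs-all SVMs assign the argmax class.
   Test candidates are pre-filtered by the training proximal-verb keywords.

Precision, recall, F1 per class and the data-size-weighted micro-average
follow the standard contingency definitions.

## Worked example

A synthetic corpus with two planted relation classes, mined and classified
end to end:

```r
library(tkrex)
train <- generate_corpus(default_templates(), synthetic_config(n_abstracts = 60, seed = 2))
test  <- generate_corpus(default_templates(), synthetic_config(n_abstracts = 30, seed = 3))

ct <- corpus_training_instances(train$corpus, seed = 2)
learned <- learn_patterns(ct$instances, invariance_config(n = 3))
for (p in learned$patterns)
  cat(sprintf("%-7s [%s] -> [%s] -> [%s]  support %d\n", p$class,
      paste(p$entity1_context, collapse = " "),
      paste(p$relation_context, collapse = " "),
      paste(p$entity2_context, collapse = " "), p$support))
#> CPR:4   [CHEMICAL RB RELATION GENEPRO] -> [RELATION GENEPRO NN IN] -> [GENEPRO NN IN DT]  support 55
#> CPR:3   [CHEMICAL RELATION DT NN] -> [RELATION DT NN IN] -> [GENEPRO IN DT NN]  support 52
#> CPR:10  [CHEMICAL CC GENEPRO VBD] -> [] -> [GENEPRO VBD VBD IN]  support 40

model <- train_pipeline(train$corpus, pipeline_config(mode = "CPI", seed = 2))
ev <- evaluate_pipeline(predict_pipeline(model, test$corpus), test$corpus)
print(ev$report, row.names = FALSE)
#>  class TP FP FN P R F1
#>  CPR:3 31  0  0 1 1  1
#>  CPR:4 28  0  0 1 1  1
#>    ALL 59  0  0 1 1  1
```

Each mined pattern is one invariance cluster's consensus PoS contexts (the
negative class CPR:10 has no relation context — non-interacting pairs carry
no Relation tag); `support` counts the instances behind it. The evaluation
table is exact on this separable synthetic corpus: every held-out pair is
gated and classified correctly. Real corpora will not be separable; the
synthetic world isolates implementation correctness from corpus difficulty
(see the methods vignette).

The same chain is scriptable:

```sh
Rscript inst/cli/tkrex simulate --out corpus --n-abstracts 60 --seed 2
Rscript inst/cli/tkrex train --abstracts corpus/abstracts.tsv \
    --entities corpus/entities.tsv --relations corpus/relations.tsv \
    --mode CPI --seed 2 --model model.json
Rscript inst/cli/tkrex predict --model model.json --abstracts test/abstracts.tsv \
    --entities test/entities.tsv --out predictions.tsv
Rscript inst/cli/tkrex evaluate --predictions predictions.tsv \
    --relations-gold test/relations.tsv --abstracts test/abstracts.tsv \
    --entities test/entities.tsv --out report.tsv
```

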