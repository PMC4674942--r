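---
title: "Unsupervised medical term extraction with a GA-weighted ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised medical term extraction with a GA-weighted ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termensemble)
```

## The problem

Clinics accumulate large archives of short free-text letters between
specialists and general practitioners. Mining the medical terms they contain
("intraocular pressure", "posterior vitreous detachment", ...) without a
labelled training set is attractive because annotation by clinicians is the
bottleneck. This package implements an ensemble of three *unsupervised*
extractors that look at complementary properties of language, plus a
genetic algorithm (GA) that learns how to combine them using only a small
annotated term list (not annotated documents):

* **PrefixSpan** — frequent-sequence mining at the *lexical* level. Every
  sentence is a sequence of words; a term is a word sequence whose support
  (the number of sentences containing it) clears a minimum-support floor.
* **C-Value** — a *syntactic + statistical* termhood measure over
  noun-phrase candidates,

  $$CV(a) = \log_2 |a| \left( f(a) - \frac{1}{P(T_a)}
    \sum_{b \in T_a} f(b) \right),$$

  where $f(a)$ is the corpus frequency of candidate $a$, $|a|$ its length
  in words, and $T_a$ the set of longer extracted candidates containing $a$
  (the subtraction vanishes when $T_a$ is empty). Long, frequent phrases
  that are *not* merely fragments of longer phrases score highest.
* **TextRank** — a *structural* co-occurrence measure: candidate terms are
  vertices of a graph, connected when they occur in the same sentence, and
  scored by the weighted voting recursion

  $$WS(v_i) = (1-d) + d \sum_{j \in in(v_i)}
    \frac{w_{ji}}{\sum_{k \in out(v_j)} w_{jk}} WS(v_j),$$

  with damping $d = 0.85$.

Each ranking is cleaned against a domain dictionary, rank-normalised to
$[0,1]$, and fused by a weighted sum $r_w(t) = \sum_i w_i\, r_i(t)$ with
$w$ on the 3-simplex. A term is predicted domain-related when
$r_w(t) \ge 0.5$. The GA evolves $w$ to maximise the F-measure against the
annotated term set.

## Fitting a model

```{r fit, eval = FALSE}
syn   <- generate_corpus(n_documents = 100, seed = 1)
truth <- generate_truth()
fit <- term_ensemble(syn, truth$dictionary, truth$annotations,
                     ga = ga_config(runs = 10, rng_seed = 1))
summary(fit)
coef(fit)        # learnt fusion weights
plot(fit)        # GA fitness history
head(predict(fit))
```

`term_ensemble()` is the central fitting function; every stage is also
exported on its own (`prefixspan_ranking()`, `cvalue_ranking()`,
`textrank_ranking()`, `filter_terms()`, `run_ga()`, ...), and
`run_pipeline()` exposes the same stages as file-to-file commands.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_sup` | 0.001 | PrefixSpan support floor; fractions resolve against the document count (0.1 % of the corpus), rounded up |
| `max_term_length` | 4 | cap on candidate/pattern length in words |
| `d` | 0.85 | TextRank damping |
| `tr_iterations`, `tr_epsilon` | 30, 1e-4 | TextRank iteration cap and convergence threshold (max absolute per-vertex change) |
| `rank_threshold` | 0.50 | ensemble classification cut-off (boundary-inclusive) |
| `population_size`, `generations`, `runs` | 100, 200, 100 | GA study conditions |
| `elitism_rate` | 0.40 | fraction of each generation preserved |
| `child_mutation_prob`, `elite_mutation_prob` | 0.20, 0.10 | gentle-mutation chances |
| `domination_threshold` | 0.85 | weight ceiling above which a child is super-mutated |

## Design choices in ambiguous corners

Several details of the procedure are underdetermined by common usage; the
package fixes them as follows.

* **Support semantics.** "Minimum support" is treated as a minimum
  frequency: a pattern at exactly `min_sup` is frequent. A `strict` flag
  switches to the strictly-greater reading.
* **Gap policy.** The PrefixSpan recursion mines gapped subsequences in
  library mode (`mine_frequent_patterns()`); the term-extraction preset
  uses `contiguous = TRUE`, where a pattern is an exact consecutive run of
  elements, so emitted terms are real word n-grams. Contiguous matching is
  defined by element equality, not subset containment — `<a c>` does not
  occur contiguously in `<a (a b) c>`.
* **C-Value for unigrams.** The piecewise formula assigns
  $\log_2 1 = 0$ to every single word, which would make unigram rankings
  impossible even though frequency clearly carries signal for them. The
  default `unigram_mode = "plus_one"` uses $\log_2(|a|+1)$ for unigrams
  (so $CV = f(a)$); `"as_printed"` keeps the literal formula. Unigrams
  never receive the nesting subtraction in either mode.
* **Nesting.** $T_a$ uses contiguous word-level sub-span containment among
  distinct extracted candidates; sub-spans of every maximal noun-phrase
  chunk are emitted at chunk time so $f$ counts nested occurrences in one
  pass.
* **Rank normalisation.** The term at rank $k$ of $N$ receives
  $1 - (k-1)/N$; raw extractor scales (support counts, C-Values, TextRank
  weights) are incommensurable, while ranks always lie on a common scale.
  Min-max normalisation of raw scores is available. Terms a method did not
  extract score 0 for that method.
* **Crossover schedule.** Naive crossover (elementwise product / sum,
  renormalised by the sum — the only normalisation that preserves the
  simplex) runs for the first half of the generations; domination
  crossover for the second half. The switch point is configurable
  (`crossover_switch_fraction`).
* **Selection plumbing.** Four distinct parents are drawn uniformly from
  the elite; two 2-vs-2 tournaments pick the winners (ties broken at
  random); children fill the non-elite share of the next population, the
  last surplus child being discarded. Elite members are gently mutated
  (probability 0.10) *before* reinsertion. A degenerate all-zero weight
  vector renormalises to uniform.
* **Filtering granularity.** The default `token_coverage` mode keeps a
  term when every non-stopword token occurs in the dictionary vocabulary,
  so compositional phrases ("fundus examination") survive without a
  verbatim entry; `whole_term` and `either` are selectable.
* **Evaluation universe.** $U$ is the union of the three filtered outputs;
  positives are annotated domain terms plus (optionally) unigrams
  confirmed by the dictionary, with explicit non-domain labels taking
  precedence over dictionary confirmation. The complex-terms-only
  condition removes unigrams symmetrically from $U$, $P$ and predictions,
  and re-normalises the per-method rankings over the remaining terms.
* **Zero divisions.** Metrics with empty denominators return 0 with a
  flag, so the GA fitness is total.

## Numerical notes

TextRank iterates synchronously (all updates read the previous iteration,
vertices in fixed sorted order), so identical inputs give bit-identical
score sequences. Stopping at "max per-vertex change < $\varepsilon$"
leaves a truncation residual of roughly
$n\,\varepsilon\,d/(1-d) \approx 5.7\,n\varepsilon$ in the total score
mass, for every $\varepsilon$; total-mass conservation
($\sum WS = n$ on graphs without isolated vertices) is therefore a
property of the *converged* fixed point. The tests iterate to full
convergence and check conservation at ten times the pipeline's default
threshold ($10^{-3}$), and — much more tightly — check the converged
scores against the direct linear solve of
$x = (1-d)\mathbf{1} + d P^\top x$ to $10^{-8}$.

Ranking ties are broken lexicographically everywhere, which combined with
seeded RNG makes every stage reproducible end to end.

## What the synthetic generator does and does not show

The generator (`generate_corpus()`) emulates the *shape* of a specialist
letter corpus: short letters of templated subject–verb–object clauses
(~5–8 sentences), multi-word ophthalmology terms planted in an exact
number of distinct documents, one nested pair ("angle closure" inside
"acute angle closure") so the C-Value discount is hand-checkable,
high-frequency non-domain distractors ("twelve months", "kind regards"),
and filler clauses. Every token carries a known POS tag, so the bundled
deterministic lookup tagger reproduces the intended chunks exactly.

It does **not** emulate: real clinical vocabulary breadth, tagger errors,
misspellings and shorthand idiosyncrasies, or the heavy-tailed frequency
distribution of a decade of letters. Passing tests therefore demonstrate
that the algorithms are implemented correctly and that the pipeline
recovers planted structure under controlled conditions — not that the
headline accuracy on a real corpus of tens of thousands of letters would
be reproduced. Default problem sizes (100 synthetic letters for
end-to-end checks; GA at 100 organisms x 200 generations, averaged over
repeated seeded runs) were chosen as the smallest sizes at which every
planted term comfortably clears the support floor and the GA's behaviour
is stable across seeds.

## Known limitations

* The bundled heuristic tagger is intentionally small; production use
  should inject lemmas/tags from a trained model via `lookup_tagger()`
  and `lookup_lemmatizer()`.
* Sentence splitting on `. ! ?` over-splits clinical abbreviations
  ("o.d."); downstream statistics are sentence-robust, so this only
  fragments co-occurrence slightly.
* The fusion is linear and the GA learns exactly one weight per extractor;
  the operators generalise to $N \ge 2$ methods but remain specified for
  scalar weights on the simplex.
* Dictionary construction (web crawling, UMLS lookup) is out of scope:
  the dictionary is an input.
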