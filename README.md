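# midecay

Mutual information decay analysis of symbolic vocal sequences.

## What problem this solves

Birdsong syllable transcripts, phonetically transcribed speech, and other
categorical sequences carry statistical dependencies between elements.
The *shape* of how those dependencies fall off with sequential distance
is diagnostic of the generative process: a Markov process (each element
depending only on its predecessor) produces mutual information (MI) that
decays exponentially, a recursive hierarchical process produces MI that
decays as a power law, and a signal governed by both processes at
different scales shows a composite of the two. `midecay` is for
researchers in bioacoustics, animal communication and speech science who
want to make that diagnosis quantitatively from transcribed corpora.

The pipeline is:

1. **Estimate** the shuffle-corrected MI between elements at distances
   `d = 1, 2, ...`:

   `MI(d) = Î(d) − Î_sh(d)`, with
   `Î = Ŝ(X) + Ŝ(Y) − Ŝ(X,Y)` and each entropy estimated with the
   digamma-based finite-sample correction
   `Ŝ = (ln N − (1/N) Σᵢ Nᵢ ψ(Nᵢ)) / ln 2` (bits). The baseline
   `Î_sh` comes from independently permuting each sequence.
2. **Fit** three decay laws to the positive corrected MI in log space
   (weighted nonlinear least squares): exponential `a·e^(−xb) + c`,
   power law `a·x^b + c`, and their 5-parameter composite
   `a·e^(−xb) + c·x^d + f`.
3. **Select** among them with small-sample corrected AIC (AICc) and
   Akaike weights (relative model probabilities).
4. **Locate the knee**: the curvature `κ = |y''| / (1 + y'²)^{3/2}` of
   the fitted composite in log-log space dips where the exponential
   regime hands over to the power-law regime.

Seeded generative grammars (Markov, recursive hierarchical, combined),
shuffle-based controls that isolate within-unit versus between-unit
information, and a config-driven `run_analysis()` round out the package.

## Worked example

Simulate a Markov corpus (8 states, sparse transitions), estimate its MI
decay, and ask which law explains it:

```r
library(midecay)

g <- random_markov_grammar(8, concentration = 0.1, seed = 42,
                           length = 400, n_sequences = 100)
corpus <- sample_corpus(g)
curve <- mi_decay_curve(corpus, max_distance = 60, seed = 1)
curve
#> # A tibble: 60 × 5
#>   distance n_pairs mi_raw mi_shuffled    mi
#>      <int>   <int>  <dbl>       <dbl> <dbl>
#> 1        1   39900  1.50    0.0000398 1.50
#> 2        2   39800  0.897   0.0000795 0.897
#> 3        3   39700  0.502   0.0000842 0.502
#> 4        4   39600  0.259  -0.000104  0.259
#> 5        5   39500  0.146   0.0000774 0.146
#> # ℹ 55 more rows

comparison <- fit_decay_models(curve)
tidy(comparison)
#> # A tibble: 3 × 9
#>   family          k     n   rss    r2   aicc delta_aicc rel_prob best
#>   <chr>       <dbl> <dbl> <dbl> <dbl>  <dbl>      <dbl>    <dbl> <lgl>
#> 1 exponential     3    46  34.9 0.768 -6.14        0      0.816  TRUE
#> 2 power_law       3    46  39.6 0.737 -0.279       5.86   0.0435 FALSE
#> 3 composite       5    46  33.8 0.775 -2.62        3.52   0.140  FALSE
```

The MI at distance 1 is 1.5 bits and falls below the estimator noise
floor within a few tens of elements; 46 of the 60 distances have positive
corrected MI and enter the fit. The exponential family wins the AICc
comparison with relative probability 0.82 — the signature of Markovian
dynamics, as it should be for this generator.

A corpus from the combined grammar (hierarchical structure whose end
states are short fixed Markov subsequences, marked as `word` units)
instead selects the composite and yields a knee:

```r
gh <- copy_hierarchical_grammar(5, q = 2, depth = 10, n_sequences = 300, seed = 7)
gm <- random_markov_grammar(25, seed = 8, length = 10, n_sequences = 5)
co <- sample_corpus(combined_grammar(gh, gm, c(2, 5), seed = 9))
cmp <- fit_decay_models(mi_decay_curve(co, max_distance = 100, seed = 1))
glance(cmp)
#> # A tibble: 1 × 4
#>   best      rel_prob_best delta_aicc_second     n
#>   <chr>             <dbl>             <dbl> <dbl>
#> 1 composite         1.000              18.0    99

curvature_profile(attr(cmp, "fits")$composite)
#> Curvature profile of composite decay (log-log space)
#>   grid: 10000 points over distances 1..100
#>   knee (curvature minimum): 25 elements
#>   following maximum:        41.3 elements
```

`autoplot()` methods draw the curve, the fitted families, and the
curvature profile; `decompose_fit()` subtracts one fitted component to
expose the other. For real corpora, `read_corpus()` ingests long-format
TSV/CSV (one element per row, arbitrary column names via
`corpus_dialect()`), `segment_bouts()` splits songs at silent gaps,
`concatenate_level()` re-keys the analysis to days/bouts/words, and
`apply_shuffle()` provides the within-unit / between-unit controls.

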