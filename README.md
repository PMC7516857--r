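# teflow

Can pairwise transfer entropy recover the true flow of information in a
neural circuit? `teflow` studies this question in a setting where the
answer is exactly computable: small digital brains — networks of 16 binary
neurons wired by deterministic 2-to-1 logic gates (Markov Brains) —
evolved to perform two classic cognitive tasks, visual motion detection
(Reichardt-style delay-and-compare) and sound localization
(Jeffress-style interaural time difference). Because the full wiring and
logic of each circuit is known, a ground-truth influence map can be
derived and compared against what transfer entropy infers from recordings
of the behaving circuit.

The package is aimed at researchers in information dynamics and network
inference who want a controlled benchmark for directed-information
measures.

## What it computes

Transfer entropy with one-step histories,

> TE(X→Y) = I(Y<sub>t+1</sub> : X<sub>t</sub> | Y<sub>t</sub>),

plus the exact machinery around it:

* **Information measures** on discrete joint tables: entropy, (conditional)
  mutual information, transfer entropy, processed information
  I(Z<sub>t</sub>:Z<sub>t+1</sub>), co-information, and the entropy
  decompositions that link them (`decomposition_residual()`).
* **The 16-gate catalog** (`gate_table()`): for every 2-to-1 Boolean gate
  under uniform inputs, the output entropy, the pairwise TEs in
  feedforward and feedback wiring, and the TE misestimate each gate
  induces — 1 bit for the cryptographic gates XOR/XNOR (one-time-pad
  logic), 0.19 bits of "obfuscation" for every polyadic AND/OR-family
  gate, zero for copies and constants.
* **Markov Brain simulation**: synchronous OR-combining updates, full
  logic-table extraction, and functional-dependence influence maps
  (`influence_map()`) that discard vestigial wiring.
* **Task environments and recordings** (`md_task()`, `sl_task()`,
  `record()`): 16 motion patterns (3 PD / 3 ND / 10 stationary), 5
  interaural lags; 64- and 20-snapshot recordings.
* **Evolution** (`evolve()`): a reproducible genetic algorithm over gate
  genomes, with replicate populations and perfect-fitness champions.
* **Knockout assays** (`knockout_assay()`) for gate essentiality and the
  catalog-based theoretical misestimate of a circuit
  (`theoretical_misestimate()`).
* **Detection scoring** (`te_matrix()`, `score_detection()`,
  `roc_curve()`, `fit_gaussian_roc()`): hits, misses and false alarms of
  thresholded TE against the influence map, ROC staircases, and a
  binormal ROC fit.

Results come back as tibbles, fitted objects support `tidy()` /
`glance()`, and `autoplot()` renders TE matrices, influence maps and ROC
curves.

## A worked example

A hand-built Jeffress-style localizer (delay lines plus five coincidence
detectors) solves the task perfectly, and transfer entropy still
misreads its wiring:

```r
library(teflow)

solver <- build_named_fixture("sl_solver")$brain
sl_evaluate(solver)$fitness
#> [1] 1

fa <- flow_analysis(solver, sl_task())
fa$detection
#> # A tibble: 1 × 8
#>   threshold  hits misses false_alarms n_edges n_nonedges hit_rate false_alarm_rate
#>       <dbl> <int>  <int>        <int>   <int>      <int>    <dbl>            <dbl>
#> 1         0    12      2           40      14        226    0.857            0.177
```

Twelve of the fourteen true influences are detected, two are missed, and
forty neuron pairs with no connection at all acquire spurious TE — the
false alarms outnumber the hits. The analytic origin of such failures is
in the gate catalog:

```r
dplyr::select(gate_table(), id, class, h_out, te_x, te_y, te_error_ff)[1:4, ]
#> # A tibble: 4 × 6
#>   id        class    h_out  te_x  te_y te_error_ff
#>   <chr>     <chr>    <dbl> <dbl> <dbl>       <dbl>
#> 1 ZERO      constant 0     0     0           0
#> 2 AND       polyadic 0.811 0.311 0.311       0.189
#> 3 AND-NOT_X polyadic 0.811 0.311 0.311       0.189
#> 4 AND-NOT_Y polyadic 0.811 0.311 0.311       0.189
```

An AND gate's output carries 0.81 bits, but the two pairwise transfer
entropies only attribute 0.62 of them; the missing 0.19 bits are the
gate's (negative) co-information — information the inputs carry *jointly*
that no pairwise measure can assign. XOR hides its entire bit this way.

Evolved circuits are produced and analysed the same way:

```r
res    <- evolve(md_task(), evolution_config())   # 20 replicate populations
brains <- best_brains(res)                        # perfect-fitness champions
flow_analysis(brains[[1]], md_task())$detection
```

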