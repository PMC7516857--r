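---
title: "Measuring information flow in evolved Boolean circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring information flow in evolved Boolean circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teflow)
library(dplyr)
```

## The question

Transfer entropy (TE) is the standard information-theoretic surrogate for
directed influence in neural recordings:

$$\mathrm{TE}_{X \to Y} = I(Y_{t+1} : X_t \mid Y_t),$$

the reduction in uncertainty about the next state of $Y$ contributed by the
past of $X$ over and above $Y$'s own past. `teflow` asks a sharp, fully
controlled version of the question practitioners care about: *if we knew the
complete wiring and logic of a small cognitive circuit, how much of its true
information flow would pairwise TE recover from recordings of the circuit
behaving?* Because the circuits here are digital — networks of binary
neurons updated by deterministic 2-to-1 logic gates (Markov Brains) — the
ground truth is computable exactly, and every failure of TE is attributable
to the mathematics rather than to noise or sampling artefacts.

## Exact information measures

All exact quantities are computed on a `joint_table`, a tibble of binary
states and probabilities. Everything reduces to marginal entropies in base-2
logarithms with $0 \log 0 = 0$; probabilities are validated to sum to one
within $10^{-12}$. Mutual informations and TEs are clamped at zero when
floating-point cancellation produces values like $-10^{-16}$; co-information
is *not* clamped, since its negativity is the phenomenon of interest: for
$Z = X \oplus Y$ on uniform inputs, $I(X{:}Y{:}Z) = -1$ bit — the one-time
pad. History lengths are fixed at one step on both sides ($k = \ell = 1$);
the processes are first-order Markov by construction, so longer histories
add estimation cost without adding information, and no API for them is
offered.

The package verifies three decomposition identities as properties (see
`decomposition_residual()`): the feedforward split of the output entropy
into conditional TEs plus a synergy term, the feedback split into TE plus
processed information $I(Z_t{:}Z_{t+1})$, and the general five-term
decomposition valid for any joint. The feedforward identity only holds when
the output is a deterministic function of the two inputs and the target's
own past is uninfluential; the random-joint generators used in the property
tests (`random_feedforward_joint()` and friends) sample exactly that
precondition, with a random truth table and a random input distribution.

## The gate catalog

`gate_table()` reproduces, at full precision, the analytic TE bookkeeping
for all sixteen 2-to-1 gates under maximum-entropy inputs, in feedforward
($Z_{t+1} = f(X_t, Y_t)$) and feedback ($Z_{t+1} = f(Y_t, Z_t)$) wiring.
Gates fall into four classes: *constant* (ZERO/ONE), *dyadic* (COPY/NOT,
output depends on one input), *cryptographic* (XOR/XNOR, each input alone
shares zero information with the output), and *polyadic* (the AND/OR
families). The feedforward misestimate is
$H(Z_{t+1}) - \mathrm{TE}_{X\to Z} - \mathrm{TE}_{Y\to Z}$, which equals the
magnitude of the (negative) co-information: 1 bit for cryptographic gates,
0.19 bits for every polyadic gate — partial encryption, or *obfuscation* —
and zero otherwise.

The feedback columns need one modelling decision. The identity guarantees
$\mathrm{TE}_{Y \to Z} + I(Z_t{:}Z_{t+1}) = H(Z_{t+1})$, so nothing is
numerically "missing"; the error is one of *attribution*: for a gate that
depends on both inputs the two terms split the entropy unevenly (0.5 vs
0.31 bits for AND, 1 vs 0 for XOR) although both sources matter equally. We
quantify that misattribution as
$\lvert \mathrm{TE}_{Y\to Z} - I(Z_t{:}Z_{t+1}) \rvert$, gated on the gate
actually depending on both inputs — which yields the familiar 0.19-bit
error for every polyadic gate and the full bit for XOR/XNOR. The "correctly attributed"
flow of a gate is then the sum of its two pairwise terms minus its error,
which keeps correct + error equal to the total attributable flow in both
wirings. The uniform-input assumption behind all of these numbers is an
approximation for gates embedded in a circuit, whose inputs are generally
neither uniform nor independent; the recordings-based pipeline below does
not inherit it.

## Markov Brains and ground truth

A brain is its gate list: each gate reads two of sixteen binary neurons and
writes one. When several gates write the same neuron the results are OR-ed
(one firing input suffices to fire the neuron); a non-sensory neuron
nobody writes decays to quiescence, which is what makes "memory by
rewriting" a real, selectable trait; sensory neurons hold their externally
clamped value. The genome is a structured gene list rather than a
byte-stream: nothing downstream depends on a byte-level encoding, and
mutation operators act directly on connections and truth-table bits.

The ground-truth influence map deliberately ignores raw wiring. An edge
$i \to j$ exists only if neuron $j$'s next value, as a Boolean function of
the current state, actually changes for some single-bit flip of neuron $i$.
This discards ZERO/ONE gates (no output entropy) and vestigial inputs
(wired but functionally inert). Dependence is tested exactly on each
neuron's support — the inputs of the gates that write it — which is
mathematically identical to flipping every bit in all $2^{16}$ states; the
test suite verifies that equivalence against the brute-force oracle on
dozens of random circuits. Self-influence is recorded on the diagonal but
excluded from detection scoring by default, and columns of sensory neurons
are zeroed: during behaviour their value is the stimulus.

## Tasks: what the synthetic data emulates

Both tasks drive two sensory neurons (N0, N1) for three updates from an
all-quiescent start and read designated outputs at the final state, so a
recording of one trial is four 16-neuron snapshots.

**Motion detection** presents one of the 16 two-step patterns; 3 are
preferred-direction, 3 null-direction, 10 stationary, following the
delay-and-compare logic of the Reichardt detector. The brain updates once
after the first frame and twice after the second — the stimulus is held
clamped during both of those updates, the simplest reading of the
"updated two times" protocol — and the *sum* of the two output neurons
(N14, N15 by default; the output indices are configurable because no
canonical choice exists) codes ND/stationary/PD as 0/1/2. A full recording
is $16 \times 4 = 64$ snapshots.

**Sound localization** encodes interaural time difference in the spirit of
the Jeffress model: one pulse per ear, lagged by $-2 \dots +2$ steps
within a three-step window (the earlier ear fires at step 1). No single
raster layout is canonical for this coding, so the schedule is
parameterised rather than fixed; the default lag set is the five-angle
version. Correctness is one-hot on the five designated outputs
N11–N15 — each output neuron claims one angle, and a trial counts only if
exactly the right detector fires. A recording is $5 \times 4 = 20$
snapshots.

These recordings emulate the *best case* for TE in real experiments:
noise-free deterministic neurons, every neuron observable, and every
possible sensory experience sampled exactly once (determinism makes
repetition redundant). What they do not emulate is everything that makes
biological recordings harder — intrinsic noise, partial observability,
continuous signals needing discretisation — so a detection failure here is
a lower bound on trouble, not an estimate of it.

## Evolution

The genetic algorithm evolves populations of 100 gene lists with
tournament selection (size 2), one elite, per-site point mutations (0.01),
gene duplication (0.1) and deletion (0.02), from initial genomes of 8–12
random genes, for up to 10,000 generations per replicate with early stop at
perfect fitness, 20 replicates by default. Replicate seeds are drawn once
from the seeded master generator, so runs are exactly reproducible.

Two details matter and were chosen after observing the search itself;
both are this package's own design choices, surfaced in the
configuration. First, selection acts on a *graded* per-trial score — partial
credit for output sums near the target, and per-bit credit on the one-hot
outputs — while reported fitness, traces, elitism ranking and the
perfect-fitness filter always use the exact fraction of correct trials.
Without shaping, motion-detection runs plateau at 15/16: the lone
blank-then-right pattern (00→10, a preferred-direction trial) sits behind a
fitness cliff that pure correct/incorrect selection rarely crosses. Second,
a relatively high duplication rate grows neutral genome length, which is
the classic route to crossing such cliffs; it roughly triples the rate at
which replicates reach perfection. Elites are ranked by exact fitness with
the shaped score as tie-break, so the max-fitness trace is non-decreasing.

With the default configuration and master seed, a majority of
motion-detection replicates and all sound-localization replicates reach
perfect fitness; the cohort analyses below run on those champions. The
default study size (20 replicate populations of 100) keeps a full cohort
analysis within minutes on a single CPU while leaving enough champions
for stable cohort means; scale `replicates` up for tighter intervals.

## Knockouts and the theoretical misestimate

A gate is *essential* when deleting it (and all its connections) drops an
otherwise perfect brain below fitness 1; `knockout_assay()` does one
knockout per gate, re-measuring fitness from scratch each time (no double
knockouts). `gate_composition()` counts gate types per brain, by default
collapsing exact duplicates, which evolution produces freely. The
theoretical misestimate of a circuit sums the catalog's per-gate error over
its essential gates — feedback columns when a gate writes one of its own
inputs, feedforward otherwise — and is explicitly an approximation: it
assumes uniform independent inputs at every gate. Cohort summaries report
mean ± 1.96 SE.

## Detection scoring

`te_matrix()` estimates all pairwise TEs by plug-in (maximum-likelihood)
frequencies over pooled within-trial transitions — never across the
inter-trial reset — with no bias correction: the datasets are tiny and
complete by design, and on an exhaustively sampled deterministic process
the plug-in estimate is exact (verified to $10^{-12}$ against the catalog).
A flow is detected when TE exceeds the threshold *strictly*, so at
threshold zero "any non-zero value" counts and the exact zeros that
cryptographic logic produces count as misses. Sensory neurons remain valid
*destinations* for scoring: no true edge can point at them, so any TE mass
there is a false alarm — the causally impossible backward flows one sees
in practice. Hit rate is hits over true edges; false-alarm rate is false
alarms over true non-edges (influence maps are sparse, so raw false-alarm
counts can exceed hits while the false-alarm *rate* stays low).

The ROC staircase scans 101 thresholds across $[0, 1]$. The binormal fit
models TE given edge / given non-edge as two Gaussians with sample
moments; the fitted curve is
$f(x) = \Phi\!\big((\mu_1 - \mu_2 + \sigma_2 \Phi^{-1}(x)) / \sigma_1\big)$,
rising through $(0,0)$ and $(1,1)$ and collapsing to $f(x) = x$ when the
two classes coincide. If either class has zero variance the fit refuses
and directs you to the empirical curve. (Equivalent erfc forms of this
curve are typeset ambiguously in places; the implementation follows the
Gaussian model itself, which fixes both the sign and which $\sigma$
divides.)

## Numerical choices and limitations

* Probabilities are exact ratios of small integer counts; no smoothing or
  bias correction anywhere. Zero-probability states contribute zero.
* Fitness ties in selection and elitism break deterministically (earliest
  index), and all stochastic steps flow through R's seeded generator, so
  every result in the package is reproducible bit-for-bit.
* A TE that is exactly zero is reported as zero; the package deliberately
  does not distinguish structural zeros from sampling zeros and ships no
  significance test (surrogate-data nulls are out of scope).
* The per-gate misestimate aggregation ignores in-circuit input
  distributions and network effects (recurrence, transitivity); the
  recordings pipeline measures those effects instead, which is why both
  exist.
* Gates are deterministic and binary with exactly two inputs; probabilistic
  gates, wider gates and longer histories are out of scope.

## A worked pass through the pipeline

```{r}
solver <- build_named_fixture("sl_solver")$brain
fa <- flow_analysis(solver, sl_task())
fa$detection
glance(fit_gaussian_roc(
  te_values_by_truth(fa$te, fa$truth)$edge,
  te_values_by_truth(fa$te, fa$truth)$nonedge
))
```

Even this hand-built, perfectly regular circuit shows the signature
pattern: most true edges are detected (12 of 14 here), a couple are
missed outright, and stimulus autocorrelation across the short trials
smears influence onto forty neuron pairs with no connection at all —
including lag-2 "edges" that skip over the real delay line. The false
alarms outnumber the hits even though the false-alarm *rate* is modest,
because true non-edges vastly outnumber edges. On evolved cohorts the
effect is stronger and task-dependent, which is the study's central
observation.
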