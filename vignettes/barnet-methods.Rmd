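---
title: "Models and methods behind barnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind barnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barnet)
library(data.table)
```

# The problem

Barcoded rabies-virus tracing reads out neuronal connectivity by
sequencing. A glycoprotein-deleted rabies library carrying random 20-nt
barcodes is injected; cells expressing TVA and the glycoprotein in trans
("source cells") are infected and pass their barcode retrogradely to
their presynaptic partners. Cells that share a barcode form a
*barcode-sharing network*, and in the ideal case each network is one
source cell plus its presynaptic inputs. Reality is messier, and the
whole point of the quantitative machinery in this package is to say *how*
messy and what can still be inferred:

* barcodes are reused across the library with very unequal frequencies,
  so two source cells can be infected independently with the same
  barcode (**double-labeled** networks);
* glycoprotein-expressing cells synapse onto each other, so a barcode
  can hop between candidate source cells (**connected-source**
  networks);
* the virus occasionally infects glycoprotein-negative cells directly,
  producing barcodes with no source at all (**no-source** networks,
  characteristically tiny);
* roughly half of source cells die before sequencing, leaving sizeable
  networks with a missing source (**lost-source** networks).

A parallel application is multiplexed retrograde mapping: two libraries
with disjoint barcode sets are injected into two projection targets and
cell bodies are assigned to targets by matching their barcodes to the
libraries.

# Statistical models

## Barcode multiplicity

If a barcode has library frequency $f$ and an experiment comprises $n$
independent infection events, the number of events involving that
barcode is $X \sim \mathrm{Binomial}(n, f)$. `multiplicity_prob()`
evaluates $P(X \ge m)$ on the stable upper tail. At $n = 1000$ and
$f = 10^{-3}$, $P(X \ge 2) \approx 0.26$ while
$P(X \ge 7) \approx 8 \times 10^{-5}$ — which is why no-source networks
are common but *large* no-source networks are vanishingly rare, and why
network size is a usable classifier between no-source and lost-source
networks (boundary: 5 cells, `build_networks()`).

## The infection-count posterior

Observing $M$ unique barcodes among source cells is consistent with any
number $N \ge M$ of infections. With $C$ the number of distinct
source-cell/barcode combinations (an upper bound for $N$: every
infection produces one combination, and transsynaptic spread between
source cells only adds more), `infection_posterior()` places a uniform
prior on $N \in [M, C]$ and computes

$$P(N \mid M) \propto P(M \mid N),$$

where $P(M \mid N)$ is the probability that $N$ draws by library
frequency contain exactly $M$ distinct barcodes. This occupancy
probability has no tractable closed form for heterogeneous frequencies,
so it is estimated by Monte Carlo (default 2000 replicates per support
point); for libraries of at most 12 barcodes an exact
inclusion-exclusion enumeration is used instead, and serves as the
testing oracle for the Monte-Carlo path. The 95% interval is the central
interval of the cumulative posterior (the source text does not state
central vs highest-density; central is reproducible and monotone).

`decompose_ledger()` then splits $C$ into single-source barcodes
(observed), double-labeled pairs ($\hat N - \text{singles}$), and
connected-source pairs ($C - \hat N$). The three parts add up to $C$ by
construction.

## The single-infection frequency threshold

`single_infection_threshold()` answers: below which library frequency is
a barcode overwhelmingly likely to represent a single infection? Each
replicate draws barcodes by frequency until the observed number of
distinct barcodes is reached, records the number of draws $N_r$, and
solves for the largest $f$ with $P(X \ge 2 \mid X \ge 1) \le 0.05$,
$X \sim \mathrm{Binomial}(N_r, f)$. The conditional form is our
formalization of "ensures single infection for 95% of barcodes" — the
statement is about barcodes that appear at all; an unconditional variant
is available (`conditional = FALSE`). Medians across replicates are
reported.

## Convergence bias

For each filtered network, every unordered pair of presynaptic members
is one "converging pair" (both cells synapse onto the same target cell).
Pairs accumulate into a subclass-by-subclass matrix $O$. The expected
matrix under label-independent membership uses abundance weights —
$n_A^2$ on the diagonal and $2 n_A n_B$ off it, scaled so total expected
pairs equal total observed pairs. The off-diagonal factor 2 is forced by
the convention that $O_{AB}$ carries the *full* A–B pair count: with
equal subclass abundances, label-independent data have
$O \propto (1, 2, 1)$ over (AA, AB, BB) and a flat bias ratio
$R = O/E = 1$. A combinatorially exact variant
(`diagonal = "choose"`: $\binom{n_A}{2}$ and $n_A n_B$) is available and
is verified in the tests against brute-force pair enumeration; the two
differ only by $n$ vs $n-1$ on the diagonal.

Significance comes from permuting subclass labels over the pooled
participating cells (which preserves network sizes and the global
subclass composition) and doubling the fraction of iterations at least
as extreme as the observation in its direction, clipped at 1. Ties count
as extreme; a $+1$ pseudo-count floor is off by default.

## Retrograde variance decomposition

For an injection target, $P_{ct}$ is the fraction of type-$t$ cells in
cubelet $c$ (a ~110 µm-wide, full-depth cortical parcel) assigned to the
target. With $M$ the grand mean and $TV = \sum_{ct}(P_{ct}-M)^2$, the
variance explained by a grouping is the *unweighted* sum of squared
deviations of group means, e.g.

$$VE_{\text{type,area}} = \sum_{t}\sum_{a}
  \bigl(\operatorname{mean}_{c \in a} P_{ct} - M\bigr)^2 / TV .$$

These formulas are implemented literally, which has a counter-intuitive
algebraic consequence worth knowing: if $P_{ct}$ depends on type alone,
$VE_{\text{type}} = 1/n_{\text{cubelets}}$, not 1 (each of the
$n_{\text{cubelets}}$ cells of a type-column contributes to $TV$ but the
group-mean sum collapses it once). A size-weighted one-way-ANOVA variant
(`mode = "weighted"`), which does return 1 in that case, is provided for
sensitivity analysis; the unweighted form stays the default because it
is what the formulas say. Undefined entries (cubelets with no cells of a
type) are excluded from every mean and from $TV$, never imputed as 0.

### Why the default significance test is not a t-test

The historical recipe compares the observed $VE_{\text{type,area}}$ to
100 area-shuffled recomputations with a one-sample t-test. That test
asks whether the *mean* of the shuffled sample equals the observed value
— its standard error shrinks with the number of shuffles, so under the
null hypothesis (no area structure) it rejects far more than 5% of the
time once the shuffle count is moderate. We therefore default to the
empirical two-sided permutation p-value (twice the fraction of shuffles
at least as extreme, clipped at 1), which is calibrated by construction,
and keep the t-test available as `test = "t"` for comparability.

# Barcode quality control

* **Linguistic sequence complexity** rejects degenerate basecalls:
  $C = \prod_{n=1}^{M} U_n$ with
  $U_n = \#\{\text{distinct } n\text{-grams}\} / \min(4^n, M-n+1)$
  (overlapping n-grams). A 15-nt homopolymer scores
  $1/(4 \cdot 14!) \approx 4 \times 10^{-12}$, far below the $10^{-0.9}$
  acceptance threshold; maximally diverse sequences score 1.
* **Within-cell error correction** merges barcodes within Hamming
  distance 2 into the more abundant barcode of the same cell, walking
  barcodes in descending count order with lexicographic tie-breaks (the
  source text fixes the rule but not the order; a deterministic order is
  required for reproducibility, and the lexicographic tie-break is
  arbitrary but stable). Passes repeat to a fixed point, making the
  operation idempotent.
* **Calling profiles**: a call needs at least 8 reads of the barcode
  (transsynaptic in situ profile) or 6 (retrograde profile), plus the
  complexity test. There is deliberately no default `min_count` —
  the threshold is an experiment property.
* **Roles**: barcoded cells with ≥2 glycoprotein transcripts are
  candidate sources (the conservative threshold; ≥12 matches
  fluorescence-defined sources and is exposed as the
  `conventional_g12` profile), cells with exactly 1 are excluded as
  unclassifiable, and 0 marks presynaptic candidates.

# The synthetic world

`simulate_transsynaptic()` generates experiments under exactly the
generative assumptions the inference makes, with ground truth. Its
defaults are a *stated world* anchored to the published experiment, not
tuning knobs:

| parameter | default | anchor |
|---|---|---|
| `n_library_barcodes` | 13,211 | library size |
| `library_skew_sigma` | 2.0 | top ~14% of barcodes carry ~82% of mass (closed form via `skew_sigma_for_mass()`) |
| `p_source_death` | 0.5 | "around half of source cells died" |
| `presyn_mean`, `presyn_dispersion` | 12, $12^2/(14^2-12)$ | 12 ± 14 cells per barcode |
| `p_direct_infection` | 0.75 | ≈429 no-source barcodes vs ≈137 glycoprotein+ infections |
| `p_intersource_connection` | 0.0022 | ≈0.66 connected partners per source (50 connected pairs / 76 infections, 300 candidate cells) |
| `n_infections` | 600 | sum of implied infection events |
| `g_count_source_mean` / `g_count_leak_mean` | 8 / 0.07 | most sources comfortably ≥2 transcripts; ~6% of bystanders show leaky expression (186/2914 barcoded cells had exactly one transcript) |
| `per_base_error` | 0.01 | typical in situ basecalling error |

Secondary spread from a connected source uses the same negative-binomial
family scaled by 0.5 (tertiary infections start later and are smaller;
the scale is configurable). Dead sources spread normally before removal
— death hides the source, not its spread; an optional necrosis-spread
mode (off by default) additionally scatters barcodes from dying cells.
Glycoprotein counts are Poisson in both modes; thresholding is
downstream's job. All randomness flows from the single `seed` in the
configuration; nothing depends on the caller's RNG state.

Ground truth records, per barcode, both the *generative* five-class
label (which mechanism built the network; precedence connected-source >
double-labeled > lost-source > single-source when mechanisms co-occur)
and the *observable* four-class label (what a perfect classifier of the
surviving cells would report). The distinction matters: a double-labeled
network that lost one source *is* observably single-source, and no
classifier can do better than the observable label. Accuracy claims in
the tests are against the observable label; mechanism-toggle claims
("no death ⇒ no lost-source networks") are against the generative
label.

What the generator does **not** emulate: imaging (optics, rolony
segmentation), gene-expression counts beyond per-cell totals and the
glycoprotein channel, spatial axon geometry, and any spatial correlation
in connectivity. A green test therefore establishes that the inference
is correct *under its own model assumptions* at realistic parameter
values — not that those assumptions hold in tissue.

`simulate_retrograde()` labels each cell independently per library with
an (area, type)-dependent probability and draws its barcode by library
frequency; `assign_cubelets()` bins the synthetic cortex into 110-µm
mediolateral cubelets (real cubelets are hand-drawn and arrive as an
input column).

# Numerical and design choices

* Hamming matching compares the first 15 sequenced bases against library
  barcodes truncated to the same prefix; matches allow 1 mismatch;
  queries within reach of more than one library are a distinct
  `ambiguous` outcome and never silently assigned.
* Barcodes absent from the library table are treated as frequency-0
  (non-repetitive) in collision statistics and *retained* by the
  convergence frequency filter: the library was sequenced shallowly, and
  an unsequenced barcode is a rare one.
* UMI counting deduplicates exactly by default; optional directional
  1-mismatch merging is available for deeply sequenced libraries.
  N-containing windows are rejected, not imputed.
* The posterior's Monte-Carlo error propagates into the mode and CI;
  2000 replicates per support point give stable results for the
  published problem geometry, and the exact enumerator bounds the error
  in tests.
* Empty denominators (`P_ct` with no cells, zero-likelihood posterior
  supports, zero-variance decompositions) raise errors rather than
  returning NaN silently.

# Known limitations

* The network classifier cannot distinguish a ≥5-cell no-source
  collision network from a lost-source network; at the published library
  skew this confuses ~1–2% of networks (the <5-cell rule is a bound, as
  in the source analysis).
* Connected-source versus double-labeled status is identifiable only in
  aggregate (the ledger), not per network.
* `single_infection_threshold()` inherits the library table's
  truncation: frequencies are conditioned on the sequenced 82% of the
  mass.
* The permutation test treats cells carrying two filtered barcodes as
  independent members of each network (distinct barcodes are distinct
  convergence observations).
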