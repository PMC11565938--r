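---
title: "Sample-specific parameter advising for transcript assemblers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-specific parameter advising for transcript assemblers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmtune)
```

## The problem

Transcript assemblers such as Scallop and StringTie2 reconstruct
full-length transcripts from aligned RNA-seq reads, and their accuracy
depends strongly on tunable parameters: Scallop exposes 18 of them,
StringTie2 eight (`builtin_space()`). A single default setting is rarely
optimal across the diversity of real samples, but optimizing the
parameters per sample is expensive — every evaluation of a candidate
parameter vector means a full assembler run. `asmtune` implements a
transfer-learning answer: spend the optimization budget once on a set of
*representative* samples, learn an embedding of samples in which
proximity means "similar optimal parameters", and then advise any new
sample in seconds by looking up the best parameters of its nearest
representatives.

The objective being optimized per sample $R$ is
$f_R(\theta) = \mathcal{L}(\mathcal{A}(R;\theta))$, where
$\mathcal{A}$ is the assembler and $\mathcal{L}$ is the negative area
under the precision–sensitivity curve (AUC) of the assembly against a
reference annotation. The advisor $\mathcal{M}$ maps a sample to a small
set of candidate parameter vectors; the oracle
$\mathcal{O}_\mathcal{M}(R) = \arg\min_{\theta \in \mathcal{M}(R)} f_R(\theta)$
evaluates the candidates and keeps the best.

## Assembly evaluation

A predicted multi-exon transcript is counted correct when its ordered
intron chain exactly matches a multi-exon annotation transcript on the
same chromosome and a compatible strand; terminal exon ends are ignored.
A single-exon prediction is correct when it overlaps at least 80% of the
length of a single-exon annotation transcript; the threshold is a
configurable argument (`single_exon_frac`) and the comparison is
one-sided against the *reference* length, following the conventions of
the standard comparison tooling. Matching is one-to-one — each
annotation transcript validates at most one prediction, so duplicated
predictions cost precision. Predictions claim references greedily in
decreasing abundance order, which makes per-transcript correctness
consistent across every abundance cutoff of the curve sweep.

The precision–sensitivity curve ranks predictions by abundance and
sweeps a cutoff over the distinct abundance values; equal-abundance
transcripts enter and leave together. The AUC integrates precision over
sensitivity with the trapezoid rule between consecutive points, plus the
rectangle from sensitivity zero to the first point at that point's
precision. Whether the curve should instead be anchored at precision 1
is genuinely underdetermined; the choice here is documented, covered by
an independent sweep oracle in the tests, and switchable
(`auc(..., anchor = "none")`). A `min_coverage` cutoff can drop
low-abundance predictions before evaluation; 0 is used for evaluation
by default, with the assembler defaults (1.01 for Scallop, 1.0 for
StringTie2) available.

## CAWarm-BO

Per-sample optimization is a two-phase procedure over a mixed
binary/integer/float space.

**Domains.** Every non-binary parameter starts with the range
$[0, 10\times\text{default}]$ (integers on the lattice); binary
parameters are $\{0,1\}$. After the warmup returns an incumbent
$\hat\theta$, each range is reset to $[0, \max(2\hat\theta_i, U_i)]$
with $U_i$ the initial upper bound — the domain can grow toward an
incumbent sitting near its boundary but never shrinks below the initial
range.

**Warmup.** Deterministic coordinate ascent from the assembler
defaults: coordinates are visited in registry order; each visit probes
one step up and one step down (binary: a flip) and then keeps walking in
the better improving direction while the loss improves. A full pass with
no improvement stops the warmup; otherwise it runs to its evaluation cap
(default 60 evaluations). Step sizes are part of the registry
(`warmup_step`); the shipped convention is a fifth of the default
(floored at 1 for integers, at 0.1 for small floats), and users can
override it per parameter. A coordinate whose probes both fail during an
otherwise-productive pass has its step halved.

**BO phase.** A Gaussian-process surrogate is refit on the full trace
each step: a Matérn-5/2 kernel with a shared length scale on min–max
scaled non-binary coordinates, multiplied by a categorical-overlap
(Hamming) kernel on binary coordinates, with signal and noise variances
estimated by marginal likelihood (re-optimized every `refit_every = 10`
evaluations from a fixed set of starts; losses are standardized before
fitting). Repeated query points are collapsed to their mean loss before
fitting so the noise-free kernel matrix stays well conditioned. The next
query maximizes expected improvement over a seeded candidate set —
uniform draws over the domain plus local perturbations of the incumbent
at two scales (10% and 2% of each range) — projected onto the
integer/binary structure and excluding already-evaluated points. The
total budget (default 200 evaluations, warmup inclusive) counts every
objective evaluation; "iteration" always means one evaluation, which
makes the budget arithmetic exact and testable. The incumbent is the
earliest trace record attaining the minimum, so ties favor older
evaluations, and since the defaults are evaluated first the result is
never worse than the defaults.

This is a generic mixed-space GP-BO; it deliberately does not reproduce
any particular trust-region implementation. Any optimizer satisfying the
same budget and domain contracts could stand behind `cawarm_bo()`.

## Trace-based similarity between samples

Two samples should be called similar when their loss landscapes are
similar. Landscapes are not available in closed form, but each
representative's BO trace supports a GP estimate $\mu_i$ of its
landscape. The *normrank* statistic is the fraction of sample $i$'s
queried points whose posterior mean is strictly below the posterior mean
at sample $j$'s optimum:

$$\mathrm{normrank}(R_i, R_j) =
  \frac{|\{\theta_g : \mu_i(\theta_g) < \mu_i(\hat\theta_j)\}|}{|\mathcal{X}_i|}.$$

If $j$'s optimum is near-optimal for $i$ too, few points beat it and the
value is small. Strict inequality is used, so exact ties (including a
constant posterior) contribute zero. Foreign optima are clipped into the
evaluating sample's domain before querying the GP, bounding
extrapolation.

normrank is neither symmetric nor a metric, so the pipeline symmetrizes
by averaging with the transpose, forces the diagonal to zero (GP
smoothing can leave $\mu_i(\hat\theta_i)$ slightly above other trace
points, so the zero diagonal is imposed rather than assumed), repairs
the matrix to a metric with all-pairs shortest paths (dense
Floyd–Warshall; repair is idempotent and never increases an entry), and
maps distances to similarities by $\hat S = 1 - 2\hat D \in [-1, 1]$ —
the range of the cosine similarity the encoder is trained to match.

## Sketches and the set encoder

Samples enter the encoder as MinHash sketches: canonical $k$-mers
($k = 21$) are counted, $k$-mers seen fewer than `min_count = 2` times
are dropped, survivors are hashed with a seeded 64-bit hash (truncated
to 53 bits so values are exact in doubles), and the $s = 1000$ smallest
hashes are kept with their counts. Both dimensions (hash value, count)
are z-score normalized with statistics pooled over the *training
corpus*, not per sample — per-sample normalization would destroy the
cross-sample comparability of hash values; the statistics are persisted
and applied unchanged to new samples.

The encoder is a DeepSets composite
$\mathrm{Enc}(X) = g\!\left(\tfrac1s \sum_i h(x_i)\right)$ with
fully-connected subnets of widths $(2,128,128,128,128)$ and
$(128,256,256,256,64)$, ReLU activations and batch normalization before
every activation except after the last layer of each subnet. Mean
pooling makes the output permutation invariant; at inference the
implementation additionally sorts set elements canonically so the
floating-point sum is bitwise identical under permutation. Batch-norm
statistics during training are pooled over all rows of the minibatch
(all set elements across the batch for $h$, all samples for $g$), the
convention of standard deep-learning batch-norm layers; inference uses
running statistics, which is what makes the invariance exact. The
network and its training loop (Adam, learning rate $10^{-3}$, batch 128,
400 epochs at full scale) are implemented in plain R matrix code with
hand-derived backpropagation, verified against finite differences in the
test suite.

Training minimizes a contrastive regression loss: the mean squared error
between all pairwise cosines of the batch embeddings and the
corresponding $\hat S$ entries, diagonal included (it contributes zero
for well-formed labels). No temperature or other contrastive
hyperparameter exists.

**Augmentation.** Each representative is subsampled at ratios
0.65–0.95 in steps of 0.05 (per-read Bernoulli retention, seeded),
yielding seven variants and an eightfold corpus without any further BO.
Variants inherit their parents' pairwise labels; two members of the
*same* family (a parent and its subsamples, which proxy the same
objective) get label 1 — the cross-parent rule does not cover this pair,
so the value is an explicit design choice.

## Advising

Representative embeddings, best parameter vectors and losses are cached
in an index (recomputing embeddings per query would give identical
results at higher cost). A new sample is sketched, normalized with the
stored statistics, embedded, and matched to its $p$ most similar
representatives by exact cosine scan (ties broken by stable index
order); the advisor set is the list of their best parameter vectors,
duplicates retained. With an objective available, `oracle_pick()`
evaluates all candidates and returns the argmin (earliest on ties), so
the oracle loss is monotone non-increasing in $p$. The field's usual
set sizes are $p \in \{1, 5, 30\}$.

Representative-sample *selection* is out of scope: the trainer accepts
whatever sample table it is given, and a low-AUC filter (best AUC below
$3\times10^{-4}$) drops representatives whose traces carry no usable
signal.

## The synthetic universe

`make_universe()` generates the study conditions for every test that
needs data: groups of samples share a planted optimal parameter vector,
and reads of same-group samples are drawn from a shared group reference
sequence (with per-sample point mutations), so k-mer similarity is
correlated with objective similarity — the premise the advising pipeline
exploits. The per-sample objectives are `synthetic_objective()`
instances: per-coordinate heavy-tailed (Cauchy-shaped) bumps centered on
the group optimum, with a small secondary bump three length scales away
and a mean/product mix across coordinates. Heavy tails keep a usable
improvement signal across the whole $[0, 10\times\text{default}]$
domain (a Gaussian bump underflows to an exact plateau at long range,
which would make any budget-bounded optimizer's success a matter of
luck); the secondary bump creates shallow local optima so the BO phase
has work to do after coordinate ascent; the product term makes the
landscape non-separable. The global minimum value is exactly $-1$ at the
planted optimum, which gives recovery tests an absolute yardstick.

What the generator does *not* emulate: read error models, splice
isoforms, coverage biases along transcripts, or any real assembler's
behavior. Passing tests therefore demonstrate that the pipeline's
machinery — budget accounting, similarity recovery, embedding geometry,
retrieval — behaves as specified under its stated assumptions, not that
any particular accuracy is reached on real RNA-seq data. Driving a real
assembler goes through `external_assembler_objective()`, which shells
out to the assembler binary and scores its GTF output.

## Numerical choices and scales

* GP: jitter $10^{-8}$ on the kernel diagonal; estimated noise floored
  at $10^{-8}$; hyperparameters bounded in $[10^{-4}, 10^3]$ on their
  native scales; three fixed optimizer starts.
* Expected improvement falls back to the posterior-mean improvement when
  the predictive standard deviation underflows; if the GP fit fails
  (degenerate trace), the step falls back to a seeded random feasible
  point.
* Mash distance: the Jaccard estimate uses the bottom-$s$ sketch of the
  union; a zero estimate saturates the distance at 1.
* All randomness is drawn from private, seeded RNG streams that save and
  restore the caller's `.Random.seed`, so library calls never perturb
  user code.
* Persistence: traces, similarity matrices and index tables are
  tab-separated text with doubles written at 17 significant digits;
  encoder weights and sketches are JSON at the same precision, so a
  reloaded index advises bit-identically.

The test suite runs everything at desk scale, chosen once as realistic
miniatures of the full procedure: 2–3-coordinate parameter spaces,
universes of up to 4 groups × 6 samples with ~100 kb of reads total,
sketches of 100–1000 hashes, encoders of widths 16–32 trained for tens
of epochs, and BO budgets of 14–200 evaluations. The published full
scale (1000+ representatives, 400 epochs, 128-wide subnets) is reached
by changing configuration values only.

## Known limitations

* The GP uses one shared length scale across non-binary coordinates;
  strongly anisotropic landscapes would profit from ARD at the cost of a
  harder marginal-likelihood problem.
* Floyd–Warshall repair is dense $O(m^3)$ — fine to a few thousand
  representatives, not beyond.
* The encoder runs on CPU in base R; it is deliberately sized for
  desk-scale corpora. At the published scale a GPU framework would be
  the right backend for the same architecture.
* `match_single_exon`'s 80% rule is one-sided by reference length;
  reciprocal-overlap semantics, used by some other tools, would score
  long predictions differently.
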