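---
title: "Protein abundance inference from fluorosequencing reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein abundance inference from fluorosequencing reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorEM)
```

## The measurement process and its abstraction

Fluorosequencing reads out partial sequence information from single peptide
molecules: proteins are denatured, digested (trypsin: cleavage after K or R
unless followed by P, zero missed cleavages), and selected residues are
coupled to fluorescent dyes — by default three channels targeting {D,E},
{C} and {Y}. Peptides are immobilized and imaged across repeated Edman
degradation cycles, each of which removes one N-terminal residue. A read is
the channels × timepoints intensity matrix of one molecule; by default an
initial pre-Edman image is included, because the initial dye count is
informative and standard in published classifiers (it can be switched off
in `error_model()`).

Peptides that share the same per-position dye pattern are indistinguishable
and collapse into one *fluorescence string*. `fluorEM` canonicalizes a
string as its label-code vector truncated after the last labeled position;
the dye-free null string `f_null` is kept at index 1 of the universe but is
experimentally unobservable. Proteins and strings are indexed 1-based in
first-appearance order throughout, including in serialized files.

## Observability and the indicator transform

A string with $N_d$ labeled positions survives dye attachment with
probability $1 - m^{N_d}$, where $m$ is the per-dye dud rate (default
0.07). This factor has the right limiting behavior — it vanishes exactly
for `f_null` ($N_d = 0$), which can never be seen — and it is the weight
with which each peptide's ideal string enters the model. `build_model()`
normalizes these weights within each protein to get the conditional
observable-string distribution $P(f \mid y)$ (rows sum to 1, null column
identically 0), and accumulates them into the expected observable-string
yield per molecule, $E_{F^\circ}(y)$. Duplicate peptides are counted with
multiplicity: this is required for the mixture
$P_{F^\circ}(f) = \sum_y P(f\mid y)\, q_y$ to equal the simulator's
empirical string frequencies.

Protein abundances $p$ and the per-read protein indicator distribution $q$
(the chance that a random read originates from protein $y$) are linked by
$q_y \propto E_{F^\circ}(y)\, p_y$. The worked two-protein example —
$p = (0.5, 0.5)$, $E_{F^\circ} = (7.5, 2.5)$ gives $q = (0.75, 0.25)$ —
is `protein_to_indicator(c(.5,.5), c(7.5,2.5))`, and the inverse transform
recovers $p$ exactly. Proteins with $E_{F^\circ} = 0$ (no labelable
peptide) are kept in the model with zero indicator mass rather than being
dropped, so index bookkeeping stays explicit; `model_report()` exposes
their counts.

## The read simulator

`generate_dataset()` draws, per read, a protein from $q$ and a string from
that protein's conditional distribution, then simulates intensities under
`error_model()`. The per-read generative procedure fixes this event order:

1. each dye is independently a dud with probability `p_dud`; the read is
   conditioned on at least one functional dye (all-dud draws are rejected
   and counted in `n_rejected`, matching the observability reweighting);
2. initial blocking with `p_block_init`; initial image;
3. per cycle: detachment (`p_detach`, all dyes vanish), Edman removal
   (succeeds with `1 - p_edman_fail` unless blocked; removal deletes the
   dye at the removed position), cyclic blocking (`p_block_cyclic`),
   per-dye bleaching (`p_bleach`), image.

The within-cycle order is not dictated by the physics description alone;
it is fixed as above and every marginal per-cycle rate is verified against
its configured parameter in the test suite. With $c$ active dyes a channel
image is $\mathcal{N}(c\mu, \sqrt{c}\,\sigma)$ plus background
$\mathcal{N}(0, \sigma_{bg})$ — per-dye variances add, i.e. dyes are
treated as independent emitters; this $\sqrt{c}$ scaling is an assumption,
as is the inclusion of the pre-Edman image.

Default parameters (small-scale conditions): 11 cycles, Edman failure
0.06, detachment 0.05, bleaching 0.05, duds 0.07, blocking 0,
$\mu = 10000$, $\sigma = 1600$, $\sigma_{bg} = 66.7$ (arbitrary intensity
units). `proteome_error_model()` provides the 39-cycle whole-proteome
presets, standard and "improved chemistry" (failure rates ÷100, dye
intensity spread ÷10). True abundances are flat-Dirichlet draws
(`sample_abundances()`: normalized unit-rate exponentials), which at
proteome scale span several orders of magnitude.

Determinism: one `set.seed()` per dataset, sequential generation; the same
seed and inputs give byte-identical datasets. Pool mode (`pool_size`)
pre-simulates a shared per-string read pool and samples from it with
replacement — distributionally equivalent for fresh draws, cheaper for
replicate datasets over the same universe.

## Classifiers

**Oracle.** `oracle_posterior()` returns
$(1-e)\,\delta_{f^t} + e/|D_F|$ for error rate $e$. It is deterministic
given the truth; its expected posterior mass on the true string is exactly
$(1-e) + e/|D_F|$, and for any $e < 1$ its top-1 choice is always correct
— error enters EM through the flattening of the posterior, not through
mislabeled argmaxes.

**Exact Bayes HMM.** `hmm_loglikelihood()` computes the exact marginal
likelihood of a read given a candidate string under the simulator's own
generative process. The hidden state is (residues removed so far, set of
still-fluorescing dyes), with every zero-dye situation — detachment, full
bleaching, complete removal — collapsed into one absorbing dark state;
transitions compose detachment, Edman success/failure (which deterministically
deletes the dye at the removed position), and binomial bleaching over
surviving dyes; emissions are the Gaussian intensity densities, evaluated
in the log domain with per-timepoint max-shifted rescaling. The dud draw
enters as the initial state distribution conditioned on at least one
functional dye, mirroring the simulator's rejection step. The state space
is capped (default $2^{12}$ dye configurations) and a capacity error asks
for pruning beyond it. Blocking is not modeled (simulations keep it at 0);
a nonzero blocking configuration triggers a warning. The test suite checks
this forward recursion against an independent brute-force enumeration of
all hidden event sequences on small instances (≤ 2 dyes, ≤ 3 cycles,
parameter grids including zeros and the standard rates) to 1e-8.

`exact_posterior()` applies Bayes' rule with a uniform string prior; the
read-wise normalizer cancels in the EM update and is never materialized.

**Sparsification.** `sparsify()` keeps the top $N_b$ strings per read
(ties broken by ascending index) and spreads the residual mass uniformly
over the whole universe; following the literal truncation convention,
retained strings also carry the residual, so the sparsified vector sums to
exactly 1. A consequence worth noting: re-sparsifying the sparsified
distribution shrinks the residual by $1 - N_b/|D_F|$, so the operation is
a fixed point on the retained set and total mass but not on the residual
itself; at $N_b = |D_F|$ it is the exact identity.

## The EM iteration

`compute_eta()` forms, per read and protein,
$\eta_{y,k} = r_k + \sum_{f \in D_F(y) \cap G_k} \hat P(f \mid x_k) P(f \mid y)$;
because conditional rows sum to 1, the uniform residual contributes exactly
the floor $r_k$, and the dense update is recovered at full support.
`em_step()` averages the responsibilities
$\gamma_{y,k} \propto \eta_{y,k} q_y$ over reads; `run_em()` is classic
batch EM — one $q$ update per full pass, accumulated over read batches in
double precision — with uniform initialization by default (custom `init`
supports using EM as a refinement step for another method's estimate).
Stopping is a fixed epoch budget (default 30) rather than a tolerance,
because the data likelihood is monotone but the external error metric is
not, and fixed-epoch trajectories are the standard way these convergence
curves are reported. Degenerate reads (zero weighted evidence) abort with
an error naming the read — they indicate a model/posterior mismatch and
should not be silently dropped. Zeros in $q$ are absorbing, so estimates
stay within the support of the initialization.

`data_loglikelihood()` is a deliberately guarded brute-force oracle
($N_r \cdot N_P \le 10^6$, dense posteriors only) used to verify the
monotonicity guarantee numerically; it computes the likelihood only up to
the read-wise classifier constants, which cancel between iterates. MAE is
computed in protein space, after the inverse indicator transform.

Aggregation: when many reads share a posterior (oracle classification
depends only on the generating string), `run_em(weights = ...)` accepts
per-posterior multiplicities; the weighted trajectory is identical to the
unweighted one and makes $10^5$-read oracle experiments effectively
instant.

## Problem sizes, defaults and what the tests show

The bundled experiments run at the five-protein scale that the framework's
small-scale validation targets: synthetic mixtures of 5 random-sequence
proteins (uniform residue composition, 60–100 aa, giving ~25 observable
strings and ≤ 7 dyes per string), $10^5$ reads per dataset for oracle
studies, $1.5\text{–}2 \times 10^3$ reads where the exact HMM classifier
is in the loop, 10 replicate datasets, 30 epochs. At these sizes the whole
validation suite completes in well under a minute apart from the HMM
blocks. Whole-proteome universes are supported by the same code paths
(sparse conditional matrix, batched EM, posterior truncation) but are not
exercised at full scale in the tests.

The synthetic generator emulates: observability-conditioned string
sampling, all five error processes, and Gaussian intensity noise. It does
not emulate: real amino-acid composition biases (uniform residues make
strings more distinguishable than real tryptic peptides — classifier
accuracies here are accordingly optimistic), missed cleavages,
post-translational modifications, dye–dye quenching, blocking (off by
default, and not modeled by the classifiers), or image-level artifacts.
Passing tests therefore demonstrate the correctness and statistical
behavior of the inference machinery under its own generative assumptions,
not performance on real instrument data. In particular, published
five-protein classification accuracies depend on the actual UniProt
sequences and the (unstated) labeling configuration; with this package's
default scheme on synthetic sequences the exact classifier reaches ~0.84
top-1 accuracy, and reproducing a specific printed accuracy requires
supplying the corresponding FASTA to the same pipeline.

## Design choices and limitations

* Eq. for observability uses $1 - m^{N_d}$ ("at least one dye attaches"),
  the only reading under which the null string's observation probability
  vanishes.
* The dud rate of the labeling model and the simulator's `p_dud` are one
  unified per-dye Bernoulli failure, exposed as a single parameter in both
  places; they should be kept equal for the conditioning to be consistent.
* Tie-breaks (sparsification sets, top-1 argmax) are stable by ascending
  string index; statistically irrelevant, but it makes runs reproducible
  to the byte.
* Emission densities with zero variance (noise-free configurations) are
  handled as point masses, so noise-free limits remain testable.
* The HMM cost grows as (peptide length) × 2^(dye count) states per
  string; beyond ~12 dyes per string the exact classifier refuses and a
  truncated/beam approximation (out of scope here) would be needed.
* No GPU or parallel path; batching exists for memory, not speed. Partial
  (within-epoch) updates are deliberately not implemented.
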