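# fluorEM

Protein abundance inference for single-molecule fluorosequencing, via
expectation maximization over peptide-level posterior estimates.

Fluorosequencing labels specific amino acids (here, by default, D/E, C and
Y on three dye channels) with fluorophores, immobilizes tryptic peptides in
a flow cell, and removes one N-terminal residue per Edman cycle while
imaging fluorescence. Each molecule yields a *read*: a channels × cycles
intensity matrix. Peptides indistinguishable by their labeled-position
pattern form a *fluorescence string* f; the dye-free string f_null is never
observed. The inference task is: given millions of reads from a known
protein database, estimate the relative protein abundances p.

`fluorEM` is aimed at method developers in single-molecule proteomics who
need a complete, testable in-silico pipeline: digestion and labeling model,
read simulator with an explicit error process, per-read classifiers, and
the EM estimator itself.

## The model

With per-dye dud rate m, a string with N_d(f) labeled positions is
observable with probability 1 − m^{N_d(f)}. Weighting each peptide's ideal
string by this factor gives, per protein y, the conditional distribution
P(f | y) over observable strings and the expected observable-string yield
E_F°(y). Abundances p and the per-read protein indicator distribution q are
linked by

    q_y = E_F°(y) p_y / Σ_l E_F°(l) p_l,

and the marginal read-generating string distribution is
P_F°(f) = Σ_y P(f | y) q_y.

Given per-read posteriors P̂(f | x_k) from any classifier that assumes a
uniform string prior, EM iterates

    η_{y,k} = r_k + Σ_{f ∈ D_F(y) ∩ G_k} P̂(f | x_k) P(f | y)
    q'_y    = (1/N_r) Σ_k η_{y,k} q_y / Σ_l η_{l,k} q_l,

where G_k is the top-N_b retained string set of read k and r_k the uniform
residual spread over the whole universe (with dense posteriors r_k = 0 and
G_k = D_F). Each iteration provably does not decrease the data likelihood.
The final q̂ is mapped back to protein space by inverting the transform
above; accuracy is reported as mean absolute error
MAE = (1/N_P) Σ_y |p̂_y − p_y|.

Two classifiers are provided:

* **oracle** — knows the true generating string and returns
  (1 − e)·δ_truth + e/|D_F| for a configurable error rate e; the e = 0 case
  upper-bounds any real classifier.
* **exact Bayes HMM** — the exact marginal likelihood P(x | f) under the
  simulator's own generative process (dud conditioning, detachment, Edman
  failure, bleaching, Gaussian intensities), computed by the forward
  algorithm over the hidden dye-survival state space, then normalized over
  the string universe.

## Worked example

```r
library(fluorEM)

proteins <- random_proteins(5, c(60, 100), seed = 12)   # synthetic mixture
model    <- build_model(proteins, label_scheme(), m = 0.07)
model
#> Proteome model: 5 proteins, 25 observable fluorescence strings (+ f_null), dud rate 0.07
#>   E_Fo range: 3.79 - 6.785

p_true <- sample_abundances(5, seed = 19)
round(as.numeric(p_true), 4)
#> [1] 0.3017 0.2716 0.1442 0.1985 0.0841

em  <- error_model()                       # 11 cycles, standard error rates
sim <- generate_dataset(model, p_true, n_reads = 2000, em, seed = 20)

post <- exact_posterior(sim$intensities, model, em)
top1_accuracy(post, sim$true_string)
#> [1] 0.8425

fit <- run_em(post, model, epochs = 30, truth = p_true)
round(rbind(truth = as.numeric(p_true), estimate = as.numeric(fit$p_hat)), 4)
#>            [,1]   [,2]   [,3]   [,4]   [,5]
#> truth    0.3017 0.2716 0.1442 0.1985 0.0841
#> estimate 0.3015 0.2546 0.1452 0.2080 0.0907
fit$mae[length(fit$mae)]
#> [1] 0.006861  (uniform-abundance guess: 0.0693)
```

The top-1 accuracy is the fraction of reads whose highest-posterior string
is the true generating string; the MAE rows show per-protein recovery after
thirty EM epochs — here a tenfold improvement over guessing uniform
abundances from 2000 reads.

A command-line interface over the same functions is installed at
`system.file("cli/fluorem.R", package = "fluorEM")` with subcommands
`build-model`, `simulate`, `classify`, `infer` and `benchmark`.

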