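---
title: "Simulating coupled sequence and regulatory-network evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating coupled sequence and regulatory-network evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnevo)
```

## The model

Classical sequence simulators evolve one sequence at a time under a
substitution model, so genes cannot influence each other's evolutionary
paths. `grnevo` instead evolves whole *organisms*: a genome of `n`
protein-coding genes of `l` base pairs each, plus a regulatory genotype —
an `n x n` interaction matrix `R` (entry `R[i, j]` is the effect of gene
`j`'s product on gene `i`), a nonnegative activation-threshold vector
`theta`, and a nonnegative decay-rate vector `lambda`.

**Development.** The phenotype is a gene-expression trajectory produced by
a deterministic discrete-time dynamical system in the tradition of
Wagner-type network models. With `q_0 = (1, 0, ..., 0)` — gene 1 seeds
development with one arbitrary unit of product — the state advances for
`m` steps as

    q_t = ( relu_theta(R q_{t-1}) + q_{t-1} e^{-lambda} ) * c

where `relu_theta` zeroes any incoming signal strictly below a gene's
threshold (a value exactly at the threshold passes: the rectifier removes
what is *below* `theta`), `e^{-lambda}` is per-step exponential decay of
existing product, and `c` is the coding mask: 0 for a gene whose current
sequence contains an in-frame stop codon anywhere, 1 otherwise. The mask
is recomputed from the sequence, so a reverted stop codon restores
expression. The columns `q_1..q_m` form the expression matrix `E`, the
phenotype on which fitness is scored. Because the seed quantity is
injected *before* the mask first applies, gene 1 counts as expressed even
when its own sequence is interrupted — it is the gene that kick-starts
development.

**Mutation and the coupling rule.** Each generation, every base mutates
independently with probability `mu` and is replaced by one of the other
three nucleotides uniformly (Jukes–Cantor; no site-rate heterogeneity, no
transition/transversion bias). Events are classified against the
pre-mutation codon as synonymous, nonsynonymous, or nonsense. Every
synonymous or nonsynonymous event then triggers **exactly one** regulatory
mutation in the gene it hit, giving a strict 1–1 link between the rates of
sequence and regulatory evolution; nonsense events change no regulatory
parameter — their entire phenotypic effect flows through the coding mask,
and the parameters remain intact awaiting a possible reversion.

A regulatory mutation in gene `g` lands on `theta[g]` or `lambda[g]` with
probability `2/(2+n)` (each `1/(2+n)`), i.e. in proportion to the share of
gene `g`'s `2+n` regulatory values those two vectors represent; otherwise
it lands in row `g` of `R`. Under this package's orientation of `R`, row
`g` holds the regulatory *inputs* of gene `g`, one per source gene. This
is a deliberate design choice: the link-targeting rule below needs a
candidate set whose *sources* vary, and a row of inputs is the only
reading under which "links whose source is expressed" distinguishes the
candidates (a column of outputs would make gene `g` itself the source of
every candidate and the rule degenerate). A nonsynonymous event mutates a
link whose source gene is expressed in the **parental** expression matrix
(an active link — the change is visible to selection); a synonymous event
mutates a link whose source is silent (an inactive link — a hidden change
that only matters if the source is later activated). Structurally zeroed
cells stay mutable, so network topology itself evolves. If the required
link class is empty, the mutation is redirected to `theta[g]` or
`lambda[g]` with equal probability, preserving the 1–1 coupling.

The mutation kernel resamples the chosen parameter uniformly from its
initialisation range. Resampling keeps every parameter inside its
declared range forever and makes the mutated value distributionally
indistinguishable from a fresh draw; an additive-Gaussian kernel
(`kernel = "perturb"`) is available for users who prefer local moves.

**Fitness.** Four criteria score the expression profile, each in [0, 1]:

* *Boundedness* — quantities must not grow without limit. We use the
  terminal growth ratio `g` = (total quantity at step `m`) / (total
  quantity one stability window earlier): 1 for `g <= 1`, declining
  linearly to 0 at `g = 1 + growth_cap`. A ratio test is robust and
  cheap, and runaway (non-finite) development scores 0 outright.
* *Participation* — the fraction of genes expressed: the more genes active
  in the system, the fitter the organism.
* *Stability* — `1 / (1 + mean CV)`, the coefficient of variation taken
  per expressed gene over the final fifth of development. Late-window
  dispersion is what separates an attractor from a transient; genes never
  expressed are excluded so a silent gene neither helps nor hurts here
  (it already costs participation).
* *Maturity* — 1 iff a designated marker gene exceeded
  `maturity_threshold` at some step *and* is still expressed at step `m`.
  The marker defaults to the last gene: with gene 1 seeding development
  and gene `n` marking completion, both ends of the network are required
  for a viable system.

Total fitness is the product of the four. A product makes maturity a hard
gate and any catastrophic failure fatal, which is the strictest reading of
"all four criteria must be met"; the components are also reported
separately in every trace, so users can recombine them if they disagree.

**Evolution.** A generational genetic algorithm with clonal, haploid,
recombination-free reproduction and constant population size `N`. Each
generation `k = ceiling(p N)` survivors are chosen — the fittest `k` under
`"high_pressure"` (ties broken uniformly at random to avoid index bias),
or `k` uniform draws under `"relaxed"`, the neutral control — and `N`
offspring are allocated to survivors round-robin, so each survivor parents
`floor(N/k)` or `ceiling(N/k)` clones. Offspring that drew zero mutations
are exact copies; since development is deterministic, their parent's
expression matrix and fitness are reused rather than recomputed (the
recomputation would be bit-identical). Any organism that did mutate is
re-developed and re-scored in full.

**Phylogeny.** A Newick tree drives the run; branch lengths are
*generation counts* and must be nonnegative integers — generations and
mutation rate are deliberately separate inputs rather than fused into a
substitution-distance branch length. The root founds a population,
branches are simulated one at a time, and the end-of-branch population is
copied to found each child branch, so sister lineages share their
ancestor's exact state. Any parameter can be overridden per branch.

## Randomness and reproducibility

All randomness flows from one master seed. Each branch (and each
acceptance replicate) derives its own stream by hashing the master seed
with a stable label — for branches, the sorted set of descendant tip
labels. Two consequences: a run is bit-reproducible from `(config,
master seed)`, and results do not depend on the order in which sibling
branches are written in the Newick string.

## Default study conditions

The defaults of `sim_params()` reproduce the proof-of-concept regime of
the method: 5 genes of 3000 bp, `mu = 5.33333e-6` per base per
generation, selection proportion `p = 0.1`, traces sampled every 100
generations. Over 20,000 generations this rate is expected to produce
patristic distances of `mu x 20000 = 0.1066666` substitutions per site in
the absence of selection, which is the package's headline calibration
target (`expected_neutral_divergence()`).

Values the method leaves to the user were fixed once, on the reasoning
below, and are not tuned per run:

* `m = 20` developmental steps — enough for a 5-gene cascade to traverse
  the network several times and settle, while keeping development cheap
  inside the innermost loop.
* `value_range = (-2, 2)` — symmetric around zero so repression and
  activation are equally likely, wide enough that a single link can carry
  a super-threshold signal.
* `sparseness = 0.5` — founder networks are half-empty, leaving real room
  for topology to evolve in either direction.
* `theta_range = (0, 1)`, `lam_range = (0, 2)` — thresholds on the scale
  of the seed quantity; decay spanning near-persistence (`e^{-0} = 1`) to
  near-total turnover per step (`e^{-2} ~ 0.14`).
* `maturity_threshold = 0.5`, `growth_cap = 10` — the marker must
  accumulate half a seed unit; growth beyond ~11x per window is treated
  as fully unbounded.
* `N = 100` founders drawn independently (not clonally), so founder
  populations carry standing variation in which genes are expressed —
  some genes start active in only a small fraction of organisms. Clonal
  founding is available as an option.

## What the simulations show — and what they do not

The package's validation runs are synthetic by construction and sized for
a desktop. The neutral calibration evolves two independent lineages of
1,000 generations at `mu = 5.33333e-5` — ten times the headline rate over
a tenth of the generations, preserving the expected product 0.1066666 —
over 20 replicates, and checks the mean Jukes–Cantor-corrected tip-to-tip
distance against it. The selection contrast uses 2 genes x 300 bp,
`N = 50`, 1,000 generations, `mu = 1e-4` (the rate scaled up as the
genome scales down, keeping the per-genome event rate comparable), 20
replicates per strategy. Topology recovery uses a symmetric 4-tip tree of
500-generation branches at the calibration rate and asks neighbor-joining
trees built per gene to match the input topology.

Passing these says the mutation process is calibrated, the coupling
bookkeeping is exact, selection responds to the fitness function, and the
branch runner transmits phylogenetic signal. It does *not* say the model
reproduces real genomes: there are no indels, duplications,
recombination, or diploidy; regulation is purely transcriptional, one
isoform per monoexonic gene; expression is deterministic (no intrinsic
noise); and fitness is an explicit function of the expression profile
rather than an environment.

## Numerical choices and degenerate inputs

* Threshold boundary: `>=` — a signal exactly at `theta` passes.
* Development runs in double precision; a non-finite quantity flags the
  organism as runaway (boundedness and stability 0, hence fitness 0)
  instead of crashing the run.
* The boundedness denominator carries an epsilon (`1e-12`) so an all-zero
  reference step cannot divide by zero.
* An expressed gene whose late-window mean is zero contributes CV 0.
* `p >= 0.75` is rejected by the Jukes–Cantor correction as saturated.
* Branch lengths within `1e-8` of an integer are accepted as that
  integer; anything else is rejected, not rounded.
* Tie-breaking in truncation selection, offspring allocation, and the
  empty-link-class fallback are all documented above; each was a genuinely
  open choice and the simplest unbiased rule was taken.

## Known limitations

Runtime grows linearly in `N`, generations, and total genome length;
large `R` entries with sub-unity decay can legitimately produce runaway
trajectories, which the fitness function penalises but the neutral
(relaxed) regime happily fixes in a population — as in any neutral
process, broken systems drift. Under long neutral runs, genes outside the
working network accumulate stop codons; representative tip sequences are
taken from the fittest organism, so under relaxed selection the
"representative" is an arbitrary member of a drifting population.

## A worked example

```{r, eval = FALSE}
library(grnevo)
params <- sim_params(n = 5, l = 300, m = 20, mu = 1e-4, N = 50, p = 0.1)
plan <- parse_newick_generations("((A:200,B:200):100,(C:200,D:200):100);")
run <- run_phylogeny(plan, params, master_seed = 1)
distance_report(run)
stop_codon_report(run, gene = 4)
plot_fitness_trace(run$traces[["A"]])
plot_participation(run$traces[["A"]])
```
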