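---
title: "Models and methods: clines, ancestry mosaics, and the consistency of hybrid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

When two lineages hybridize, selection and recombination decide which
chromosomal segments of each parental genome survive in the hybrids.  In a
*contemporary* hybrid zone this shows up as locus-specific deviations from
genome-average introgression; in an *old or ancient* hybrid lineage — one
that stopped exchanging genes long ago and has partially "stabilized" — it
shows up as loci fixed or nearly fixed for one parent's ancestry.  If the
same loci that resist introgression today are the ones that fixed long ago,
hybrid genome composition is predictable across timescales, and those loci
are candidates for barriers to gene flow.

`clinemosaic` implements the full analysis chain needed to ask this
question, and a synthetic-data module that generates every input with known
truth so each stage can be validated by parameter recovery.

# Observation model

All inference runs on **genotype likelihoods** for biallelic SNPs, not on
called genotypes.  For individual $i$ at locus $\ell$ the data are a triple
$\mathrm{GL}_{i\ell g} \propto P(\text{reads} \mid g)$ for $g \in \{0,1,2\}$
copies of the counted allele.  Triples are normalized internally, so any
positive rescaling is irrelevant; an all-equal triple encodes missing data
and is marginalized, never dropped.  This matters at GBS-like coverage
(a few reads per site), where hard genotype calls would discard most of the
information about uncertainty.

# Stage by stage

## Allele frequencies and AIMs

Population allele frequencies are estimated by EM under Hardy–Weinberg:

$$p^{(t+1)} = \frac{1}{2n}\sum_i E\!\left[g_i \mid \mathrm{GL}_i,
p^{(t)}\right],$$

initialized at $p = 0.5$, with a convergence tolerance of $10^{-3}$ on
$\max|\Delta p|$ and at most 20 sweeps by default (both exposed).  The
observed-data log-likelihood is non-decreasing across sweeps (tested), and
the estimate agrees with a brute-force grid search of the marginal
likelihood to $10^{-3}$ (tested).

Ancestry-informative markers (AIMs) are loci where the two parental mean
frequencies differ by at least 0.3 (inclusive; 0.2 as a sensitivity
setting).  Parental means are *unweighted* across the listed reference
populations, so a small reference population counts as much as a large one.

## Ancestry frequencies in ancient hybrids

In a partially stabilized hybrid population, individuals have similar
genome-wide admixture but ancestry *frequencies* vary along the genome.
The model: each allele copy has a latent origin
$z \sim \mathrm{Bernoulli}(q_\ell)$; the allele given its origin follows
the parent-1 or parent-0 frequency; the genotype is observed through the
GL triple.  The prior on $q_\ell$ is a correlated beta process realized as

$$q_\ell \sim \mathrm{Beta}(\nu\,\mu_\ell,\ \nu\,(1-\mu_\ell)),$$

where $\mu_\ell$ is the moving average of the current $q$ over a window of
$w$ loci centered on $\ell$ (truncated at chromosome ends) and $\nu$ is a
precision.  This gives the two properties that matter — autocorrelation of
ancestry along chromosomes and freedom for $q$ to vary locus to locus —
with a conjugate, testable Gibbs update (origins given $q$; then $q$ given
origin counts, beta-binomial).  Defaults: $w = 3$ SNPs, $\nu = 10$, 10,000
sweeps with a 5,000-sweep burn-in and thinning of 10.  $\nu$ controls
smoothing strength only; with $\nu \to 0$ the sampler collapses to the
per-locus beta-binomial posterior, which is how the conjugate closed-form
oracle test works.  Loci where the two parental frequencies coincide are
unidentifiable and flagged (the posterior reverts to the prior).  Female
Z-chromosome hemizygosity (one allele copy) is supported via the
population map's `sex` column; the default treats all individuals as
diploid, matching a males-only robustness analysis.

Fixation summaries report the fraction of loci with
$\hat q \ge 0.95$ (parent-1) or $\hat q \le 0.05$ (parent-0), overall, per
chromosome, and Z versus autosomes.

## Hybrid indexes and genomic clines

The hybrid index $h_i$ is the genome-wide fraction of parent-1 ancestry,
estimated by bounded 1-D maximum likelihood with
$\pi_\ell = h\,p_{1\ell} + (1-h)\,p_{0\ell}$ and the genotype observed
through the GLs (tolerance $10^{-6}$; agreement with a grid search is
tested).

The genomic cline function maps $h$ to the locus-specific probability of
parent-1 ancestry:

$$\phi(h;\alpha,\beta) = h + 2h(1-h)\left[\alpha + \beta(2h-1)\right],$$

truncated to $[0,1]$, with $\phi(0)=0$, $\phi(1)=1$ for any parameters.
$\alpha$ shifts the cline center (directional introgression; equivalent to
twice the shift of a geographic cline center) and $\beta$ changes the rate
of transition (restricted introgression when $\beta > 0$; narrower clines).
This quadratic-in-$h$ form is exposed behind a single function so an
alternative (e.g. logit-logistic) could be swapped without touching the
sampler.

Per AIM, $\alpha$ and $\beta$ get independent normal priors (SD 1 by
default) and are updated by random-walk Metropolis, vectorized across
loci, with proposal scales tuned during burn-in toward 20–40% acceptance.
Hybrid indexes are estimated first and held fixed — a deliberate two-stage
simplification (a joint sampler is heavier and, at the sample sizes used
here, changes estimates negligibly since $h$ is informed by hundreds of
loci).  Chains are pooled after burn-in; split-$\hat R > 1.1$ on either
parameter flags a locus (reported, never dropped).  Credible deviations
are read off 95% equal-tail intervals: CI$(\alpha) > 0$ (excess parent-1
introgression), CI$(\alpha) < 0$ (excess parent-0), CI$(\beta) > 0$
(restricted).  Because deviations are defined *relative to the
genome-average gradient*, planting strong deviations at a large fraction
of loci shifts the reference itself; calibration tests therefore use a
fully neutral genome, and power tests plant deviations sparsely.

## The randomization framework

All "is this pattern excessive?" questions run through one machinery:

* **Top-quantile sets** — the $\lfloor qN \rfloor$ loci with the most
  extreme scores; ties broken stably by locus order (and reported).
* **Set overlap** — observed $|A \cap B|$ against a null built by
  relabeling one set uniformly at random; x-fold = observed / null mean;
  one-sided $P = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$,
  so $P$ is never exactly zero.  The null mean is checked against the
  hypergeometric expectation $|A||B|/N$ in tests.
* **Category membership** — same relabeling null for counts of Z-linked or
  near-feature loci, with an explicit deficit direction for
  under-representation.
* **Chromosome-size correlations** — Pearson $r$ with the two-sided $t$
  $P$-value on $n-2$ df, with an exclude-Z rerun available.

The consistency grid runs the nine standard comparisons (high-$\alpha$,
low-$\alpha$, high-$\beta$ in the zone, each against high parent-1, high
parent-0, and extreme ancestry in the ancient hybrids) over a quantile
ladder (10% … 1%) and over chromosome scopes.  For scope-restricted runs
the default (`within_scope`) rebuilds the top-quantile sets and permutes
inside the scope; the alternative (`global_sets_scoped_null`) intersects
genome-wide sets with the scope.  Both are provided because the two
reasonable readings give different set sizes; neither is asserted against
any particular published number.

## LD, F_ST, and isolation by distance

Polarized LD recodes each AIM so the counted allele is the parent-1-like
one; admixture then produces *positive* (coupling) correlations between
posterior-mean genotypes, and a panmictic population produces none
(tested).  The default inclusion rule of 20+ individuals avoids noisy
small-sample correlation matrices.

$F_{ST}$ is the ratio of averages
$\overline{(H_T - H_S)} / \overline{H_T}$ with
$H_S = \tfrac{1}{2}(2p_A(1-p_A) + 2p_B(1-p_B))$ and
$H_T = 2\bar p(1-\bar p)$, $\bar p$ the unweighted mean.  (With equal
population weights the "pooled mixture" definition of $H_T$ is
algebraically identical, so no switch is offered.)

The isolation-by-distance model regresses logit-$F_{ST}$ (clipped to
$[10^{-6}, 1-10^{-6}]$) on log great-circle distance and a same/different
taxon indicator, with a random effect per population entering through both
members of each pair — the standard device for the correlated errors of
pairwise observations.  Priors: normal(0, precision 0.001) on
coefficients, gamma(1, 0.01) on precisions.  All conditionals are
conjugate, so the sampler is a plain Gibbs; the full, geography-only and
taxon-only models are compared by
$\mathrm{DIC} = \bar D + p_D$, $p_D = \bar D - D(\bar\theta)$.

## Phylogenomic windows and f_d

Five-lineage analyses work on nonoverlapping 1000-SNP windows (trailing
remainders dropped; windows never span chromosomes).  For five taxa there
are exactly 15 unrooted binary topologies, so instead of heuristic tree
search the package scores *all* of them and takes the argmin — Fitch
parsimony by default (heterozygous calls as ambiguity sets; the scorer is
verified site-by-site against an independent parsimony implementation), or
least-squares minimum evolution (OLS branch lengths clamped at zero,
residual sum of squares as score).  Ties are flagged and broken by lowest
canonical id; an all-invariant window ties across all 15 and is flagged
uninformative.  Externally inferred Newick trees can be mapped onto the
same canonical ids.

Topology excess/deficit by window class (autosomes, Z, candidate-barrier
windows) uses label permutation across windows.  The $f_d$ admixture
proportion uses the site pattern weights
$\mathrm{ABBA} = (1-p_1)p_2p_3(1-p_O)$,
$\mathrm{BABA} = p_1(1-p_2)p_3(1-p_O)$, with the denominator recomputed
under the complete-sharing donor scenario $p_D = \max(p_2, p_3)$
substituted for both $P_2$ and $P_3$; $f_d = 1$ in the complete-sharing
limit and is undefined (flagged) when the denominator vanishes.  The role
mapping $(((P_1, P_2), P_3), O)$ must be passed explicitly: the consensus
quartet statement "(parent-A and parent-B)(hybrid, outgroup-like)" does
not map uniquely onto donor/recipient roles, so guessing would be worse
than requiring the caller to decide.  The candidate-window test compares
the mean $f_d$ of a window set against random draws of equally many
windows, lower tail, with ties between null and observed split evenly
(so a degenerate null gives $P \approx 0.5$ rather than 1).

# The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every recovery claim is made.

* **Parental divergence** — Balding–Nichols: ancestral frequency uniform
  on (0.05, 0.95), descendants
  $\mathrm{Beta}(\pi(1-F)/F, (1-\pi)(1-F)/F)$.  One honest subtlety: the
  fraction of loci with $|p_1 - p_0| \ge 0.3$ is *not* monotone in $F$ —
  at extreme divergence both descendants increasingly fix for the *same*
  allele (probability $\approx \pi^2 + (1-\pi)^2$), so the AIM fraction
  peaks at moderate divergence and then declines.  Tests compare the
  generator against an analytic quadrature oracle rather than folklore.
  The full-study preset therefore reaches its ~2000-AIM condition by
  rejection (`min_diff = 0.3`), not by cranking $F$.
* **Ancient hybrids** — per-chromosome blockwise target profiles $q_\ell$
  (segments fixed for parent 1, fixed for parent 0, or intermediate, with
  Z segments biased toward parent 1, defaults 11% / 3.5% autosomal and
  30% parent-1 on the Z, matching the fixation levels the package is
  meant to detect); haplotype ancestry follows a two-state Markov chain
  with switch rates $s_1 = 1/(2Lq)$, $s_0 = 1/(2L(1-q))$, chosen so the
  expected ancestry run length equals the block length $L$ at *any*
  stationary $q$ (exact 0/1 targets are absorbing).  No explicit
  recombination map: the block length *is* the recombination surrogate.
* **Contemporary zone** — $h_i \sim \mathrm{Beta}(0.5, 0.5)$ (U-shaped,
  spanning 0–1, 115 hybrids by default); each allele copy is
  parent-1-derived with probability $\phi(h_i; \alpha_\ell, \beta_\ell)$,
  so the inference model's data-generating assumptions are matched at the
  haplotype level by construction.
* **GBS noise** — reads per site $\sim$ Poisson(depth; default 2, the
  low-coverage regime), alternative-allele reads binomial with error
  0.01; GL triples are the binomial read likelihoods; zero reads give a
  flat triple.
* **Topology windows** — window labels follow a Markov chain along each
  chromosome (switch probability 0.25) over three generating topologies
  (species tree; an introgression tree uniting one hybrid lineage with
  the melissa-like parent; a tree uniting the two hybrid lineages), with
  autosome weights (0.45, 0.40, 0.15) and Z weights (0.45, 0.05, 0.50)
  so the Z shows the deficit/excess structure the class tests look for;
  10% of sites conflict with the window's topology by default.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: coalescent gene genealogies and incomplete
lineage sorting (window labels are planted, not evolved), linked selection
within blocks, allele-frequency estimation error in the parental
references (truth is passed where a real analysis passes point
estimates),
sequencing depth heterogeneity across loci, and reference-bias artifacts.

# Problem sizes and numerical choices

Function defaults carry the full-scale MCMC settings (clines: 5 chains ×
25,000 iterations, burn-in 5,000, thin 5; ancestry: 10,000 / 5,000 / 10).
The test suite and `run_pipeline()` deliberately run smaller problems —
e.g. 2 cline chains × 3,000 iterations on 2,000 AIMs × 115 hybrids, and
4,000 ancestry sweeps — sizes chosen so the full synthetic study (three
parental populations, two ancient hybrid populations, one zone, 23
chromosomes including Z, ~2,000 AIMs, plus a 92-window five-lineage
panel) completes in a few minutes on one CPU while leaving every recovery
check comfortably above its threshold.  Numerical guards: likelihoods
floored at $10^{-300}$ before logs; $q$ and $\phi$ clamped to $[0,1]$;
logit-$F_{ST}$ clipped; the AIM threshold compared with a $10^{-12}$
guard so "exactly 0.3" is inclusive under floating point; all-flat
individuals and monomorphic loci flagged rather than dropped silently.

Seeds: every stochastic entry point takes a seed (in its config or as an
argument); identical seeds give identical outputs end to end (tested).
One caveat is recorded honestly: swapping parent labels maps
$\hat q \to 1-\hat q$ exactly *in distribution*, and the test asserts it
within Monte-Carlo error rather than bitwise, because the sampler does
not use a mirrored random-number construction.

# Known limitations

* Two-stage cline fitting (fixed $\hat h$) slightly understates
  uncertainty in $\alpha$, $\beta$ when few AIMs inform $h$.
* The ancestry model treats parental frequencies as known point
  estimates; error in them propagates into $\hat q$ unmodeled.
* The cline MCMC has no linkage model across loci (per-locus treatment).
* Fitch parsimony ignores branch lengths; for very asymmetric trees the
  least-squares method is the better default.
* The IBD sampler assumes Gaussian residuals on the logit scale and
  exchangeable population effects; strong spatial structure beyond
  distance is absorbed into the random effects, not modeled.
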