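---
title: "Simulating mating systems and genetic diversity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mating systems and genetic diversity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`matesim` is an individual-based, forward-in-time population-genetic
simulator built for questions where social structure and genetics interact:
how marriage rules, inbreeding avoidance and demographic change shape
nucleotide diversity on the autosomes, the X and Y chromosomes, and
mitochondrial DNA. Coalescent simulators cannot address these questions
because marriage rules break the exchangeability (random-mating) assumption
on which the coalescent rests; the only general route is to simulate every
individual forward through time.

Each individual carries a complete genome over a user-chosen set of
unlinked loci:

* **autosomal** loci — two copies (maternal and paternal slots), one copy
  inherited from each parent, each parental copy chosen uniformly;
* **X-linked** loci — two copies in females, one in males; the child always
  receives one of the mother's two copies, and a daughter additionally
  receives her father's X;
* **Y-linked** loci — one copy, father to son only;
* **mitochondrial** loci — one copy, mother to every child.

Loci are fully unlinked (free recombination between loci, none within), and
generations are non-overlapping: each generation is produced from the
previous one and replaces it wholesale. Selection, recombination within a
locus, migration and age structure are out of scope.

### Mutation

Every transmitted copy passes through a Kimura two-parameter (K80) mutation
step. The model is parameterized by the total per-site per-generation
mutation probability $\mu$ and the transition:transversion probability-mass
ratio $R$ (default 2, a conventional vertebrate figure; user-settable per
locus class). The number of hit sites per transmission is exactly
$\mathrm{Binomial}(L, \mu)$ — per-site Bernoulli hits, not a Poisson
approximation — with positions drawn without replacement, so a site mutates
at most once per transmission (the difference from allowing multiple hits
is negligible at realistic $\mu L$ and the single-hit contract is simpler).
A hit always changes the nucleotide: a transition (A$\leftrightarrow$G,
C$\leftrightarrow$T) with probability $R/(R+1)$, otherwise one of the two
transversions, equiprobably. The stationary distribution is uniform over
the four bases for any $R$.

### Mating systems

Unions are re-formed each generation (no persistent pair-bonds):

* **monogamy** — a uniform random perfect matching of $\min(N_f, N_m)$
  exclusive pairs; excess same-sex adults stay unmated that generation;
* **polygyny** — every female independently takes a uniformly chosen
  husband, so wives-per-male is Binomial and male offspring variance is
  inflated without any extra harem-size parameter;
* **polyandry** — the mirror image;
* **polygamy** — no precomputed unions; each offspring draws an
  independent uniform mother and father (classical random mating).

Each of the $N'$ offspring draws its parent pair by the system's rule, with
replacement across offspring, which yields Wright–Fisher-like offspring
number variance under random mating. Offspring sexes are i.i.d. fair
Bernoulli, with the whole vector redrawn until both sexes are present —
conditioning that keeps very small demes viable and is applied identically
under every mating system so that comparisons between systems are fair.

**Sibling avoidance** prohibits parent pairs that share a mother or a
father (full and half siblings; one generation of pedigree depth —
parent–offspring matings are structurally impossible under non-overlapping
generations). It is implemented as rejection sampling of the pair with a
cap (default 1000 redraws); exhausting the cap raises an error naming the
generation rather than silently permitting inbreeding.

### Demography

Population size is a deterministic piecewise function of the generation
index: an ordered schedule of constant phases (`phase_constant`) and linear
growth/decline phases (`phase_growth`, $k$ individuals per generation).
Running past the schedule, or a schedule that drops below two individuals,
is an error, never a silent truncation. Arbitrary mid-run parameter changes
(mating system, rates, schedule) are made by the save/stop/restart
mechanism: `save_state()` serializes the complete population, configuration
and RNG state to versioned, checksummed JSON, and a restarted run continues
bit-exactly — or under changed rules for scenario chaining (e.g. monogamy
followed by polygyny, or a constant phase followed by growth to model a
settlement).

### The buffering phase

Forward simulators must choose an initial state; neither "all identical"
nor "all different" is biologically meaningful, and a long burn-in is
wasteful. `matesim` starts from monomorphic founders (all-'A' by default)
and offers a **buffering phase**: evolution at all mutation rates
multiplied by a `boost` factor (default 100, per-site ceiling 0.1) until
the whole-deme mean pairwise difference $\theta_\pi$ on a monitored class
(mtDNA by default) first crosses a user-chosen target. Original rates are
then restored and the generation counter reset, so buffer generations are
not counted. Monitoring the whole deme, not a subsample, makes the stopping
generation a deterministic function of the trajectory.

A genuine limitation, quantified by the acceptance suite: buffering
reproduces the *pairwise diversity* target by construction, but because the
target is reached over far fewer generations than a standard-rate
equilibrium run, mutations are concentrated on the recent branches of the
genealogy. At matched $\theta_\pi$, buffered populations therefore carry an
excess of young haplotypes relative to equilibrium populations. The suite
compares haplotype-count distributions between 100 buffered and 100
equilibrium replicates at matched diversity (N = 100, 1 kb mtDNA, target
equal to the equilibrium mean $2 N_f \mu L$), using a deliberately gentle
boost of 2 — the smallest elevation that still meaningfully accelerates the
approach — and the distributions still differ: the excess shrinks with the
boost but vanishes only in the boost $\to$ 1 limit, where buffering no
longer saves any time. Users comparing haplotype-count statistics across
scenarios should buffer both arms identically (the contrasts remain valid),
and should not treat a buffered state as a drop-in replacement for an
equilibrium state when absolute haplotype numbers matter.

### Summary statistics

For a panel of $n$ sequences of length $L$ (whole deme or a sample of
individuals; diploid sampling counts chromosomes, so $s$ sampled
individuals yield $n = 2s$ autosomal sequences):

* $S$ — segregating sites;
* $\theta_w = S / a_n$, $a_n = \sum_{i=1}^{n-1} 1/i$ (Watterson);
* $\theta_\pi$ — mean pairwise Hamming distance over all
  $\binom{n}{2}$ pairs;
* $h$ — distinct haplotypes (exact sequence identity);
* $H_A = \frac{n}{n-1}\left(1 - \sum_k p_k^2\right)$ — unbiased gene
  diversity over haplotype frequencies;
* $H_N = \frac{1}{L} \sum_{\text{sites}} \left(1 - \sum_a q_a^2\right)$ —
  Nei's per-site heterozygosity, without sample-size correction.

$\theta_w$ and $\theta_\pi$ are reported in per-locus units with per-site
variants available, since either convention appears in applied work. Every
statistic is verified exactly against naive string-based implementations on
randomized panels; panels are permutation-invariant and obey the standard
metamorphic identities (duplicating all sequences, appending an invariant
site).

## Implementation notes

DNA is bit-packed at 2 bits per site (A=00, C=01, G=10, T=11), 32 sites per
64-bit word, site 0 in the lowest bits, trailing bits zero; words cross the
R boundary as little-endian raw bytes so serialized states are portable.
Hamming distances use XOR, a bit-pair collapse and popcount. The
generation loop, mutation, transmission and the statistic battery are
implemented in C++ (via Rcpp), the configuration, demography, orchestration
and I/O layers in R — the same division of labour used by other
forward-in-time engines, where the inner loop dominates runtime.

All randomness flows through R's RNG: `set.seed()` fully determines every
trajectory, `.Random.seed` is the complete serializable stream state (which
is what makes save/restart splicing bit-exact), and replicate $r$ of a
batch runs on a private stream derived from `(seed, r)`, so batch outputs
are byte-identical for any worker count and replicates are embarrassingly
parallel.

Founder populations receive `floor(N * sex_ratio)` females (default 0.5).
Trajectory statistics recorded by the engine are whole-deme, so recording
never consumes random numbers; sampled panels (`collect_panel`) draw from
the RNG explicitly.

## Validation strategy and problem sizes

The test suite validates three layers, mirroring how forward simulators
are conventionally checked:

1. **Exact oracles** — every statistic against brute-force string
   implementations; encode/decode round trips; closed-form toy panels.
2. **Distributional laws** — Mendelian segregation frequencies, unlinked
   two-locus segregation, union multiplicity per mating system,
   wives-per-male under polygyny, the transition fraction $R/(R+1)$, the
   Binomial mutation count, K2P stationarity (chi-square).
3. **Population-genetic expectations** — at neutral random-mating
   equilibrium the replicate-mean $\theta_\pi$ is compared with the
   coalescent predictions $2 N_f \mu L$ (mtDNA), $2 N_m \mu L$ (Y), and
   $E[S] = \theta a_n$ for samples, within 15% over 200 replicates run for
   2000 generations at $N = 100$; plus the directional contrasts (polygyny
   vs monogamy on Y haplotypes, the monogamy-to-polygyny switch, growth
   with lag on the X, sibling avoidance on autosomal $\theta_w$ from
   buffered standing diversity at $\theta_\pi = 25$).

Monte-Carlo sizes (100–500 replicates; populations of 50–200; loci of
1–16 kb) were chosen so the full suite runs on a single CPU in tens of
minutes while leaving each tested effect several standard errors from its
null. The generator is synthetic end to end: it emulates neutral evolution
under idealized social rules, with exact fair-Bernoulli sex ratios,
deterministic schedules and no selection, structure or migration — so
passing tests certify the simulator's internal consistency and its
agreement with neutral theory, not the realism of any particular empirical
system.

## Known limitations

* Haplotype-count inflation of the buffering phase (above).
* The sibling-avoidance effect on effective size at mutation–drift
  equilibrium is of order 1% at $N = 100$ and is not resolvable with
  moderate replicate numbers; the avoidance contrast is therefore run, as
  in the decay-from-standing-diversity design, where the effect compounds.
* Polygyny/polyandry use the uniform-spouse rule; harem-size caps or
  rank-structured marriage are extension points, not implemented.
* Haplo-diploid reproduction is not modelled; haploid systems can be
  emulated by configuring only mtDNA and/or Y loci.
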