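---
title: "Testing reproductive character displacement in gamete recognition genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing reproductive character displacement in gamete recognition genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcdpopgen)
```

## The scientific question

Reproductive character displacement (RCD) predicts that a prezygotic
isolating trait diverges faster where two closely related taxa co-occur
than where they are separated. In broadcast-spawning marine invertebrates
the trait in question is molecular: sperm and egg surface proteins (gamete
recognition proteins, GRPs) mediate species-specific fertilization, and
RCD should appear as elevated positive selection on the genes encoding
them in sympatric populations relative to allopatric ones.

`rcdpopgen` implements the full test battery for this hypothesis in two
cryptic, strongly postzygotically isolated lineages (called A and B) of a
single nominal species:

1. **Divergence screen.** Nei–Gojobori (1986) pairwise
   $\omega = d_N/d_S$ between the lineages, averaged over the four
   combinations of two sequenced individuals per lineage; genes with
   averaged $\omega > 0.5$ (strict) are flagged as positive-selection
   candidates; candidate GRPs are compared against control (house-keeping)
   genes with a one-tailed Mann–Whitney U test.
2. **Polymorphism battery.** Per population: segregating sites $S$,
   Watterson's $\theta_W = S/(a_n L)$, nucleotide diversity $\pi$ overall
   and partitioned into synonymous and nonsynonymous site classes, and
   Hudson-style $F_{ST}$ between populations.
3. **Neutrality statistics with simulated nulls.** Tajima's $D$, Fu &
   Li's $D^*$ and $F^*$, and Fay & Wu's $H$, each referred to a null
   distribution from 1,000 neutral coalescent simulations run at the
   observed per-gene $\theta_W$; sympatric and allopatric populations are
   declared different for a statistic only when each population's 95%
   simulation interval excludes the other population's observed value.
4. **McDonald–Kreitman tests.** Fixed versus polymorphic, synonymous
   versus nonsynonymous contingency tables between the lineages with a
   two-tailed Fisher's exact probability.
5. **Bayesian $\omega$ comparison.** A constant-$\omega$ posterior per
   population from a pairwise composite likelihood under a codon
   substitution model; the sympatric-vs-allopatric decision comes from
   whether the 95% credible interval of the posterior $\omega$ difference
   contains zero.

## Models and their assumptions

### NG86 divergence

Synonymous and nonsynonymous site counts follow the Nei–Gojobori scheme:
each codon position contributes a synonymous fraction equal to the number
of synonymous single-base changes over the number of changes that do not
create a stop codon (stop neighbours are excluded from numerator and
denominator — a convention choice; positions whose every change is a stop
count as one nonsynonymous site, so sites always sum to 3 per codon).
Multi-difference codons are resolved by equal-weight averaging over all
orderings of the single-base steps, excluding orderings that pass through
a stop codon. Proportions are corrected with the Jukes–Cantor map
$d = -\tfrac34 \log(1 - \tfrac43 p)$ per class; $p \ge 3/4$ is reported as
saturated rather than extrapolated. Codons containing `N` or `-` in either
sequence are skipped pairwise. The estimator deliberately uses
equal pathway weights rather than transition-favouring weights, and it is
a counting estimator, not a maximum-likelihood codon model: on data
generated with a transition-biased mutation process it underestimates
$\omega$ by roughly 10%, which the parameter-recovery tests accommodate
within their 20% band.

### Polymorphism conventions

All per-site statistics use complete deletion per column (any column with
missing data is removed from both $S$ and $L$). Class-specific $\pi$
divides pathway-classified per-codon differences by NG86 fractional sites
averaged over the whole sample, so the denominator is common to all pairs;
this makes $\pi_{total} L = \pi_{syn} L_{syn} + \pi_{nonsyn} L_{nonsyn}$
an exact identity, which the tests exploit.

### Neutrality statistics

Tajima's $D$ uses the 1989 coefficients; Fu & Li's outgroup-free $D^*$ and
$F^*$ use the corrected coefficient set of Simonsen et al. (1995); both
return `NA` when $S = 0$ or $n < 4$. Fay & Wu's $H$ requires polarization:
the package uses the per-column majority consensus of the *other* lineage
as the outgroup (a documented choice — the original analyses delegated
this to their analysis software without reporting it), excludes sites
where the outgroup base is missing or absent from the sample, and reports
both the raw $H = \pi - \theta_H$ and the normalized form (Zeng et al.
2006 variance). Published tables for this system mix scales for $H$
(values of order 0.1 against intervals of order 10), so no numeric
reproduction of them is attempted anywhere.

### The coalescent simulator

`simulate_sample()` is an event-driven Hudson-style ancestral
recombination graph: lineages carry intervals of ancestral material on
$(0,1)$ labelled with their descendant sets; coalescence (rate
$k(k-1)/2$), recombination (rate $\rho/2$ per unit breakable span) and
infinite-sites mutation (rate $\theta/2$ per unit ancestral material)
compete, and material reaching its local MRCA is retired. Each mutation
yields one segregating site with a known derived-allele count, so every
neutrality statistic evaluates directly on the simulated spectrum.
Simulations are run at the observed per-gene $\theta_W$ (not conditioned
on $S$); $\rho$ is taken as supplied rather than estimated. The one-tailed
simulation p-value is taken on the side of the observed deviation from the
null median, floored at $1/(\text{reps}+1)$ when the observation falls
outside the simulated range; replicates with undefined statistics
(typically $S=0$) are dropped, and a null with more than half its
replicates undefined is refused.

### The Bayesian constant-$\omega$ model

The likelihood is a *pairwise composite* approximation, not a full
population likelihood: for every unordered haplotype pair the probability
of the pair is computed under an NY98-style codon model (transition bias
$\kappa$, nonsynonymous weight $\omega$, empirical codon frequencies with
a 0.5 pseudocount, rate matrix normalized to one expected substitution per
codon site per unit divergence) at divergence $\mu t$, with the pair
coalescent time integrated over $t \sim \mathrm{Exp}(1)$ by 16-node
Gauss–Laguerre quadrature. Two calibration points matter:

* Because all $\binom{n}{2}$ pairs share one genealogy, the summed pair
  log-likelihood is rescaled by $(n-1)/\binom{n}{2}$ — the information of
  the $n-1$ effectively independent contrasts. Without this the posterior
  curvature is overstated by a factor of roughly $n/2$ and the
  downstream credible-interval decisions become anti-conservative.
* Sixteen quadrature nodes integrate the time mixture to an absolute
  log-likelihood accuracy of order $10^{-1}$ on $\sim 10^{5}$-scale
  log-likelihoods; the node count is configurable and the tests verify
  convergence of the quadrature family against adaptive integration.

Priors are reciprocal ($\propto 1/x$) truncated to $[10^{-6}, 10^{3}]$
for $\mu$, $\kappa$ and $\omega$ — uniform on the log scale, so the
Metropolis–Hastings acceptance ratio with log-scale Gaussian random-walk
proposals is simply the likelihood ratio inside the support box. One
randomly chosen parameter moves per iteration. Defaults are 250,000
iterations thinned by 1,000 with an automated 20% burn-in (trace-based
manual burn-in is replaced by a fixed fraction); two independent seeded
runs are combined only after their means and 95% CrI endpoints agree
within 0.5 pooled standard deviations per parameter. Samples with fewer
than two distinct haplotypes are flagged `"Not enough variation"` and
propagate an `NA` verdict. Recombination is deliberately excluded from
the MCMC state: the constant-$\omega$ target does not require it, and
recombination enters the battery only through the coalescent nulls.

The sympatric-vs-allopatric comparison resamples $\omega$ draws (with
replacement, seeded) from the two posteriors and summarizes
$\omega_{sym} - \omega_{allo}$ by its mean and equal-tailed 95% interval;
the populations differ significantly only if that interval excludes zero.

## The synthetic-data generator

`generate_gene_dataset()` emulates the sampling design: four populations
(sympatric and allopatric samples of lineages A and B, 10 diploid
individuals each by default) plus a 2+2 divergence panel taken from the
allopatric samples. The genealogy is a structured coalescent with the two
lineages splitting $\tau$ coalescent units ago; sympatric lineages may
migrate between demes at rate `m_sym` (0 by default — the contact zone
shows only limited introgression); deme sizes scale with per-gene
$\theta$. Codon sequences evolve down the genealogy from a random
stop-free ancestral sequence: mutation attempts fall at rate $\theta/2$
per lineage, pick a uniform site and a transition-biased ($\kappa$) base,
redraw on stop codons, and *retain nonsynonymous changes with probability*
`omega_class` — selection enters only as this acceptance filter, giving
each gene class a known realized $d_N/d_S$ truth without linked-selection
dynamics. A haploid flag emulates an organelle-like control gene, and
`diploid_packaging()` optionally reproduces the clone-based allele
discovery step, miscalling a heterozygote homozygous with probability
$(1/2)^{7}$.

Default calibration (chosen once, against the study system's published
anchors): $\tau = 12$, $\theta_A = \theta_B = 10$ per gene, 300 codons,
$\kappa = 2$, GRP class $\omega^* = 0.6$, control class $\omega^* = 0.1$.
This puts between-lineage p-distances at roughly 0.04–0.12 for both gene
classes (the two lineages' published divergence spans 0.035–0.124) and
within-population $\pi$ at a few parts per thousand, inside the published
0.002–0.05 range; occasional populations fall below 0.002, as they do in
the real data. What the generator does *not* emulate: demographic history
of the real invasions, linkage maps, within-gene recombination during
sequence evolution, codon usage bias, and selection acting on linked
sites. Passing tests therefore show estimator correctness and decision-
rule calibration under a clean neutral-plus-filter model, not robustness
to real demographic complications.

## Worked example

```{r example, eval = FALSE}
library(rcdpopgen)

# a small synthetic study: 6 candidate GRPs, 4 controls
man <- synthesize_manifest(synthetic_config(), n_grp = 6L, n_control = 4L,
                           seed = 7L,
                           mcmc = mcmc_config(iterations = 5000,
                                              thinning = 10,
                                              burn_in_fraction = 0.3))

div <- run_divergence_stage(man)   # per-gene averaged omega + rank test
head(div$table)
div$p_value

pop <- run_population_stage(man)   # summaries, neutrality nulls, MK, decisions
subset(pop$neutrality, statistic == "D" & gene == "grp_01")
pop$decisions

om <- run_omega_stage(man)         # Bayesian sympatric-vs-allopatric verdicts
om
```

## Numerical choices and degenerate inputs

* Ties in the candidate screen: $\omega = 0.5$ exactly is *not* a
  candidate (strict inequality).
* The Mann–Whitney test enumerates exactly for combined $n \le 12$ without
  ties and otherwise uses the tie-corrected normal approximation; all-tied
  input returns $p = 1$ with a warning.
* Fisher's two-tailed p sums table probabilities $\le$ the observed one
  with a $10^{-7}$ relative tolerance guarding floating-point ties; any
  zero row or column margin yields `NA`. Fractional pathway counts are
  resolved to integers at MK-table level by largest-remainder rounding
  (the raw fractional counts are kept in the `raw` field).
* A sequence with no synonymous sites at all (e.g. all-ATG) has undefined
  $d_S$; $\omega$ is undefined whenever $d_S = 0$ — distinct from
  $\omega = 0$, which arises when $d_N = 0 < d_S$.
* Consensus ties polarize toward the alphabetically first base; this only
  matters for Fay & Wu's $H$ at 50/50 outgroup columns.
* The global pipeline seed fans out as `seed + counter` across coalescent
  configurations and as `seed + 10000 + counter` across MCMC runs, so
  every stage is reproducible independently.

## Problem sizes used by the test suite

The suite exercises the battery at reduced but honest sizes: coalescent
checks at 700–2,000 replicates, MCMC chains of 1,500–2,500 iterations
(thinned by 4–5, 25–30% burn-in) whose acceptance rates of 0.3–0.7
indicate adequate mixing at these posterior widths, 20-replicate
parameter-recovery batches, and null-specificity manifests of 4–6 genes
at the full 1,000 coalescent replicates.

## Known limitations

* The composite likelihood is a surrogate: its point estimates track the
  realized $\pi_N/\pi_S$ of the sample, so with only a handful of
  segregating mutations per gene (the situation at realistic
  within-population diversity) posterior medians scatter around the
  generating $\omega^*$ with the full Poisson noise of the mutation
  process. Comparisons between populations remain calibrated (the
  difference interval covers zero under the null), but single-population
  $\omega$ estimates from sparse data should be read as order-of-magnitude.
* NG86 with equal pathway weights underestimates $\omega$ under strong
  transition bias; the divergence screen is a ranking instrument, and the
  0.5 threshold inherits that conservatism.
* The CI-overlap decision rule (both populations' simulation intervals
  must exclude the other's observation) is deliberately conservative; its
  false-positive rate under the null is far below nominal.
* The simulator's infinite-sites mutations do not map back onto codon
  positions, so simulated nulls calibrate the frequency-spectrum
  statistics only — exactly the role they play in the battery.
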