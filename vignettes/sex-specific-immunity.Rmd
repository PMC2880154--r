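---
title: "Eco-evolutionary dynamics of sex-specific immune defence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary dynamics of sex-specific immune defence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimorphESS)
```

## The question

Males and females of many species differ in how well they cope with
infection. dimorphESS asks when such dimorphism is the product of natural
selection alone: in a sexually reproducing host population coupled to an
endemic pathogen, under what ecological conditions do the two sexes evolve
different investments in immune defence, even though every individual
carries the same genes?

The package implements a full eco-evolutionary loop: explicit diploid
genetics with sex-limited expression, susceptible-infected-susceptible
(SIS) epidemiological dynamics, invasion fitness of rare mutant alleles
computed as a dominant eigenvalue, and a numerical search for the joint
evolutionarily stable strategy (ESS) of the two sex-specific traits.

## The model

### Demography and mating

Hosts are diploid with two sexes. Births are limited by females: the total
birth rate is `b (1 - qN) * F`, where `N` is total density, `q` scales
density dependence, and `F` sums the effective fecundity of females
(susceptible females count fully, infected females by a factor `phi_f`).
Males follow Bateman's principle: an unlimited gamete supply means male
genotypes compete only for *shares* of paternity, in proportion to their
effective reproductive weight `M_k = S_m + phi_m I_m`. Male composition
therefore shapes the genetics of the offspring pool but never its size;
this asymmetry between the sexes is built into the model and is the reason
male strategies turn out more sensitive to ecological change than female
ones. Offspring are split 1:1 between the sexes and distributed over
genotypes by Mendelian segregation with free recombination
(`mendelian_offspring()`, `birth_rates()`).

### Epidemiology

Each genotype-sex class follows SIS dynamics with mass-action
(density-dependent) transmission:

```
dS/dt = B/2 - d S - beta S I_tot + gamma I
dI/dt = beta S I_tot - (d + alpha + gamma) I
```

with `I_tot` the total infected density (infectivity is independent of sex
and genotype), sex-specific susceptibility `beta` and virulence `alpha`,
and genotype- and sex-specific background mortality `d` and recovery
`gamma`. Recovery returns hosts to the susceptible pool of their own class
(no acquired immunity). Density-dependent transmission matters: it is the
channel through which one sex's traits feed back on the other sex's
infection risk, and several headline results (the 50%-prevalence turning
point, the cross-sex effects of susceptibility) depend on it.

Closed forms anchor the numerics: the disease-free density is
`K = (1 - 2 d_f / b) / q` (only female mortality enters, because females
limit reproduction), and the pathogen invades iff
`R0 = S_f beta_f / (d_f + alpha_f + gamma_f) + S_m beta_m / (d_m + alpha_m + gamma_m) > 1`
at the disease-free equilibrium. Both are verified against integration in
the test suite.

### Genetics and sex-limited expression

Two autosomal loci are carried by both sexes; the first is expressed only
in females (trait `x_f`), the second only in males (trait `x_m`). Allelic
effects are additive, so heterozygotes express the mean of their two
allele values. This is the minimal genetic architecture in which the two
sexes can evolve independently while still sharing — and recombining —
all their genes every generation.

### Trade-offs

A trait value `x` in (0, 1) is mapped to a phenotype
(`gamma`, `d`, `phi`) by one of three trade-off models
(`tradeoff_model()`):

| model | benefit (rises with x)        | cost (worsens with x)     | cost type    |
|-------|-------------------------------|---------------------------|--------------|
| i     | recovery `gamma`              | background mortality `d`  | constitutive |
| ii    | infected fecundity `phi`      | background mortality `d`  | constitutive |
| iii   | recovery `gamma`              | infected fecundity `phi`  | facultative  |

Raising `gamma` is *resistance* (it shortens infections and hurts pathogen
transmission); maintaining `phi` is *tolerance* (it restores host fitness
without touching the pathogen). Models (i) and (ii) pay for defence
whether or not infection happens; model (iii) pays only while infected.

**Default shapes.** The shapes are free design parameters of the analysis
(only the traded pair and its direction are fixed), and they decide
whether interior ESSs exist at all. The defaults are

* `Gamma(x) = 2 gamma0 x / (x + 0.5)` — saturating benefit, anchored so
  `Gamma(1/2) = gamma0` (the reference recovery rate 2 sits at the trait
  midpoint) and bounded by `2 gamma0`;
* `D(x) = d0 / (1 - x^2)` — accelerating mortality cost, near `d0` at
  small `x`;
* `Phi(x) = x` and `Psi(x) = 1 - x` — linear fecundity benefit / cost.

Two considerations fix this family. First, an interior ESS needs
diminishing marginal benefits against accelerating marginal costs; all
three models then satisfy "cost convex in benefit", which the tests check
on a grid. Second, the recovery benefit must be *bounded*: with an
unbounded `Gamma` (for example `gamma0 * x / (1 - x)`), model (iii)
escalates resistance until `R0` drops below one and the pathogen goes
extinct, at which point a facultative cost is never expressed, selection
becomes neutral, and no interior ESS exists. The bound `2 gamma0` keeps
`R0 > 1` across the whole trait range at the default parameters, so
host evolution alone can never eradicate the pathogen. Every shape is
replaceable through the `tradeoff_model()` arguments (including
sex-specific trade-offs, by passing different models for the two sexes).

### Reference parameters

`host_params()` defaults (arbitrary time/density units): `b = 1`,
`q = 0.01`, `d0 = 0.25`, `gamma0 = 2`, `beta_f = beta_m = 0.2`,
`alpha_f = alpha_m = 0.75`. At these values the disease-free density is
`K = 50` and `R0 = 10/3` for the midpoint phenotype, so the pathogen is
comfortably endemic.

## Invasion fitness and the ESS search

A resident population homozygous at both loci sits at its ecological
equilibrium (`equilibrium()`; long integration of the four-compartment
system plus Newton polishing, residual tolerance `1e-9` on the derivative
max-norm, extinction threshold `1e-8`). A rare mutant allele at one locus
then grows or dies according to the linearised dynamics of its carrier
classes (`invasion_matrix()`): at first order in rarity only single-locus
heterozygotes matter (mutant homozygotes and double heterozygotes are
quadratic), giving a 4x4 system — susceptible/infected x female/male
heterozygote. Mutant mothers transmit the allele to half their offspring;
mutant fathers sire the share of resident females' offspring given by
their effective weight against the resident male pool, again halved by
segregation. The dominant eigenvalue (largest real part) is the invasion
fitness; by construction the resident's own equilibrium spans the neutral
eigendirection, so self-invasion gives exactly zero — the neutrality the
tests verify to `1e-6` (numerically it holds to machine precision).
Eigenvalues within `1e-6` of zero are classified neutral.

`find_ess()` alternates best mutant responses at the two loci (a coarse
21-point candidate scan refined by golden-section search). Pure
best-response iteration overshoots around the singular point — the
best-response map typically has slope below -1 there — so steps are
damped adaptively (halved whenever the update direction at a locus
reverses, down to 1/8). Once the iteration settles, the candidate is
polished by Newton iteration on the two-locus selection gradient (central
differences, step `1e-4`), which pins the singular point to ~1e-8 and is
what makes the symmetric-sex check (`|x_f* - x_m*| < 1e-3`) pass with
orders of magnitude to spare. Finally the fixed point is *certified*: a
101-point mutant grid at each locus must show no eigenvalue above the
neutral band, and the maximum found is reported as `certificate`.
Convergence stability (the selection gradient pointing inward on both
sides) is reported separately — ESS status itself only requires
non-invasibility. Warm starts along sweeps re-seed a small infected
density whenever the previous cell's equilibrium lost the pathogen, so the
infection-free manifold (which is invariant under the exact dynamics)
cannot spuriously absorb a sweep.

## The brute-force oracle

The linearisation is validated, not trusted: `simulate_invasion()`
integrates the full nonlinear genotype-resolved system (three genotypes at
the mutated locus, 12 equations) from the resident equilibrium perturbed
by heterozygotes at allele frequency `1e-5`, and reads the verdict off the
slope of the log allele frequency over the final third of the horizon
(2000 time units, early exit once the log frequency moves by 3; slopes
below `1e-4` per unit time count as neutral). `invasion_agreement()`
scores randomized (resident, mutant, parameters) triples with both
methods; the acceptance suite requires at least 98% agreement on 200
triples outside the neutral band.

## What the analyses show

With all extrinsic parameters equal between the sexes, Bateman's principle
alone creates no dimorphism: both sexes evolve the same strategy, in all
three models. Dimorphism appears as soon as exposure or virulence differs
between the sexes, and its direction is set by ecological feedback rather
than by the asymmetry in mating competition directly:

* Joint susceptibility up: more resistance under a constitutive cost
  (model i), more tolerance under models (ii) and (iii) — in (iii) at the
  expense of resistance, because infections become too frequent for
  resistance to pay its facultative price.
* Joint virulence up: non-monotone defence under a constitutive cost
  (rising individual stakes versus falling prevalence); under the default
  shapes this non-monotonicity is expressed by model (i), while model
  (ii)'s tolerance declines monotonically — the marginal value of
  fecundity-during-infection tracks time-spent-infected, which falls with
  virulence from the outset. Model (iii) shows no prevalence feedback at
  all: with a facultative cost there is no incentive to disarm as the
  pathogen grows deadlier.
* Sex-specific susceptibility: the ES male recovery rate is non-monotone
  in male exposure, peaking where male prevalence crosses one half — past
  that point males are reinfected faster than defence pays back, and with
  extreme male exposure (roughly tenfold the female rate at the reference
  parameters) males end up *less* immunocompetent than females. Under the
  facultative-cost model the more exposed sex always resists less.

Each of these statements is computed by the test suite or the acceptance
script, not asserted from memory.

## Problem sizes and determinism

The analyses are deterministic given a parameter set; randomness enters
only through the oracle's sampling of test triples, which is seeded. The
shipped sweeps use grids sized for a single CPU: 5-point curves for the
directional checks, an 8-point male-susceptibility sweep spanning
[0.05, 1.2] for the turning-point analysis (the range is chosen so the
recovery maximum is interior), two-dimensional surfaces default to 8x8.
All grids are arguments, so finer resolution is one keystroke away.

## Limitations

* No sexual selection or mate choice: mating is homogeneous, so the model
  isolates natural selection.
* One pathogen, no pathogen evolution, no vertical or sexual transmission,
  no acquired immunity, no linkage disequilibrium, no sex chromosomes.
* Results about *which* patterns arise are conditional on the trade-off
  shapes; the package treats shapes as first-class inputs for exactly this
  reason, and the qualitative feedback mechanisms (prevalence-mediated
  benefit of defence) are the robust content.
* ESSs are found by local search certified on a grid; multiple singular
  strategies would need multistart (`init`) to map out.
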