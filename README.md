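# dimorphESS

Why do males and females so often differ in how well they fight
infection? `dimorphESS` studies the *natural-selection* side of that
question with an eco-evolutionary model: a diploid, sexually reproducing
host population coupled to an endemic pathogen with
susceptible–infected–susceptible (SIS) dynamics, in which two autosomal
loci with sex-limited expression control female and male investment in
immune defence. The package is aimed at evolutionary ecologists and
theoreticians working in adaptive dynamics.

## The model in brief

Each genotype–sex class `(S, I)` follows SIS dynamics with mass-action
transmission,

    dS/dt = B/2 − d·S − β·S·I_tot + γ·I
    dI/dt = β·S·I_tot − (d + α + γ)·I

with sex-specific susceptibility `β` and virulence `α`. Births track
females — `B_total = b(1 − qN)·Σ_j F_j` with `F_j = S_f + φ_f I_f` — while
males, following Bateman's principle, compete only for paternity *shares*
`M_k / Σ M_u` with `M_k = S_m + φ_m I_m`; offspring are distributed over
genotypes by Mendelian segregation with free recombination. A trait
`x ∈ (0,1)` at the female-expressed (resp. male-expressed) locus is mapped
to the phenotype `(γ, d, φ)` by one of three trade-offs: (i) recovery γ
vs. background mortality d (resistance, constitutive cost), (ii) fecundity
during infection φ vs. d (tolerance, constitutive cost), (iii) γ vs. φ
(resistance with a facultative cost).

Evolution is analysed by adaptive dynamics: the invasion fitness of a rare
mutant allele is the dominant eigenvalue of the linearised dynamics of its
heterozygote carrier classes at the resident's ecological equilibrium, and
`find_ess()` searches the square `{0 < x_f < 1, 0 < x_m < 1}` for the
joint evolutionarily stable strategy, certifying non-invasibility on a
fine mutant grid. A brute-force nonlinear simulation oracle
(`simulate_invasion()`) validates the eigenvalue criterion.

## Worked example

```r
library(dimorphESS)

params <- host_params()        # b = 1, q = 0.01, d0 = 0.25, gamma0 = 2,
                               # beta = 0.2, alpha = 0.75 (both sexes)
model  <- tradeoff_model("i")  # resistance with a constitutive cost

fit <- find_ess(params, model)
fit
#> <ess_result> interior-ESS: x_f* = 0.2832, x_m* = 0.2832 (certificate -1.3e-07, 5 iterations)
#>   female: gamma = 1.45, d = 0.272, phi = 1 | male: gamma = 1.45, d = 0.272, phi = 1
#>   equilibrium: endemic, N = 15.45, prevalence f/m = 0.201/0.201
```

With no extrinsic difference between the sexes, both loci evolve to the
same strategy (`x* = 0.283`): mating competition alone creates no
dimorphism. The resident equilibrium is endemic with 20% prevalence in
each sex, and no mutant allele on a 101-point grid at either locus has
invasion fitness above the neutral band (the negative `certificate`).

Fitted objects have broom-style accessors and sweeps return tibbles with
`autoplot()` methods:

```r
glance(fit)[, 1:4]
#> # A tibble: 1 × 4
#>   status        certificate convergence_stable     N
#>   <chr>               <dbl> <lgl>              <dbl>
#> 1 interior-ESS -0.000000134 TRUE                15.5

invasion_fitness(0.45, 0.45, locus = "f", mutant = 0.35,
                 params = params, model_f = model)
#> <invasion_result> resident (0.45, 0.45), mutant f-locus 0.35: lambda = 0.006161 (invades)
```

A resident above the ESS is invaded by mutants back towards it
(`λ = 0.0062 > 0`). Closed forms anchor the ecology: without the pathogen
the population equilibrates at the carrying capacity
`K = (1 − 2d/b)/q = 50`, and at the trait midpoint
`R0 = K·β/(d + α + γ) = 10/3`, so the pathogen is endemic:

```r
equilibrium(0.5, 0.5, params, tradeoff_model("iii"), seed_infection = FALSE)
#> <sis_equilibrium> disease-free, N = 50, prevalence f/m = 0/0 (residual 0)
basic_reproduction_number(0.5, 0.5, params, tradeoff_model("iii"))
#> [1] 3.333333
```

Sex-specific sweeps reproduce the model's headline asymmetries, e.g. the
non-monotone response of ES male recovery to male exposure:

```r
tp <- recovery_turning_point(params, model,
                             beta_m_values = seq(0.05, 1.2, length.out = 8))
autoplot(tp$sweep)
```

A thin command-line wrapper for sweeps, pairwise-invasion grids and the
oracle lives in `inst/scripts/dimorphess`.

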