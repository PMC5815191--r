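---
title: "Modelling insecticide-resistance evolution under mixtures and sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling insecticide-resistance evolution under mixtures and sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irmsim)
```

## The model

irmsim simulates the spread of insecticide resistance in a large, randomly
mating insect population (the motivating system is *Anopheles gambiae*
under malaria vector control, but nothing is mosquito-specific). Resistance
to each of two insecticides is controlled by a single biallelic locus with
a resistant (R) and a susceptible (S) allele, giving three genotypes per
locus and nine two-locus genotypes. The population is effectively infinite,
so the model is a deterministic recursion on the frequencies of the four
gametes (haplotypes) S1S2, S1R2, R1S2 and R1R2, tracked separately for
females and males.

Each generation proceeds as:

1. **Random union of gametes.** Offspring genotype frequencies are the
   outer product of the female and male gamete frequency vectors; the sex
   ratio is 1:1 and both sexes have identical genotype distributions at
   birth.
2. **Sex-specific viability selection.** Genotype frequencies are
   multiplied by the sex's marginal fitness and renormalised by the mean
   fitness. Selection is the only sex-differentiated step, and only through
   exposure (females seeking blood meals contact treated surfaces more
   than males); all headline scenarios use equal exposures, under which the
   two sexes stay identical.
3. **Gamete production with recombination.** Every genotype transmits half
   of each constituent haplotype, except the two double heterozygotes,
   which emit parental haplotypes with probability $(1-c)/2$ each and
   recombinant haplotypes with probability $c/2$ each, where $c$ is the
   recombination fraction.

There is no mutation, migration or drift: resistance alleles are assumed
pre-adaptive, already segregating at the starting frequency.

## Fitness construction

Fitness is relative to the unexposed SS genotype, fixed at 1. Seven inputs
per insecticide determine everything (all proportions):

| input | meaning | default |
|---|---|---|
| effectiveness | proportion of SS killed on exposure | 0.5 |
| exposure | proportion of the (sex-specific) population contacting the deployment | 0.5 |
| resistance restoration | fraction of the insecticide-induced loss regained by RR | 0.5 |
| dominance of resistance | position of exposed SR between SS and RR | 0.5 |
| start frequency | initial R-allele frequency | 0.01 |
| cost | fitness loss of unexposed RR | 0 |
| dominance of cost | position of unexposed SR between SS and RR | 0 |

Exposed: $w_{SS} = 1 - \text{eff}$, $w_{RR} = w_{SS} + \text{eff} \cdot
\text{rest}$, $w_{SR} = w_{SS} + h\,(w_{RR} - w_{SS})$. Unexposed:
$w_{SS} = 1$, $w_{RR} = 1 - \text{cost}$, $w_{SR} = 1 - h_c \cdot
\text{cost}$. Two-locus fitness is the product of the two single-locus
values; the marginal fitness of a genotype is the exposure-weighted mean
over the contacted/uncontacted classes.

Under a **mixture** the exposed fraction contacts *both* insecticides
simultaneously, so there are exactly two exposure classes ({both} and
{neither}). A four-class structure (each insecticide contacted
independently) is conceivable for spatially separated products, but a
co-deployed mixture — both actives on the same net or wall — is the setting
modelled here, and the binary split is the faithful representation of it.
Survival probabilities multiply across the two actives (e.g. $0.3 \times
0.2 = 0.06$); synergistic or antagonistic interactions and cross-resistance
are out of scope.

When the two insecticides are given different exposure values and a
mixture is requested, the engine warns and uses their mean: exposure is a
property of the deployment setting, not the molecule, so a well-posed
mixture scenario gives both insecticides the same value.

## Strategies and metrics

* **single** — one insecticide deployed until its locus reaches the
  resistance threshold (default 0.5; 0.25 and 0.75 give the same strategy
  ordering on the headline scenarios, which the test suite checks).
* **sequence** — insecticide 1 until its locus crosses; from the following
  generation insecticide 2 until its locus crosses. The idle locus
  experiences only cost selection.
* **mixture** — both deployed every generation; total time is the first
  generation at which both loci have crossed.

Censuses happen at whole generations; the crossing generation is the first
census with frequency $\ge$ threshold (no interpolation), generation 0
being the initial state. Runs hitting the generation cap (default 500)
return an explicit not-reached sentinel (`NA`), never an error. The
headline comparison statistic is the mixture/sequence ratio of total
times, reported raw and rounded half-away-from-zero to one decimal.

With the default base parameterisation this yields 59 generations for sole
use, 118 for the sequence and 90 for the mixture (ratio 0.8): each
insecticide evolves resistance *more slowly* inside the mixture than alone
(the other active kills resistant heterozygotes and homozygotes, removing
selection pressure — "protection"), yet the sequence can still win in
total because its two phases run one after the other. Raising
effectiveness strengthens mutual protection and flips the ordering toward
the mixture; raising exposure accelerates the mixture more than the
sequence and favours the sequence; dominance, restoration and starting
frequency move both strategies together and leave the ordering unchanged.

## Numerical choices

* Default $c = 0.5$: the loci are treated as unlinked, independently
  segregating genes. The reported generation counts are insensitive to
  $c$ on the headline scenarios because all of them start at linkage
  equilibrium with symmetric or single-deployment selection; `scenario()`
  exposes $c \in [0, 0.5]$ for exploring linked loci.
* Haplotype vectors are renormalised every generation; the validity
  tolerance on inputs is $10^{-12}$.
* Threshold bookkeeping is integer-generation; the sequence switch takes
  effect the generation *after* crossing (the crossing generation counts
  toward phase 1). These conventions shift whole-generation counts by at
  most one or two relative to alternatives (e.g. 59 rather than 60 for the
  base single run) without affecting any qualitative comparison.
* Zero mean fitness in a sex raises an explicit extinction error rather
  than propagating NaNs.
* Parameter validation is strict (reject, not clamp) everywhere except
  calibration, where documented clamps mirror how field data are handled
  (below).

## Calibration from bioassay data

Genotype-specific survival (alive/(alive+dead)) from exposed and unexposed
assay arms inverts the fitness construction:
effectiveness $= 1 - SS_{\text{exp}}$; restoration
$= (RR_{\text{exp}} - SS_{\text{exp}})/\text{eff}$; dominance of
resistance $= (SR_{\text{exp}} - SS_{\text{exp}})/(RR_{\text{exp}} -
SS_{\text{exp}})$; cost $= 1 - RR_{\text{unexp}}$; dominance of cost
$= (SS_{\text{unexp}} - SR_{\text{unexp}})/(SS_{\text{unexp}} -
RR_{\text{unexp}})$. Both dominance formulas are the inverse of the linear
interpolation used in the fitness construction, so a derived parameter set
reproduces its input survivals exactly (a round-trip the tests enforce).
Survivals are first rescaled by the unexposed SS survival so that the
reference genotype has fitness 1 — control-arm mortality otherwise leaks
into every parameter. Exposure and starting frequency cannot be inferred
from bioassays and stay user-supplied.

Field data are noisy, so the calibration clamps with warnings instead of
failing: a dominance outside $[0,1]$ (under-/over-dominance, biologically
implausible at these loci) is set to 1 so SR matches RR; exposed RR below
SS (no resistance signal) gives restoration 0; a missing control arm means
costs are assumed absent. The shipped `field_derived` preset calibrates a
pyrethroid/kdr and a carbamate/ace-1 parameter set from the packaged
survival tables (`inst/extdata/bioassay_*.csv`) and exhibits exactly these
clamps: the pyrethroid control arm shows underdominant costs (unexposed SR
0.50 below RR 0.67), so its dominance of cost is clamped to 1.

## The stochastic counterpart

`simulate_stochastic()` is an individual-based finite-population analogue
(multinomial gamete draws, binomial sex assignment and viability survival)
whose mean trajectory must agree with the deterministic recursion — the
test suite requires agreement within three standard errors at generation
20 with 10,000 individuals, alongside an exact ($10^{-10}$ over 100
generations) match to the closed-form one-locus selection recursion. It
exists to validate the deterministic engine and to explore drift at small
population sizes; it is not used by any strategy runner.

## What the test scenarios do and do not show

The parameter draws behind the property tests (effectiveness, exposure,
restoration, dominance uniform on sensible ranges; starting frequencies
0.001–0.1; costs up to 0.1) cover the operationally plausible region but
are still idealisations: one major gene per insecticide, constant
insecticide efficacy over time (no decay), no mosaics or rotations, no
density dependence, and no link from resistance frequency to vector
abundance or disease transmission. Passing tests demonstrate internal
consistency of the selection model and reproduction of its documented
behaviour, not a field prediction; the calibration example in particular
is a demonstration of parameter-setting, with small genotype samples and
surprisingly high control-arm mortality in the source data.

Problem sizes used throughout (4-element frequency vectors, at most 500
generations, 200 random property scenarios, 20 stochastic replicates of
10,000 individuals) keep any run at desk scale — the full suite completes
in seconds.
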