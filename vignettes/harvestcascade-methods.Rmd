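---
title: "Model and methods behind harvestcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind harvestcascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harvestcascade)
```

# The model

`harvestcascade` simulates a linear food chain of three or four trophic
levels (producer, primary consumer, secondary consumer, top predator), each
level a single asexual population of discrete individuals, iterated in
synchronous stochastic rounds. The producers graze a finite but replenishing
resource pool; every other level feeds exclusively on the level below it;
the top or penultimate level can be harvested at consistent effort. The
question the simulator addresses is how quantitative-trait evolution in the
*non-harvested* levels — along a competition–defense tradeoff — feeds back
on the abundance, yield and sustainability of the harvested species.

## Individuals and the competition–defense tradeoff

Each individual carries a quantitative genotype $G$ (a stand-in for a highly
polygenic performance trait) that simultaneously sets three phenotypes,
realized once at birth with a mean-zero environmental error $\epsilon$ on
each base rate:

$$a_i = (a_0+\epsilon_a)\left(1+\tfrac{A\,G_i}{100}\right),\qquad
  v_i = (v_0+\epsilon_v)\left(1+\tfrac{V\,G_i}{100}\right),\qquad
  d_i = (d_0+\epsilon_d)\left(1+\tfrac{M\,G_i^2}{100}\right),$$

where $a_i$ is the attack rate (competitiveness), $v_i$ the vulnerability to
predators (inverse defense), and $d_i$ the intrinsic death probability. $A$
and $V$ are the percent change per genotype unit of attack and
vulnerability; their ratio sets the tradeoff slope
$S = \partial_G a / \partial_G v = a_0 A / (v_0 V)$
(`tradeoff_slope()`). A large $A/V$ makes competition cheap, a small one
makes defense cheap. The quadratic canalization term $M$ (25 at every level
carrying a tradeoff) penalizes extreme trait values so that evolution does
not run away when predators are absent. Attack and vulnerability are floored
at 0, death probabilities clipped to $[0,1]$.

Inheritance is clonal with rare mutational input,
$G_{\mathrm{off}} = G_{\mathrm{par}} +
\mathrm{Bernoulli}(P_{\mathrm{mut}})\cdot\mathrm{Normal}(0,\sigma_{\mathrm{mut}})$,
with $P_{\mathrm{mut}} = 0.12$ and $\sigma_{\mathrm{mut}} = 0.05$. Founder
genotypes are Normal(0, 0.25) at evolving levels.

## One iteration

With start-of-iteration abundances $N$ fixed, one round computes, level by
level:

1. **Functional responses.** Each consumer's per-prey Holling type II rate
   $f_i = a_i/(1+h\,a_i N_{\mathrm{prey}})$, with handling time $h$.
2. **Deaths.** Each individual dies with probability
   $D_i = 1-(1-d_i)(1-d_{P,i})(1-f-\epsilon_f)$, where
   $d_{P,i} = \overline{f_{\mathrm{pred}}}\; v_i N_{\mathrm{pred}}$ is the
   predation hazard and the harvest factor applies only at the harvested
   level ($f$ the harvest intensity; $\epsilon_f$ a Normal(0, $0.05 f$)
   effort error drawn each iteration). Deaths are Bernoulli draws.
3. **Predation accounting.** The prey actually transferred up the chain is
   the predation-attributed fraction of realized deaths,
   $N_{\mathrm{eaten}} = \sum_{\mathrm{dead}} d_{P,i}/D_i$, and the
   harvest-attributed fraction is the yield
   $Y=\sum_{\mathrm{dead}} (f+\epsilon_f)/D_i$.
4. **Births.** Each individual's expected offspring is its conversion-
   efficiency-weighted share of the prey eaten one level down,
   $L_i = b\, f_i N_{\mathrm{eaten}} / (\bar f N)$; realized offspring are
   Poisson($L_i$). Summing the shares gives exactly
   $\sum_i L_i = b\,N_{\mathrm{eaten}}$, so biomass conversion is conserved
   and selection acts purely on relative shares.
5. **Resource.** The pool replenishes by $r(R_{\max}-R)$ and is grazed in
   proportion to the producers' mean response, capped at the pool.

All levels update synchronously: deaths are realized from start-of-iteration
abundances, and this iteration's prey-eaten counts feed this iteration's
births (an individual that dies can still have reproduced in the same
round). An extinct level stays extinct — collapses are observable, not
patched. Per-level parameters follow a geometric progression from the
producer (attack halves, handling time grows 100-fold, death rate quarters
per level), which makes abundance decrease and generation time increase up
the chain.

## Bifurcated experiments

Every experiment burns a community in with evolution running at the
configured levels, clones the end state at harvest onset, and runs the
harvest phase twice: an *eco-evolutionary* branch where evolution continues,
and an *ecology-only* branch where the evolving levels' genotypes are frozen
at the harvest-onset mean (environmental noise is retained, so phenotypic
variance persists; only heritable change is switched off). Differences
between the branches isolate the effect of non-target evolution. Replicates
are fully independent worlds; replicate $r$ uses seed stream
(`seed_for(base, r, branch)`) with branch 0 for the shared burn-in, so the
two branches of one replicate resume from a byte-identical state but
experience independent post-onset demographic randomness.

Phase lengths follow the evolving-level convention: 12,500 iterations when
the producer is the highest evolving level, 20,000 for the primary
consumer, 50,000 for the secondary consumer (burn-in and harvest phase
alike), long enough for quasi-equilibrium trait change given each level's
generation time.

# Calibration of the defaults

## The per-iteration rate scale

The canonical starting rates of this model family (producer attack
$6\times10^{-6}$, vulnerability 1, conversion $10^{-3}$, handling
$2\times10^{-10}$, death $10^{-3}$) leave the overall per-iteration time
scale and the abundance scale open. Two anchors pin them:

* the reference per-level generation-time profile the default community is
  calibrated to, $T \approx$ 1.55, 17.19, 54.15 and 639.50 iterations for
  levels 1–4, and
* the requirement that the producer population stays desk-scale.

At stationarity the mean parent–offspring birth interval of a level is
$T=(1-D)/D$, with $D$ its per-capita death probability. The top predator
pre-harvest dies only intrinsically, so $T_4 = 639.5$ fixes its realized
death rate at $1.56\times10^{-3}$ — 100× the tabulated value, i.e. the
trait equations' multiplier acting on its centered value of 100. Carrying
that factor through the mean-field equilibrium of the whole chain shows the
full $T$-profile is reproduced when attack, conversion and death carry
the factor 100 while vulnerability (a dimensionless multiplier) stays at
its tabulated value; any other assignment either breaks the profile or
drives the producer population to $10^9$ individuals. Hence
`producer_base_params(rate_scale = 100)`: realized producer rates
$a_0=6\times10^{-4}$, $b=0.1$, $d_0=0.1$ (with `rate_scale = 1` recovering
the tabulated numbers). Equilibrium abundances then come out near 1850,
1130, 210 and 145 individuals for levels 1–4.

Generation-time bookkeeping follows the age-at-reproduction convention: the
recorded interval is the parent's age at the start of the iteration in
which the offspring is produced, so a parent reproducing at its first
opportunity contributes 0. This is the convention consistent with the
reference $T$-profile (the producer discriminates sharply: the alternative
off-by-one convention gives $T_1 \approx 2.5$ instead of $\approx 1.5$).

## Resource pool

The resource is modeled as linear restocking toward a cap: replenish
$r(R_{\max}-R)$, then graze. Defaults $R_{\max}=24{,}500$, $r=0.5$ and
`graze_scale = 0.4` (the producers' per-resource-unit encounter rate is
`graze_scale * a0`; resource units are a granularity choice, not an
observable). These values are chosen so that (i) the producer per-capita
turnover matches its generation time ($D_1\approx0.41$), which makes
$R_{\max}$ the enrichment knob balancing the producer and
secondary-consumer generation times, and (ii) grazing is *partial* (mean
grazed fraction $\approx 0.45$). Partial grazing matters structurally: if
the pool were fully consumed every iteration, total producer intake would
be capped and attack-rate evolution could only redistribute shares,
severing the pathway by which producer competitiveness feeds back up the
chain. The granularity also tunes how strongly harvest perturbations
propagate to the bottom of the chain: a very fine-grained resource
(`graze_scale` $\ll 1$) lets producer productivity compensate consumer
changes almost completely, muting the cascade, while full grazing rigidly
caps the energy flux. The default sits between the extremes: the cascade
transmits (harvest measurably lowers primary-consumer abundance, releasing
producers) and both arms of the tradeoff remain under selection.

## Environmental noise and heritability

The per-lifetime environmental error on each trait is Normal with standard
deviation `noise_cv` times the base rate. Under clonal inheritance the
offspring-on-parent regression slope of the attack phenotype is

$$h^2=\frac{k^2\sigma^2}{k^2\sigma^2+c^2(1+k^2\sigma^2)},\qquad
k=\frac{A}{100},\ \sigma=\mathrm{founder\ SD},\ c=\texttt{noise\_cv},$$

and mutation leaves the slope untouched (it is independent of the parental
deviation). `calibrate_noise_cv()` inverts this for the target effective
heritability 0.6 at founder SD 0.25 — e.g. $c\approx0.060$ at the producer
setpoint $A=29.5$ — and is the default for every level with a tradeoff
(levels without one use $c=0.06$).

## Setpoints and sweeps

Tradeoff setpoints $(A,V)$ are (29.5, 39.3), (22.0, 45.4), (19.1, 52.5)
for producer, primary and secondary consumer under top-predator harvest
($f=0.0009$), and (20.5, 48.8), (17.0, 58.8) for producer and primary
consumer under secondary-consumer harvest ($f=0.0077$), the same pairs used
by the three-level "fishing down the food web" chain. Tradeoff sweeps move
the ratio $A/V$ at constant $A\cdot V$, so a grid multiplier $\rho<1$ makes
defense cheap and $\rho>1$ makes competition cheap without changing the
overall trait leverage. The cheap-competition end of a sweep has a hard
boundary: because death probabilities are capped at 1, the quadratic
canalization penalty stops acting once $d_0(1+MG^2/100)$ reaches the cap
(near $|G|\approx6$ at the default death rates), and with $A/V$ several
times the setpoint the selection gain on attack then drives unbounded trait
escalation. Sweeps therefore treat $\rho\approx4$ as the cheap-competition
extreme.

# Numerical and design choices

* **Stochastic draws** occur in a fixed order (effort error; Bernoulli
  deaths bottom-up; Poisson births, mutations, phenotype noise bottom-up),
  so a configuration plus seed fully determines every output byte. The
  compiled (Rcpp) phase loop reproduces the pure-R reference step draw for
  draw; a test asserts trajectory identity between the two engines.
* **Clamping.** Phenotypes are clamped (attack, vulnerability at 0; death
  and all combined probabilities to $[0,1]$), so extreme genotypes or error
  draws cannot leave the admissible range; the effort error is likewise
  clipped.
* **Harvested level never evolves**; non-evolving levels run with $G$
  pinned at 0 and environmental noise retained, which makes the two
  branches structurally identical apart from genotype updating.
* **Population scaling.** `pop_scale = s` divides attack rates by $s$ and
  multiplies the resource cap and initial sizes by $s$; every per-capita
  rate, death probability and generation time is preserved exactly, so
  scaled-down runs differ only in demographic noise. `phase_scale` shrinks
  phase lengths. Together they provide honest CI-scale runs.
* **Quasi-equilibrium is not tested for**; fixed phase lengths are used.
  The trailing-window coefficient of variation of abundance
  (`summarize_timeseries()`) serves as the stability diagnostic.
* **Windows.** Long-term comparisons (`compare_models()`, `yield_curve()`)
  average the terminal 25% of the harvest phase by default; the window is
  an argument, not a constant.
* **Collapse** is defined as zero abundance of the harvested level before
  the end of the phase; the collapse threshold of a harvest sweep is the
  smallest intensity with collapse in at least half the replicates.

# What the test problem sizes do and do not show

The package's own checks run the full default community for the
generation-time and heritability calibrations, the trophic-cascade and
feedback-sign checks at phases scaled by 0.25 with 6 replicate worlds, and
the tradeoff-regime sweep at phases scaled by 0.1 — sizes chosen as honest
reduced-scale versions of the full designs. At these scales the
*directions* of trait change at all three evolving levels and of the
adjacent-level feedbacks (one and two levels below harvest) are
reproducible run over run. The producer's twice-removed feedback on the
harvested species is a knife-edge in this model: at chain equilibrium the
harvested level responds to producer trait change in proportion to
$\frac{D_1}{D_1-d_1}\frac{A}{100}-\frac{V}{100}$, which is $\approx 0$ at
the producer setpoint $(A,V)=(29.5,39.3)$, and resource depletion and the
canalization cost push it slightly negative — so its sign is not a robust
prediction of this implementation at any scale, in contrast to the two
upper feedbacks. Scaled runs say nothing quantitative about full-scale
effect magnitudes, yield curves near maximum sustainable yield, or real
fisheries.

Known limitations: one species per level, no omnivory, no spatial
structure, no plasticity, clonal inheritance (no recombination or
dominance), a single basal resource, and discrete synchronous time.
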