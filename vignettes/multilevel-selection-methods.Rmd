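---
title: "Models and methods: Price accounting, toy models, and the mtDNA hierarchy"
author: "mlsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: Price accounting, toy models, and the mtDNA hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsel)
```

# The problem

Cooperation — paying a fitness cost to produce a benefit that partners can
consume — is exploitable: a cheater that consumes the benefit without
reciprocating outcompetes cooperators whenever both have equal access to
it. Within any mixed interaction group, cheaters therefore gain. Yet
cooperation persists in nature, from toxin-producing bacteria to the
mutualism between eukaryotic cells and their mitochondria. The resolution
is multilevel: when a community is partitioned into groups that *vary* in
cooperator frequency, cooperator-rich groups out-produce cheater-rich ones,
and the between-group advantage can outweigh the within-group loss.

Two families of mechanism generate or exploit that variance. In **partner
choice (PC)** a focal cooperative entity directs more benefit (or better
survival odds) to cooperative than to cheating partner entities even though
the partners are spatially equivalent. In **partner fidelity feedback
(PFF)** there is no discrimination among partners; instead interaction
groups persist long enough, and vary enough in cooperator frequency, that
cooperators reap the returns of their own acts. The same physical
mechanism can read as PFF at one level of the biological hierarchy and PC
one level up, so every operator in this package carries an explicit
`{level, PC|PFF}` annotation (`mechanism_annotations()`), and the package's
job is to make the bookkeeping and the mechanisms executable.

# Price-equation accounting

For groups indexed by \(i\), with initial cooperator frequency \(P_i\),
final size \(\pi_i\) and final frequency \(P_i'\), the Price identity

\[
\bar\pi\,\Delta\bar P \;=\; \mathrm{Cov}(\pi, P) \;+\;
\mathrm{Ave}(\pi\,\Delta P)
\]

splits the community-frequency change into a between-group covariance term
(rewritable as \(\beta\,\mathrm{Var}(P)\)) and a within-group change term.
`price_decompose()` implements two conventions:

* **uniform** (default): every group weighs \(1/G\) and the covariance is
  the population covariance, which matches the two-group worked example
  (weights 0.5 each). Under equal weighting the identity is exact when
  \(\bar P\) is the equally weighted mean of the group frequencies; this
  coincides with the pooled frequency (total cooperators over total
  members) whenever groups start at equal sizes, as in all worked
  examples. The object reports both the identity's \(\bar P\) and the
  pooled frequency so the distinction is visible rather than silent.
* **size**: groups weigh \(n_i/N\) and fitness is per-capita
  \(w_i = \pi_i/n_i\). The identity then holds with fully pooled community
  frequencies for arbitrary unequal group sizes.

Both are algebraic identities, and the package treats them that way: a
group that dies out contributes \(\pi\,\Delta P = k' - \pi P = 0\) (its
undefined final frequency never enters), centering \(P\) at any constant
leaves the covariance unchanged because \(\pi\) is centred at its own mean,
and an exact mode (`exact = TRUE`) evaluates every term in reduced rational
arithmetic so the residual is *identically* zero. The rational layer stores
integers in doubles with a hard guard at \(2^{53}\); that is exact at the
problem sizes the accounting is used for (tens of groups, sizes in the
tens) and fails loudly, never silently, beyond it.

## The deterministic group game

`reproduce_group()` is the one-generation rule behind the worked numbers: a
cooperator births one cooperator and grants each *other* member one extra
offspring before dying; a cheater births two cheaters. In closed form
\(c' = c^2\), \(d' = d(2+c)\), so within any mixed group the cooperator
frequency strictly falls, while cooperator-rich groups grow larger —
exactly the tension the Price identity accounts for. With two six-member
groups holding 1 and 5 cooperators the community frequency rises from 6/12
to 26/48 (\(\bar\pi = 24\), \(\mathrm{Cov} = 8/3\),
\(\mathrm{Ave} = -5/3\)); with 3 and 3 it cannot rise (zero variance).

`run_generations()` chains generations by pooling all offspring and
re-forming groups. The reproduction rule itself is a single-generation
object; pooled re-formation is the standard trait-group lifecycle and keeps the
across-group variance a per-generation experimental knob
(`form_groups()` schemes: multivariate-hypergeometric `random`, explicit
`fixed-counts`, maximal-assortment `perfect-segregation`; individuals that
do not fill a group form a final smaller group so nobody is dropped).
`cull_groups()` abstracts selective abortion of cheater-dominated units:
one operator, two readings (PC for the higher-level chooser, PFF for the
groups that die with their members).

# The toxin–antitoxin model

Cooperators carry a toxin–antitoxin pair; at a density threshold
(`K = 250` by default) a fraction `s = 0.1` of them lyse and each lysis
kills up to `k = 2` cheaters; cooperators are immune (screening-type PC:
the fixed response favours cooperative neighbours without recognition).
Per episode cooperators lose the fraction \(s\) while cheaters lose
\(k s C / D\), so cheater frequency declines iff the cooperator frequency
exceeds \(1/(1+k)\) — independent of \(s\) when cooperators grow as fast
as cheaters. That threshold is why 210/250 cooperators eliminate all
cheaters in one episode while 50/250 trade 10% of themselves for 5% of the
cheaters, a net loss. With a growth cost the critical frequency is the
fixed point of the grow-then-lyse cycle map, located numerically with
`uniroot`. Suicides are rounded half-even (`round()`), which is exact at
the printed values; kills are capped at the cheaters present.

`lattice_trajectory()` adds the spatially structured regime on a torus with
Moore neighbourhoods. The update rule is this package's design choice (the
threshold argument above fixes no spatial algorithm): synchronous colonisation of empty sites by
growth-rate-weighted neighbours, then density-triggered lysis killing up to
`k` cheaters drawn at random within a Chebyshev `kill_radius`, applied
sequentially in seed-determined random order. Local killing plus local
reproduction makes the killing benefit accrue to the killer's own
neighbourhood — repeated local interaction is the PFF ingredient that joins
the PC immunity, and a clustered 2% cooperator minority reliably expands
where the well-mixed threshold says it must die. Setting
`density_scope = "global"` and `kill_radius = Inf` removes the locality and
recovers the well-mixed outcome on the same machinery. Defaults (40×40
grid, 60% initial occupancy, crowding at ≥7 of 8 neighbours, 120 steps)
were chosen so the clustered-minority regime is comfortably inside the
mechanism's operating range: the first handful of steps merely fill the
lattice (transiently diluting the minority), and the killing-driven
expansion works on a slower timescale, so the horizon is several multiples
of the fill time; at 2% of a 40×40 grid the founding cluster is large
enough (~19 cells) that early stochastic extinction is rare. These are
scale choices, not estimates of any real plate.

# Proportional tit-for-tat

`ptft_probability()` encodes the rule: cooperate in round 1, then cooperate
with probability equal to the previous round's fraction of cooperative
*partners*. pTFT never singles out an individual, so PC is absent by
construction. The payoff envelope is a linear public good: a cooperative
act costs `cost` and delivers `b/(n-1)` to each partner; `b = 3`,
`cost = 1` are documented as arbitrary (the pTFT rule itself fixes no
payoffs). Inside any mixed group a cheater weakly dominates a pTFT player
every round, so pTFT can only win on the across-group margin.
`ptft_requirements_experiment()` makes the two PFF requirements a 2×2
factorial: round number (1 vs 20) crossed with across-group variance
(half-and-half groups vs assorted 8:2/2:8 groups at fixed totals). The
high-variance arm is deliberately assorted-but-*mixed*: complete
segregation would let pTFT win even in a single round (cheater groups earn
nothing), which is not the claim under test. pTFT out-earns always-cheat
only in the repeated × high-variance cell.

# The mtDNA → mitochondrion → cell → organism hierarchy

A dysfunctional mtDNA replicates at least as well as a functional one in
the same heteroplasmic pool but delivers less benefit upward — a
within-entity cheater. The simulator nests four entity levels and exposes
each counter-mechanism as a toggleable operator:

| operator | level | reading |
|---|---|---|
| `delta` (replication advantage) | mtDNA in mitochondrion | the cheater advantage itself |
| `mito_fitness` | mitochondrion vs its mtDNAs | PFF: dysfunctional genomes slow their own carrier |
| selective import, `segregation_bias`, `mitophagy` | cell vs mitochondria | PC: the cell discriminates among spatially equivalent organelles |
| `apoptosis_rule` | cell vs its mtDNAs | PFF: the cell dies with its cargo |
| `bottleneck_size` | organism → offspring | PFF enabler: variance source |
| `organism_fecundity` | organism vs its mtDNAs | PFF: the organism's output rides on its load |

Mechanics, bottom-up, per generation: every mitochondrion divides with
probability `mito_fitness(functional fraction)`, first growing its pool to
twice its copy number by a sequential weighted urn (per-copy weight
\(1+\delta\) for dysfunctional — implemented in C++ because the draws are
inherently one-at-a-time), then splitting binomially; mitophagy destroys
each organelle with odds multiplied by
\(1 + \text{selectivity}\,(1-f)\,w\); germ cells divide with organelle
assignment probabilities \(0.5 \pm \text{bias}/2\) by the organelle's
binary functional status (threshold: at least half functional mtDNAs);
apoptosis removes cells by their heteroplasmy; each organism then leaves
`round(organism_fecundity(h))` offspring, each founded by a hypergeometric
draw of `bottleneck_size` molecules from the pooled germline (optionally
weighted toward functional molecules — selective import), amplified back to
the adult copy number under the same urn, and partitioned exactly (without
replacement) into the offspring's organelles and cells. The population is
capped at `n_organisms` by uniform sampling, so all *directional*
organism-level selection flows through the fecundity map. `h = 0` and
`h = 1` are absorbing: there is no mutation in scope (an extension point,
not an omission by accident).

Per generation the simulator also runs the Price decomposition with
organisms as groups of mtDNAs — initial size/cooperators are the adult
functional counts, final size/cooperators the molecules actually
transmitted through offspring founders (so \(\pi\) is proportional to
realised offspring number). The identity holds exactly on these records,
tying the hierarchy back to the accounting layer.

## Parameter and scale choices

None of the hierarchy's rates is tied to a measured biological value, so
all claims about it are property claims, not value claims, and the
defaults are scale choices: 10 mtDNAs per mitochondrion, 8 mitochondria
per cell, 4 germ cells per organism, 20 organisms. These sizes keep a
multi-generation, many-seed experiment in seconds while leaving every
level genuinely populated (organelle-level selection needs several
organelles per cell; bottleneck variance needs founder samples well below
the adult copy number of 320). Where tests compare filter settings they
use paired seeds and, for within-lifetime mechanisms such as selective
mitophagy, the one-generation mean response — measured before the germline
bottleneck injects transmission drift, which at these population sizes
otherwise dominates the signal. The filter-efficacy experiment
(bottleneck 4 + quadratic apoptosis + declining fecundity against a
δ = 0.5 background, versus the same background with a loose bottleneck
and no filters) uses 12 organisms × 8 generations × 100 paired seeds.

# What the synthetic settings do and do not show

Every experiment in this package runs on data the package itself
generates; nothing is fitted to measurements. Passing tests therefore show
that the *mechanisms* behave as the theory says they must — identities
hold, thresholds sit where the algebra puts them, variance scales as
\(1/N_b\), filters move heteroplasmy the right way — under the stated
rules. They do not show that any real system sits at these parameter
values: real mitochondrial dynamics involve continuous quality variation,
mutation pressure toward dysfunction, paternal leakage, and biochemical
feedbacks (membrane potential, ROS) that are all out of scope here, and
the lattice model is an abstraction with no diffusion chemistry. The
binary cooperator/cheater and functional/dysfunctional dichotomies are the
working definitions of the framework, chosen for analytical transparency.

# Numerical choices, determinism, degenerate inputs

* All stochastic entry points take a `seed`; one global seed expands to
  per-component streams via `derive_seed()` (an affine hash modulo
  \(2^{31}-1\)), so toggling one mechanism does not perturb another's
  stream. Identical seeds give bit-identical outputs.
* Rounding that affects counts is round-half-even (`round()`), exact at
  the worked values; printed-precision output columns round to two
  decimals (two significant digits below 0.1) to mirror how the worked
  examples print.
* Degenerate inputs are contracts, not crashes: empty groups and
  out-of-range rates error immediately with field-level messages
  (`load_config()` enforces the same ranges at file load); population
  extinction in a running simulation is *reported* in a `status` field,
  never raised, because it is a legitimate outcome.
* The exact-rational mode refuses (with an explicit overflow error) rather
  than degrade to floating point.

# Known limitations

* Uniform-weight Price accounting with *unequal* initial group sizes
  reports the equally weighted mean of group frequencies as the identity's
  \(\bar P\); users wanting fully pooled frequencies with unequal sizes
  should use `weights = "size"`. Both objects expose the pooled frequency
  for comparison.
* The lattice model's update order (synchronous colonisation, then
  sequential random-order lysis) is one defensible choice among several;
  conclusions drawn from it are qualitative.
* Multi-generation group-game runs with `fixed-counts` require the counts
  to stay feasible as the population changes; the scheme is intended for
  single-generation demonstrations, with `random` or
  `perfect-segregation` for dynamics.
* `iterated_group_game()` reports payoffs only; mapping payoff to
  reproduction (an evolutionary dynamic over strategy frequencies) is
  deliberately out of scope.
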