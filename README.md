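# oligonet

Design and kinetic-dispersion analysis of DNA oligomer networks.

DNA nanotechnology builds reaction networks out of short single-stranded
oligomers that recognize each other by Watson-Crick pairing. Nominally
identical hybridization reactions nevertheless show rate constants spread
over orders of magnitude, and a major controllable cause is *unnecessary
duplexes* — accidental complementary runs within or between strands that
the designer never intended. `oligonet` is for people who design such
networks (strand displacement circuits, reporters, probe panels) and for
people who re-analyze hybridization rate data: it finds every unnecessary
duplex a design can form, scores them, optimizes sequences to remove them,
and quantifies the kinetic dispersion they cause.

## The scores and the rule

A duplex window of length `L` is worth `10^L` fitness points; a maximal run
of `M` contiguous pairs contributes all of its sub-windows (`M - L + 1` of
each length `L`). Summed over the network:

* `N` — points over all inter-oligomer alignments (every unordered species
  pair, including each species against an identical copy of itself),
* `O` — points over all intra-oligomer pairings,
* `W_x = N + x·O` — the weighted combination (default `x = 10000`),
* `ΔN`, `ΔO`, `ΔW_x` — the same after subtracting the *necessary* windows,
  i.e. the pairings implied by the design's domain structure. A design with
  `Δ`-scores of zero forms exactly the duplexes it declares.

Since any intra-oligomer structure can also form between two copies of the
strand, `N ≥ 2·O` always. The "no 3's and no 8's" design rule passes a
network that has no unnecessary intra-oligomer duplex of 3+ bp and no
unnecessary inter-oligomer duplex of 8+ bp.

Around the scores sit an evolution-inspired optimizer that permutes bases
within variable domains (`optimize_network()`), a random-sampling study of
how `ΔN` and `ΔO` scale with network size via `a·i^b·j^c` power laws
(`scaling_study()`, `fit_power_law()`), bootstrap estimators of kinetic
dispersion — the interquartile range of `ln k` — for fitness-ranked versus
random sub-populations (`bootstrap_dispersion_fit()`,
`bootstrap_dispersion_random()`), and second-order / Arrhenius /
enthalpy-entropy-compensation fitting of hybridization kinetics
(`fit_rate()`, `arrhenius_fit()`, `compensation_fit()`).

## Worked example

Two strands intended to form one 4-bp duplex: domain `a = AACG` on strand
`X` and its reverse complement on strand `Y`.

```r
library(oligonet)
design <- oligo_design(variable = c(a = "AACG"),
                       oligomers = list(X = "a", Y = "a*"))
net <- compile_network(design)
net
#> Oligomer network: 2 oligomers, 8 bases
#>   X (4 nt): AACG
#>   Y (4 nt): CGTT
fitness(net, x = 1)
#> Fitness report (x = 1, intraSLC = 1, interSLC = 1)
#>   N  = 12,600   dN  = 260
#>   O  = 20   dO  = 20
#>   Wx = 12,620   dWx = 280
#>   largest unnecessary intra/inter: 1 / 2 bp
```

The intended duplex contributes the necessary baseline (12,340 points: one
4-bp window, two 3-bp, three 2-bp, four 1-bp). The remaining `dN = 260`
comes from two off-register 1-bp pairings of X with Y and a self-complementary
CG/CG register in each strand's self-alignment; `dO = 20` from one 1-bp
hairpin pair per strand:

```r
duplex_profile(net)
#> Duplex profile
#>   largest unnecessary intra-oligomer run: 1 bp
#>   largest unnecessary inter-oligomer run: 2 bp
#>   unnecessary windows by length:
#>     intra : 1bp x 2
#>     inter : 1bp x 6, 2bp x 2
```

This toy design already passes the rule. A realistic one usually does not:
the three-strand formation/displacement model system
(`model_system_design()`, a 49-bp intended duplex with a fixed `TCTCCATG`
toehold) starts with dozens of unnecessary duplexes, and the optimizer
removes every rule-violating one by scoring only windows at or above the
rule thresholds (`intraSLC = 3`, `interSLC = 5`):

```r
res <- optimize_network(model_system_design(seed = 1),
                        evolver_config(CPL = 2500, NL = 8,
                                       intraSLC = 3, interSLC = 5,
                                       scoringWeightX = 1e6, seed = 51))
res
#> Sequence evolution result
#>   objective dW (x = 1e+06): 330000900000 -> 0
#>   cycles: 2500  lineages: 8  evaluations: 19576
rule_check(res$best_network)$pass
#> [1] TRUE
```

An objective of 0 means no unnecessary intra window of 3+ bp and no
unnecessary inter window of 5+ bp remain anywhere in the network.

Three one-liners from the analysis side:

```r
threshold_min_j(c(0.0526, 1.56, 3.63), 1e3, i = 1)  # fitted dO law crosses
#> [1] 16                                             # 10^3 at a 16-mer
largest_intra_fraction(16, 10000, seed = 1) * 100   # % of random 16-mers
#> [1] 58.42                                          # with a 3-bp hairpin run
derived_constants(19.1, 20.6e19)                    # compensation line ->
#> $C3 1.97e+08   $Tc 352                             # max rate, critical temp
```

A command-line interface wraps the same functions; the installed script is
at `system.file("scripts", "oligonet", package = "oligonet")` with
subcommands `profile`, `rulecheck`, `evolve`, `scaling`, `dispersion`,
`kinetics`, and `fixtures`.

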