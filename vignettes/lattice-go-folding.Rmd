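---
title: "Methods: lattice Go-model folding of circular-permutant families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lattice Go-model folding of circular-permutant families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A protein is a chain of `N` beads on the simple cubic lattice: consecutive
beads sit one lattice spacing apart and no two beads share a site.  A
*non-bonded native contact* is a pair of beads, non-contiguous along the
chain, that occupy neighbouring sites in the native structure.  The
interaction potential is native-centric (Gō-type): a conformation's energy
is

E(conf) = -epsilon * (number of native contacts formed),

with `epsilon = 1` and `kB = 1`, so all temperatures and free energies are
in reduced units.  Non-native adjacencies carry zero energy: the
Hamiltonian contains only the native-contact sum, which is the standard
reading of a pure Gō potential, and the question the model isolates is how
*topology alone* shapes folding.  Under this energy the reaction coordinate
`E` is equivalent to the fraction of native contacts `Q` up to a constant
factor.

Native structures are maximally compact conformations: Hamiltonian paths
filling an `a x b x c` cuboid.  Such a path touches
`(a-1)bc + a(b-1)c + ab(c-1)` lattice edges, of which `N - 1` are chain
bonds; the remainder are native contacts.  For the 48-mer on the 3x4x4
cuboid this gives 104 - 47 = 57 contacts, and a native energy of -57.
Because beads at unit distance have opposite coordinate-sum parity, every
contact has odd sequence separation of at least 3.

The *contact order* (CO) of a structure is the mean sequence separation
`|i - j|` over its native contacts.  At fixed chain length absolute and
relative CO rank structures identically, so the absolute value is used
throughout.

## Circular permutants

A circular permutant joins the native termini and cuts the backbone at
bead `k`: bead `j` of the permutant is bead `(j + k) mod N` of the parent.
The construction is defined whenever the parent's termini are adjacent on
the lattice; the old terminus-terminus contact becomes the new bond and
the cut bond becomes a contact, so the contact count is invariant across
the family (asserted by enumeration in the tests) while CO varies.  A
family contains exactly `N` permutants (`k = 0` is the parent).  One
parity caveat: on a bipartite lattice a Hamiltonian path of an odd-volume
cuboid (e.g. 3x3x3) must start and end in the same sublattice, so its
termini can never be adjacent; odd-volume fixtures therefore carry no
family.

## Parent generation by homopolymer collapse

`collapse_homopolymer()` anneals a homopolymer whose energy is -1 per
non-bonded contact, confined to the target cuboid extended by one layer
along its longest side.  Inside that confinement the target cuboid is the
unique contact-maximising shape (extending a short side admits degenerate
competitors, which we observed at N = 24 and N = 40), so reaching the
ground state means reaching a Hamiltonian path of the cuboid.  The
schedule (geometric cooling 2.0 to 0.3 over 30 stages, then a search phase
at T = 0.5) is config-exposed.

Terminus adjacency needs care.  The annealed chain freezes into a single
Hamiltonian-path basin, and instrumented runs showed that waiting for a
frozen path with adjacent termini is hopeless: across seeds, about 1e5
ground-state visits produced none.  The generator therefore gives the
terminus-terminus pair - which is itself one of the non-bonded pairs of
the homopolymer energy - an extra weight (default 4) during collapse.
Compact states with adjacent termini then become the annealing ground
states; all of them remain degenerate with one another, so the bias
selects the required subset without ordering it, and it plays no role in
any Gō-model simulation afterwards.  Different seeds yield different
parents (observed CO between about 13 and 18 for 48-mers).  High- and
low-CO parents are chosen as the extremes of a seeded candidate pool
(default 200 runs; ties broken lexicographically).

## Monte Carlo move set and detailed balance

The move set is local: end moves (a terminal bead re-placed at a free
neighbour of its bonded neighbour), corner flips (a right-angle bead moved
across the square diagonal) and crankshafts (a U-shaped bead pair rotated
by 90/180/270 degrees about the axis through its flanking beads).  One
attempted elementary move is one MC time unit; null and rejected proposals
advance time without moving the chain.

Proposals are drawn from a fixed per-bead slot space: 6 slots at a
terminus (one per direction around the anchor), 7 for an interior bead
(corner flip + three rotations for each of the two possible crankshaft
pairs).  A drawn slot whose move is geometrically illegal or collides is a
null proposal.  Because the slot space is fixed and the reverse of every
realizable move occupies exactly one slot at the same bead, the proposal
density is exactly symmetric; "pick one legal candidate uniformly" is not,
since candidate counts can differ between the two endpoints of a move.
Metropolis acceptance `min(1, exp(-dE/T))` then preserves detailed
balance, which the tests verify directly: the sampled energy histogram of
the 8-mer toy matches exact Boltzmann enumeration over all 81390
self-avoiding 8-bead walks within three standard errors per level.

## Equilibrium sampling, heat capacity, WHAM

Replica-exchange (parallel tempering) MC with a geometric temperature
ladder samples the whole conformational spectrum; adjacent replicas swap
with probability `min(1, exp((1/Ti - 1/Tj)(Ei - Ej)))`, alternating pair
parity between rounds.  The production default is about 50 replicas
spanning half to twice a pilot estimate of the melting temperature.  For
the desk-scale studies in the test suite we use 14-24 replicas spanning
0.75-1.35 of the pilot estimate: concentrating replicas near the
transition roughly halved the activation-energy noise at fixed cost.
Replicas start from the native conformation, which is the equilibrium
state of the cold end of the ladder; burn-in discards the melting
transient of the hot end.

The heat capacity is the fluctuation estimate `Cv = var(E)/T^2`; the
melting temperature `Tm` is the `Cv` peak refined by parabolic
interpolation through its neighbours.  The density of states is estimated
by the standard multi-histogram (WHAM) iteration in log space, with
histogram bin width fixed at one reduced unit because Gō energies are
exact integers.  Convergence: maximum change of the per-temperature shifts
below 1e-7, cap 1e5 iterations; non-overlapping adjacent histograms are an
error naming the gap.  Free-energy profiles are
`F(E; T) = E - T ln Omega(E)` up to a constant; energy levels never
sampled (some are geometrically unrealisable, e.g. one broken contact from
the compact state) are simply absent from the grid.

## Barrier analysis and two-state classification

On the profile at `Tm`, the folded minimum is the lowest-energy basin (at
`-epsilon * n_contacts` when sampling has reached the ground state), the
barrier is the global maximum between the folded basin and the
highest-energy basin, and the unfolded minimum is the global minimum above
the barrier (near `E = 0`).  The activation free energy is
`dG = F(barrier) - F(unfolded)`, reported both in reduced units and in
thermal units `dG/Tm` so that the transition-state-theory regression of
`ln k` has an expected slope of -1.  All annotations are invariant under
additive shifts of the profile.

Any extra local minimum between the barrier and the folded minimum whose
flanking maxima exceed a depth threshold (default 0.2 reduced units,
config-exposed) marks a post-transition-state intermediate and the
permutant is excluded from family regressions as a non-two-state folder.
The threshold is a declared stand-in: the quantitative criterion used for
the original exclusion of such permutants is not published.  The barriers
of these intermediates are small, which is why a depth threshold rather
than mere existence of a dip is used.  Monotone profiles are flagged
`barrierless`, never silently processed.

## Folding kinetics

Folding rates come from independent fixed-temperature trajectories (500
per permutant under the production defaults), each starting from a fresh
uniform random coil and stopping when all native contacts are formed;
first passage times are in MC steps, so rates are comparable only within
the study, which is all the correlation analyses need.  The unfolded
survival `Pu(t)` is evaluated on a log-spaced grid and `k` is the negative
slope of a weighted linear regression of `ln Pu` on `t` over the window
`Pu` in [0.05, 0.95] (weights `n Pu / (1 - Pu)`, the inverse binomial
variance of `ln Pu`).  The window trims the short-time transient and the
noisy tail; a weighted residual above 0.1 flags non-exponential decay, and
censoring above 5 percent flags the rate unreliable.  Calibration at the
production trajectory count (n = 500, synthetic exponential data): bias
about -0.1 percent, relative RMSE about 4.9 percent; a planted two-rate
mixture trips the residual flag.

## Transition-state ensembles and networks

Candidates are trajectory snapshots within one reduced unit of the barrier
energy (window config-exposed), deduplicated up to translation.  Each
candidate's commitment probability (Pfold) is the fold fraction of
independent trials that reach the native state before the fraction of
native contacts drops to `q_unfold = 0.2` (the unfolded basin sits near
`E = 0`; 0.2 cleanly separates the basins and is config-exposed).  With
100 trials the binomial standard error at `p = 0.5` is 0.05, matching the
five-percent error requirement; trials hitting the step cap count as
indeterminate and more than 10 percent of them flags the estimate.  The
ensemble keeps candidates with `|p - 0.5| <= 0.1` and `SE <= 0.05`.

For each member the contact order is computed over its *formed native*
contacts (non-native adjacencies carry no energy and the analysis concerns
native topology); `CO_TSE` is the ensemble mean.  `RMSD_TSE` is the mean
least-squares superposition RMSD to the native structure in lattice units
(Kabsch/SVD solution, reflections excluded; the tests bound it by the
24-lattice-rotation brute force).  The transition-state network (TSN) is
the set of native contacts present in the ensemble with frequency at least
`p_star = 0.5` (config-exposed; the published threshold is not available
in the source text), with its size `n`, mean separation `CO_TSN` and
contact-range spectrum.

## Reproducibility

One master seed drives everything: per-permutant, per-stage streams are
derived deterministically, and the compiled sampler uses its own
xoshiro256++ generator so trajectories are bit-reproducible across
platforms.  Identical seeds give identical family tables; the tests assert
this end to end.

## Desk-scale study sizes, and what they do and do not show

The full study conditions (48-mers, about 50 replicas, 500 trajectories
per permutant, all 48 permutants of two families) are the package
defaults, but a complete 48-mer family at its melting temperature costs
tens of CPU-hours: at `Tm` the measured activation barrier is about 6
thermal units and the median first passage time about 5e9 MC steps per
trajectory.  The test suite therefore runs the same pipeline end to end on
24-mer families (2x3x4, 23 contacts, full circular-permutant families of a
high- and a low-CO parent drawn from a 12-candidate pool) plus 8-mer and
18-mer fixtures with exactly enumerable properties.

What carries over at that scale, with the study's own seeds: melting
temperatures across each family agree to within 2-3 percent; the high-CO
family shows a stronger, correctly signed rate-contact-order correlation
than the low-CO family; and the high-CO family loses many permutants to
post-transition-state intermediates while the low-CO family loses few.
What does not: the quantitative transition-state-theory regression (slope
-1, |r| >= 0.9 of `ln k` against `dG/Tm`).  Desk-scale barriers are only
1-2.5 thermal units, and the measured between-permutant spread of the
kinetic prefactor (about 1.2 in `ln k` units) is as large as the barrier
spread, so the correlation is attenuated to about 0.5-0.75 even with the
sampling noise driven well below the spread; the clean TST regime needs
barriers several times `kT`, i.e. the 48-mer study conditions.  The 8-mer
toy is too small even to define a barrier: exact enumeration shows its
free-energy profile over six energy levels is single-basin at every
temperature.  Synthetic-data checks (exponential rate recovery, two-level
thermodynamics, Boltzmann enumeration) close the gap by validating each
estimator against ground truth independently of system size.

## Known limitations

- Pure Gō energetics: no non-native attraction or repulsion beyond
  excluded volume, no side chains, no sequence.
- Rates are per attempted elementary move; no mapping to physical time is
  claimed, and only within-study comparisons are meaningful.
- The collapse generator samples termini-adjacent compact conformations
  uniformly at the ground-state level only approximately (annealing is not
  an equilibrium sampler over basins).
- The folding nucleus, as distinct from the transition-state network, is
  not computed.
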