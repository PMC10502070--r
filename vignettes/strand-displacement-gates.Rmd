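---
title: "Domain-level semantics of strand-displacement logic gates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-level semantics of strand-displacement logic gates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsdgates)
```

## The system being modelled

A strand-displacement reporter gate is a DNA duplex made of a template
strand carrying a BHQ1 quencher and an incumbent (reporter) strand
carrying a FAM fluorophore. While the two are hybridised, the
fluorophore sits next to the quencher and the solution is dark. Input
strands that are complementary to runs of the template can invade the
duplex and displace the reporter; a released reporter fluoresces. The
gate's logic is the map from which inputs are present to whether the
reporter comes off.

`dsdgates` works at the *domain* level: the template is an ordered list
of named domains (indexed 1..n, 5'→3', matching the left-to-right
reading of the usual gate diagrams), complementary domains are named by
case swap (`F`/`f`), and every strand is a list of domains. Individual
nucleotides enter only in the sequence-design layer. Three designs are
built in (`paper_gate()`):

* **OR** — template `E-F-H-G`, reporter `fh` on positions 2–3, toeholds
  `E` and `G` exposed; inputs `efh`, `fhg`, `efhg`.
* **AND** — blunt duplex `ABCD:abcd`, no exposed toehold; inputs `ab`,
  `cd`, `bc`.
* **MAJORITY** — template `E-F-H-G`, reporter `fh`; inputs `ef`, `hg`,
  `fh` (the third input shares the reporter's domain composition but is
  unlabelled).

Strand names follow the diagram convention of naming a strand by the
template domains it covers; antiparallel orientation is carried entirely
by `complement()`, which reverses the domain list, rather than by
re-ordering names.

## The chain-reachability rules

The logical engine (`evaluate_gate()`, `truth_table()`) decides release
by growing *displacement chains* to a fixpoint (`extend_chains()`):

1. **Strong anchor.** An input complementary to an exposed toehold can
   initiate displacement there (`anchor_sites()`).
2. **Weak anchor (terminal fray).** An input complementary to the
   template's terminal domain (position 1 or n) can initiate there even
   though the position is paired, via end fraying. This is the only
   entry point into a blunt duplex.
3. **Overlap joining.** An input whose template run overlaps an
   anchored chain's coverage in at least one position joins the chain
   and extends its coverage — hand-over-hand displacement, where the
   junction left by the previous invader acts as an internal toehold.
4. **Release.** The reporter comes off iff a single chain's coverage
   contains its whole footprint, or the union of strongly anchored
   chains' coverages does. Disconnected weak chains never cooperate:
   two independent fray events cannot sustain a continuous migration
   front, so `ab` + `cd` (which jointly cover the blunt AND duplex but
   share no position) leave it closed.

Rules 2–4 are this package's mechanistic model of cooperative
displacement on a blunt duplex; they are the unique minimal discipline
under which the three built-in designs realise OR, AND and MAJORITY
simultaneously. Joining is computed as connected components of the
run-overlap graph, which makes the fixpoint trivially order-independent;
chains are presented sorted by anchor position only for stable output.

```{r}
truth_table(paper_gate("MAJORITY"))
```

## The brute-force oracle

`oracle_enumerate()` is an independent check on the chain rules: a
breadth-first search over per-position occupancy states of one template
molecule, with moves (i) bind at a free position of the invader's run,
(ii) fray-bind at a terminal position, (iii) bind onto a position held
by an overlapping fellow invader, and (iv) single-position branch
migration in either direction, for invaders and the incumbent alike.
Strand copies are in excess; a strand holding nothing has unbound. A
state counts as "released" under the same anchoring discipline as rule
4, evaluated on the state itself: either one run-overlap-connected group
of bound invaders holds the whole footprint, or groups containing a
toehold-capable member jointly do. The search is exhaustive within a
state budget and reports an explicit inconclusive error if the budget is
hit, never a silent 0. The test suite checks oracle/engine agreement on
all 24 built-in gate rows and on 100 random fixtures of 4–8 domains
(800 comparisons, about 2 s); templates are capped at 8 domains to keep
the state space enumerable.

## The kinetic layer

`compile_reactions()` turns a gate plus input combination into a
stochastic mass-action network whose channels correspond one-to-one to
the logical moves; branch migration inside a chain is coarse-grained
away, since the observable is endpoint fluorescence. A complex species
is "this template with this set of inputs bound, reporter attached or
not". Channels and default rates (`rate_parameters()`, arbitrary time
units):

| channel | condition | rate |
|---|---|---|
| strong anchoring | input has an exposed-toehold anchor | `k_strong = 1` |
| overlap joining | input's run overlaps an anchored chain on the complex | `k_join = 1` |
| fray anchoring | input has only a terminal-fray anchor | `k_fray = 1e-3` |
| dissociation | input alone in its chain | `k_unbind1 = 0.1` |
| release | bound set satisfies rule 4, reporter attached | `k_release = 10` |

The three-orders-of-magnitude gap between `k_strong`/`k_join` and
`k_fray` mirrors the qualitative hierarchy of toehold-mediated vs
toehold-free invasion; `k_release` is fast because a fully displaced
reporter holds nothing. Released complexes are inert (no rebinding or
leak channels by default), which makes the zero-input baseline exactly
zero. Every channel conserves each strand's total copy number
(`check_conservation()`).

`simulate_network()` runs Gillespie's direct method (the inner loop is
compiled C++ for speed); identical `(network, t_end, seed)` give
identical trajectories, and the caller's RNG state is untouched.
`readout()` converts an endpoint into a signal: the free fraction of
reporter strands times `F_max = 150` a.u., binarized at the boundary
`50` a.u. — strictly above is 1, below is 0, and exact equality is
reported as 0 with a warning since the boundary rule only defines
"above" and "below". `F_max` is chosen so that even a half-released
population (free fraction 0.5 → 75 a.u.), as can arise when an
unlabelled input shares the reporter's composition and exchanges with it
symmetrically, binarizes to 1 while the baseline stays 0. Defaults
elsewhere: `copies = 100` per species at 1:1 input:duplex
stoichiometry (the annealing convention), `t_end = 1e4`, ten seeds per
truth-table row with the median signal reported. Signal magnitudes are
in arbitrary units throughout; only their position relative to the
boundary is meaningful.

```{r}
kinetic_truth_table(paper_gate("AND"), seeds = 1:3)
```

## Sequence design

`assign_sequences()` draws random ACGT sequences per canonical domain
(defaults: toeholds 6 nt, recognition domains 15 nt — typical
strand-displacement practice; the domain-level logic never depends on
these lengths), under three constraints: GC fraction in [0.3, 0.7], no
homopolymer run longer than 4, and no 6-mer shared in either orientation
with any previously assigned domain. The last constraint means generated
sets pass the `validate_orthogonality()` k-mer screen at the same word
length by construction; the screen itself remains useful for sequences
imported from FASTA. Lower-case domains are reverse complements of their
partners, strand sequences are 5'→3' concatenations of their domain
sequences, and FASTA import re-derives and re-validates the assignment
(length, alphabet, cross-record consistency, reverse-complement
pairing). The shipped `inst/extdata/or-gate-synthetic.fasta` is a
synthetic assignment produced this way, not a laboratory sequence set.

## The fixture generator

`generate_fixture()` emulates the three archetypes at 3–8 domains
(toehold-flanked reporter, blunt cooperative duplex, two-toehold
majority design) and draws fully random valid systems for property
testing. The archetypes are generalised so their truth tables remain
exactly OR/AND/MAJORITY (the AND-like bridge input spans the junction of
the two halves; the MAJORITY-like third input is the reporter's
composition), which the suite asserts for several sizes. Random
fixtures emulate structural validity only — contiguous complementary
runs, labelled duplex, three inputs — and deliberately not any
particular logic, experimental salt/temperature conditions, or
sequence-dependent thermodynamics; tests passing on them show the two
engines agree on the model, not that the model predicts any specific
wet-lab outcome beyond the three designs it was built from.

## Numerical and design choices

* Intervals are 1-based inclusive; footprints and input runs must be
  contiguous, validation errors name the offending element.
* Duplicate strand names are allowed only for identical domain
  composition (the MAJORITY design reuses the reporter's composition as
  an input); FASTA export then emits identically named, identical
  records.
* `extend_chains()` deduplicates chains with the same kind, members and
  coverage, so a cooperative chain seeded from both ends appears once.
* The oracle's default state budget is 2e5; the AND/OR/MAJORITY
  state spaces are a few hundred states, 8-domain random fixtures a few
  thousand.
* Problem sizes in the shipped suite: 100 random fixtures for
  oracle-equivalence and monotonicity properties, 10 seeds x 8 states x
  3 gates for the kinetic consistency check, 100 seeds for the
  orthogonality Monte-Carlo — together about half a minute.

## Known limitations

* No pseudoknots, 4-way migration, hairpins, or leak pathways; the
  optional leak rate is off by default and the logical layer has no
  notion of partial signal.
* Kinetic rates are phenomenological and unitless; the model is not
  calibrated to spectrophotometer units, so only binarized outputs (and
  not bar heights) are comparable to fluorescence data.
* Sequence design screens k-mer cross-talk only — no melting
  temperatures, no secondary-structure prediction.
* The terminal-fray and overlap-joining rules are a deliberately
  minimal mechanism; real blunt-end invasion kinetics are far slower
  and leakier than a two-rate separation can express.
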