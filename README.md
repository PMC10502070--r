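# dsdgates

Domain-level simulation of DNA strand-displacement logic gates.

DNA strand displacement is the workhorse of molecular programming: an
input strand anchors at a single-stranded toehold on a reporter duplex
and, by branch migration, displaces the incumbent strand. When the
incumbent carries a FAM fluorophore and the template a BHQ1 quencher,
displacement turns fluorescence on, so a set of input strands computes a
Boolean function readable in a fluorometer. `dsdgates` is for people
designing or teaching such circuits: it models gates at the domain
level (named domains, upper/lower case for complements), decides for
any input combination whether the reporter is released, and produces
both digital truth tables and stochastic fluorescence-style kinetics.

Three three-input designs are built in:

| gate | duplex | inputs | logic |
|---|---|---|---|
| OR | `EFHG : fh`, toeholds `E`,`G` exposed | `efh`, `fhg`, `efhg` | x₁ ∨ x₂ ∨ x₃ |
| AND | blunt `ABCD : abcd` | `ab`, `cd`, `bc` | x₁ ∧ x₂ ∧ x₃ |
| MAJORITY | `EFHG : fh` | `ef`, `hg`, `fh` | 1 iff ≥ 2 inputs |

The core of the package is a chain-reachability semantics: inputs
anchor at exposed toeholds (strong) or at frayed template ends (weak),
inputs whose template runs overlap an anchored chain join it
hand-over-hand, and the reporter is released iff one chain covers its
whole footprint or the strongly anchored chains jointly do. Disconnected
weak chains never cooperate — that is what makes the blunt AND duplex
require all three inputs. An exhaustive state-space oracle
(`oracle_enumerate()`) independently verifies every decision, and a
Gillespie simulator compiled from the same rules produces endpoint
signals binarized at a boundary of 50 a.u. (scale 150 a.u.). See the
vignette `vignettes/strand-displacement-gates.Rmd` for the model in
detail.

## Worked example

```r
library(dsdgates)
gate <- paper_gate("MAJORITY")
gate
#> <gate 'MAJORITY': template EFHG (4 domains), reporter fh on 2..3>
#>   INPUT1: ef (5'-e-f-3')
#>   INPUT2: hg (5'-h-g-3')
#>   INPUT3: fh (5'-f-h-3')

truth_table(gate)
#> state      output
#> (0 0 0)    0
#> (1 0 0)    0
#> (0 1 0)    0
#> (0 0 1)    0
#> (1 1 0)    1
#> (1 0 1)    1
#> (0 1 1)    1
#> (1 1 1)    1
```

Each row is one input state (INPUT1 INPUT2 INPUT3); output 1 means the
fluorophore-labelled reporter `fh` is displaced from the quenched
duplex, i.e. the well lights up. A single input cannot displace the
reporter (no single run covers the footprint), while any two cooperate
— either from both toeholds at once, or with the `fh` input joining an
anchored chain through its overlap at `F` or `H` — so the gate computes
the majority function.

The stochastic engine reaches the same table through kinetics (median
endpoint signal over ten seeds, 100 copies per species, binarized at
50 a.u.):

```r
kinetic_truth_table(gate, seeds = 1:10)
#> state      output  signal_au
#> (0 0 0)    0          0.0
#> (1 0 0)    0          0.0
#> (0 1 0)    0          0.0
#> (0 0 1)    0          0.0
#> (1 1 0)    1        150.0
#> (1 0 1)    1        150.0
#> (0 1 1)    1        150.0
#> (1 1 1)    1        150.0
```

Gates can also be loaded from structured spec files
(`read_gate_system()`, YAML or JSON; an example ships in
`inst/extdata/or-gate.yaml`), given nucleotide sequences
(`assign_sequences()`, with a k-mer orthogonality screen) and exported
to FASTA. `generate_fixture()` builds OR/AND/MAJORITY-like and random
valid gates of 3–8 domains for testing.

A command-line wrapper is installed as `exec/dsdgate`:

```sh
dsdgate evaluate --gate AND --state 110 --engine both
# AND (1 1 0) -> 0 (signal 0.0 au)
dsdgate truthtable --gate OR --out or.csv
```

Exit codes: 0 success, 2 validation error, 3 logical/kinetic
disagreement, 4 oracle inconclusive.

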