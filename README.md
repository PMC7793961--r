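# mesovm

A meso-scale virtual machine for plastic neural circuits in R.

## The problem

How can a bio-inspired artifact *learn* the association between percepts
and actions of incomparable modalities — say, a right/left spatial
percept and a forward/backward gear selection — instead of having it
wired in? mesovm implements a computational answer: neural circuits are
modelled not as biophysical neurons but as **asynchronous communicating
threads** linked by weighted, threshold-gated synapses, executed by a
virtual machine with two time scales — per-thread local clocks *T*
(micro scale) and per-stream sequence numbers *I* (meso scale). Synaptic
plasticity is abstracted as a coincidence detector: when two internal
stimuli are emitted under the same stream sequence number, long-term
potentiation and depression (`ltp`/`ltd`) shift link weights across
their gating thresholds, closing one pathway while opening another
(inhibition/disinhibition switching). A link is OPEN iff
`weight > threshold`; with the defaults (closed = 0, open = 1,
threshold = 0.5, δ⁺ = δ⁻ = 1) a single coincidence flips a path.

The package is aimed at computational-neuroscience and neuro-robotics
modellers who want to experiment with circuit-level learning rules —
classical and operant conditioning, and the learning of causality rules
from synchronized multimodal perceptions — without committing to any
biophysical neuron model.

It ships:

* the VM kernel (`vm_run`, `vm_sense`, `vm_react`, `vm_reflect`,
  `deduce_instruction`) with deterministic scheduling and event traces;
* a symbolic circuit language (thread patterns with instruction trees,
  ground or wildcard links) with compiler, validator, a diffable text
  file format and DOT rendering;
* a circuits library: synaptic transmission, classical conditioning,
  operant conditioning, and the autonomous-vehicle fire detectors
  (random, and plastic in instantiated or generalized mode);
* a one-dimensional track world (fire, smoke, gears, home station) whose
  gear-to-direction mapping is hidden ground truth the circuits must
  discover;
* tidy tooling: traces are tibbles, reports have `tidy()`, `glance()`
  and `autoplot()` methods, plus a thin command-line runner.

## A worked example: learning a causality rule

The vehicle sits at home on a 7-position track with a fire at
`right(3)`. In `general` mode the plastic links are wildcard
(`sense(right(_))`), so one successful episode learns the rule
"if detect(right(_)) then move(forward)":

```r
library(mesovm)
rep <- run_scenario(figure_scenario("fig17"))
rep
#> <vm_report> fig17: cleared, 11 event(s), fetch_count = 1
#> 0: learn(right):fetch(forward)
#> 1: recall(forward):inhibit
#> 1: recall(backward):inhibit
#> 1: move(forward):excite
#> 1: detect(right(3)):inhibit
#> 2: move(forward):excite
#> 2: detect(right(3)):inhibit
#> 3: move(forward):excite
#> 3: detect(right(3)):excite
#> 3: detect(right(3)):clear
#> 3: detect(right(3)):stop
```

Reading the trace: each line is `I: thread:stimulus`. At `I = 0` the
open learn pathway draws a gear at random (the internal `fetch`
stimulus). The closed recall gates knock (`inhibit` at `I = 1`). Then
each stream tick pairs the move thread's positional excite with the
detect thread's fire check — inhibit, inhibit, and at `I = 3` **two
simultaneous excite stimuli**: the vehicle is on the fire and on a
defined coordinate at the same stream tick. That synchronized pair
triggers the plasticity step, then the fire is cleared and the run
stops. The weight changes hit the wildcard links:

```r
subset(rep$weights, before != after,
       select = c(from, to, before, after, open))
#> # A tibble: 2 × 5
#>   from            to              before after open
#>   <chr>           <chr>            <dbl> <dbl> <lgl>
#> 1 sense(right(_)) learn(right)         1     0 FALSE
#> 2 sense(right(_)) recall(forward)      0     1 TRUE
```

The learn pathway is now inhibited and recall(forward) disinhibited for
*every* right-direction coordinate: replaying with a fire at `right(5)`
clears it deterministically with `fetch_count = 0`, while a fire on the
left still goes through learning. `reproduce_figures()` runs the whole
published sequence (random detector both directions, instantiated
learning / replay / failure at a new position, generalized learning /
rule application) with the learned weights carried between consecutive
runs.

From a shell, the same run is:

```sh
Rscript inst/cli/mesovm.R --preset fig17 --trace-out run.jsonl --format jsonl
```

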