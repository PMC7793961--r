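---
title: "Circuits, clocks and coincidence: the mesovm execution model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circuits, clocks and coincidence: the mesovm execution model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesovm)
```

## The model

mesovm simulates neural circuits at a *meso* scale: individual neurons are
not modelled biophysically (no membrane equations, no spike shapes) but as
**threads** — communicating entities, each standing for a neuron or a
whole assembly, that process their inputs individually rather than summing
them. A circuit is a set of thread patterns, each enclosing a finite tree
of instructions, plus a table of directed **links** between threads. A
link carries a dimensionless weight and a threshold and is *OPEN* iff
`weight > threshold`; transmission through a closed link is blocked. Two
synaptic protocols are abstracted from plasticity physiology:

* **send/receive** — asynchronous transmission subject to the gate: the
  sender never blocks (it enqueues a signal and fires the recipient when
  the gate is open); the receiver consumes one queued signal only if the
  weight stands above the threshold, and otherwise retries.
* **join/merge** — coincidence detection: a `join` succeeds only when its
  peer has posted a token (an explicit `merge`, or any excite stimulus)
  under the *same stream sequence number*. A successful coincidence is
  what enables the weight changes `ltp` (potentiation, `+ δ⁺`) and `ltd`
  (depression, `− δ⁻`).

Learning is therefore inhibition/disinhibition path switching: a
coincidence of percepts potentiates one pathway above its threshold
(disinhibition) while depressing another below it (inhibition). This is
the package's extended Hebbian step: synchronized multimodal stimuli,
rather than co-firing cells, are what wire pathways together.

### Two time scales

The machine keeps two clocks:

* **micro-scale**: each thread instance has a local time `T`, incremented
  by exactly one after each *successful* instruction. A failing
  instruction (a receive with nothing above threshold, a join with no
  token) leaves `T` unchanged and is retried on a later pass.
* **meso-scale**: each stream (activation episode) has a sequence number
  `I`, starting at 0 when the stream activates. `I` advances on motor
  commands: every execution of the `drive` primitive ticks the stream
  once, whether or not displacement occurred (a blocked attempt at the
  track limit is still a motor command). Two events are *synchronized*
  iff they carry the same `I`.

There is no central clock. The scheduler (`vm_run`) is a deterministic
round-robin: one instruction per runnable instance per pass, instances
ordered by activation; instances activated mid-pass take their first turn
on the next pass. The run halts at a **fixpoint** — a pass in which no
stimulus was captured and no instruction succeeded cannot be followed by
a different one, so the machine is quiescent; `stop` ends motor activity
and lets residual signalling (plasticity enabled at the synchronization
tick) drain to the fixpoint. `max_cycles` (default 500 passes) bounds
runs that spin forever; hitting it is flagged as truncation, distinct
from normal termination.

### Contextual deduction

Compiled code is indexed by `(thread, T)`: `deduce_instruction()` returns
the unique instruction a thread executes at its local time, under its
current parameter bindings. Where both ground code (`right(3)`) and
wildcard code (`right(_)`) match an instance, the more *specific* (more
ground nodes) entry wins; two equally specific candidates are a
compile-integrity error. Bodies are stored as numbered instruction lists
with explicit branch targets rather than literal trees: the
resume-detecting/resume-moving loops of sensory and motor threads need a
back-edge, and keeping the loop in the control graph (rather than
unbounded code) preserves the invariant that `T` increases by exactly one
per success while the program position is a separate register.

The variable alphabet is the single letters `F`–`Z` minus `P`, `Q`, `R`
(which circuit diagrams in this tradition reserve for thread names, as
they do `A`–`E`); `_` is the anonymous wildcard and matches exactly one
term. Variables may sit in functor position: `F(X)` matches `right(3)`
binding `F = right`, `X = 3` — this is how a synchronization thread
recovers the coordinate it witnessed from the token it joined.

## The vehicle experiment

The bundled world is a one-dimensional track with coordinates `F(X)`,
`F ∈ {right, left}`, `X = 1..7` by default, and a home station `_(0)`.
The vehicle has a forward and a backward gear; **which gear drives in
which direction is the environment's hidden ground truth** (forward →
right, backward → left). No circuit encodes this mapping — discovering it
is the learning problem, so the smoke percept arms the sense thread but
carries nothing to the gear choice.

Two detector circuits are provided:

* `build_random_detector()` — a wired decision tree: on smoke, `choice`
  draws a gear (emitting an internal `fetch` stimulus), the vehicle
  drives step by step, and after every motor command the detect thread
  re-checks `on(F(X))` while the move thread reports the positional
  `at(F(X))` feedback. Because the detect scan is cued by the move thread
  and the move thread waits for the scan's verdict before the next step,
  the two percepts are evaluated under the same stream tick: on the fire,
  both produce `excite` simultaneously — the synchronization the plastic
  circuit exploits. This circuit has no plastic link and provably never
  changes behavior.
* `build_deterministic_detector(mode =)` — the same sensory-motor loop
  with an operant fork grafted on: `sense` feeds a `learn` pathway
  (initially open) and `recall(forward)` / `recall(backward)` pathways
  (initially closed). The synchronization thread joins the detect-excite
  and move-excite tokens and then potentiates `sense → recall(gear)` and
  depresses `sense → learn`. In `instantiated` mode the plastic links are
  ground (one per coordinate): each position is learned separately. In
  `general` mode they are wildcard links `sense(right(_))`: one
  successful episode learns the causality rule "if detect(right(_)) then
  move(forward)", which transfers to every coordinate of that direction
  while the opposite direction stays unlearned.

### Tick accounting and the printed trace numbers

The accounting conventions are calibrated once against the published
traces and then fixed:

* the fetch stimulus of the initial gear choice is reported at `I = 0`;
* on the 7-position track a wrong-direction run shows move-excite /
  detect-inhibit pairs at `I = 1..7`, the move thread's limit inhibit at
  `I = 8`, its confirming inhibit at `I = 9`, and the stop — the
  confirmation (one retry of the blocked boundary check before
  committing to stop) is why the terminating inhibit lands at 9;
* a send into a *closed* gate enqueues the signal, never fires the
  recipient, and reports an inhibit attributed to the recipient's gate.
  Such events fall between stream ticks and are reported at the
  following tick. In the replay run after instantiated learning this
  places the closed learn path's inhibit at `I = 1`, alongside the
  closed `recall(backward)` gate's and the detect thread's — the
  repeated inhibit at time 1 — while the run proceeds with zero fetch.

The within-tick ordering of simultaneous events follows the scheduler
(move before detect); only the grouping by `I` is meaningful.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `weight` | 1 (open) / 0 (closed) | dimensionless synaptic strength per link |
| `threshold` | 0.5 | gate: link OPEN iff weight > threshold |
| `delta_up`, `delta_down` | 1 | ltp increment / ltd decrement per coincidence |
| `length_per_direction` | 7 | track coordinates per direction |
| `max_cycles` | 500 | scheduler pass budget per run |

With the defaults a single coincidence flips a path (0 ↔ 1 across the
0.5 threshold): the circuits here describe binary open/closed switching,
and one-shot flipping reproduces every published run. Gradual acquisition
— *k* pairings to learn — is expressed per link by `delta_up = 1/k`.
`ltd` fires on the same coincidence as `ltp`, targeting the complementary
pathway; no depression occurs on non-coincidence, so a failed search run
changes no weight. Negative reinforcement in the operant fork is treated
symmetrically to positive (reject-path ltp plus learn-path ltd); whether
depression can also be driven by negative stimuli independent of any
coincidence is left out, as the fork semantics only need the symmetric
case.

## Design choices made where the design was open

* **Scheduling.** Threads are logically concurrent; any interleaving is
  admissible. The deterministic round-robin in activation order makes
  every run replayable and makes the printed traces the single source of
  truth for regression tests.
* **Coincidence window.** Same stream tick `I`. No temporal asymmetry is
  imposed within a tick: the conditioning scenario is run with the
  conditioned stimulus slightly preceding the unconditioned one, and
  nothing in the modelled behavior depends on the reverse order being
  rejected.
* **Unknown stimuli** are logged and dropped rather than raised: sensors
  may fire with no listener in larger circuits.
* **Stop-after-clear.** After clearing the fire the run stops immediately
  (the alternative — continuing to the limit — is a world option left
  unexposed because every reproduced run stops at the clear).
* **Environment-side reset.** After a failed run the vehicle returns home
  with the detector re-armed; the return trip consumes no stream ticks
  and is not part of the reported trace. Plastic weights persist in the
  circuit object across runs (`run_scenario()` returns the updated
  circuit); the world is rebuilt per run.
* **Extra opcodes.** The instruction set reconstructed here adds `drive`
  (the motor primitive: one motor command with positional feedback —
  without it no instruction could move the vehicle) and `switch` (the
  operant fork's positive/negative discriminator). Both are documented
  with the rest of the instruction set in `?instructions`.

## What the generator and tests do and do not show

All inputs are generated in-process; there is no external data. The
synthetic scenarios emulate the study conditions exactly: a 7-position
track, one fire, forced or seeded random gear choices, and single
activation episodes. The randomness calibration checks the `choice`
primitive against a fair binomial over 2000 seeded runs. What passing
tests show is that the execution model reproduces the published traces
and properties under those conditions; they say nothing about noisy
perception, continuous kinematics, multiple concurrent streams, or
biological plausibility of the one-shot weight flip — all outside this
model by construction.

Numerical notes: weights are plain doubles and gate comparisons are
strict (`>`); with the default integer-valued weights and 0.5 thresholds
no tie is possible. Problem sizes throughout the suite are the study's
own (tracks of 5–7 positions, circuits of 2–8 threads, 2000-run
calibration), chosen to match the published experiment.

## Known limitations

* One stream per run: fibers with several concurrently active streams
  are representable but untested territory.
* The trace records the scheduler's interleaving within a tick; only
  grouping by `I` is contractual.
* `deduce_instruction()` deduces only at the instance's current local
  time (the machine state does not retain past contexts).
* No real-time or hardware interface: the machine is a simulator, and
  gear/direction physics live entirely in the bundled world.
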