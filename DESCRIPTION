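Package: mesovm
Title: A Meso-Scale Virtual Machine for Plastic Neural Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discrete-event virtual machine for simulating asynchronous
    neural micro-circuits at a meso scale. Circuits are sets of communicating
    threads (neurons or neural assemblies) linked by weighted, threshold-gated
    synaptic connections; long-term potentiation and depression are abstracted
    as coincidence-triggered weight changes that open and close pathways
    (inhibition/disinhibition switching). The machine maintains two time
    scales - per-thread local clocks and per-stream sequence numbers - and
    reports traces of synchronized events. Includes a symbolic circuit
    language with compiler and validator, a library of classic circuits
    (synaptic transmission, classical and operant conditioning, random and
    plastic fire detectors for an autonomous-vehicle learning experiment),
    a one-dimensional track world, scenario runners, and tidy trace tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
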