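# rigflow

Actor-based dataflow pipelines for experimental rigs, in R.

Behavioural experiments are pipelines: cameras and sensors produce
streams, task logic transforms them, and savers and actuators consume
them — often across devices that each keep their own frame counter.
rigflow is a headless engine for running such pipelines described as a
graph of **Source**, **Transform** and **Sink** nodes connected by
directed port-to-port links. It is aimed at experimenters and rig
engineers who want (a) each pipeline stage isolated in its own process
with actor-model semantics, (b) *no* hidden buffering — a stage that
cannot keep up drops packets, and every drop is logged — and (c) the
provenance machinery to reconstruct exact cross-device frame
correspondences after the fact.

## The model

A running graph of *N* nodes is exactly **2N + 4 OS processes**: a
director, three publish–subscribe forwarders (proof-of-life, parameters,
data), and a relay ("com") plus worker process per node. Workers implement
three hooks — `initialise`, `work`, `end_of_life` — where `work` is an
infinite-loop body for sources and a callback for transforms and sinks.
Delivery is **at-most-once**: a packet arriving while a node's callback is
busy is dropped, never queued, and per-link counters satisfy

```
emitted = delivered + dropped          (exactly, on every link)
```

Every relay logs `(upstream_packet_id, local_packet_id)` pairs, so a chain
of relays defines a composable relation between what a device generated
and what was saved. With a shared TTL pulse train — a base train at
*f* Hz triggering camera A, and a divide-by-*k* pulse divider producing an
*f/k* Hz train triggering camera B (120 Hz → ÷4 → 30 Hz in the reference
rig) — divided pulse *j* maps to base pulse *k·j*, and saved frames of B
map to saved frames of A through the composed logs, drops and all.
Parameters flagged updatable can be changed while the graph runs; the
worker applies them between work passes.

The package also ships ready-made nodes (scripted sources, pulse divider,
table sink, an external-process wrapper that manages a child executable
over a handshake protocol) including a complete probabilistic
reversal-learning (PRL) task: a trial generator (two alternating blocks, a
2×4 reward-contingency matrix over four stimulation types, block lengths
uniform on a range) wired in a loop with a trial controller (odour →
pre-response delay → response window → reward window).

## Worked example

Parse the bundled PRL graph (note the generator/controller 2-cycle), run
it live, and read back the saved trial table:

```r
library(rigflow)
g <- parse_graph(system.file("extdata", "prl_graph.json", package = "rigflow"))
print(g)
#> <rigflow graph: 4 nodes, 4 edges, schema 1>
#>   KeyPress##0                  source    in:[] out:[Key Out]
#>   Trial Generator##0           transform in:[Start/Previous Trial Result] out:[Trial Definition]
#>   Trial Controller##0          transform in:[Trial Definition] out:[Trial Result,Trial History]
#>   Save Table##0                sink      in:[Row In] out:[]
#>   ...

g$nodes[[2]]$parameters[[5]] <- parameter_spec("max_trials", 25L, updatable = FALSE)
h <- start_graph(g, run_config(log_dir = "/tmp/readme_run", seed = 42))
process_census(h)
#> [1] 12        # 2 x 4 nodes + 4 engine processes
Sys.sleep(3)
stop_graph(h)
#> <termination report: 4 nodes, 4 links, 0 forced, 0 orphans>
#>   KeyPress##0/Key Out->Trial Generator##0/... emitted 1  delivered 1  dropped 0
#>   Trial Generator##0/Trial Definition->...    emitted 25 delivered 25 dropped 0
#>   Trial Controller##0/Trial Result->...       emitted 25 delivered 25 dropped 0
#>   Trial Controller##0/Trial History->...      emitted 25 delivered 25 dropped 0

head(read.csv("/tmp/readme_run/logs/Save_Table_0_table.csv")[, 1:5], 5)
#>   trial_number block_index stim_type correct_port_licked rewarded
#> 1            0           0         1                TRUE     TRUE
#> 2            1           0         0                TRUE     TRUE
#> 3            2           0         1                TRUE     TRUE
#> 4            3           0         0                TRUE     TRUE
#> 5            4           0         0                TRUE    FALSE
```

The `12` is the live process census; the counters show the single
key-press start packet and 25 trials circulating the loop with nothing
lost. With the same seed, a rerun saves an identical table.

Drop accounting on the reference capture chain — a camera device
generating 216,300 frames relayed through a capture node and a video-save
node that together lose 56:

```r
ref <- reference_capture_chain(n_origin = 216300, n_drops = 56, seed = 1)
compose_chain(ref$substate, ref$logs)
#> <correspondence: 216300 origin -> 216244 terminal, 56 dropped (0.03%)>
```

And cross-device alignment on a simulated lossy rig (120 Hz base train,
÷4 divider, both chains dropping frames), checked against the simulator's
hidden ground truth in the test suite:

```r
rig <- simulate_rig(rig_sim_config(duration = 30, drop_probs_a = c(0.01, 0.005),
                                   drop_probs_b = c(0.005, 0.01), seed = 7))
a <- compose_chain(rig$chain_a$substate, rig$chain_a$logs)
b <- compose_chain(rig$chain_b$substate, rig$chain_b$logs)
map <- align_two_chains(a, b, rig$chain_a$substate, rig$chain_b$substate, rig$pulses)
head(map[, c("b_terminal", "divided_pulse", "base_pulse", "a_terminal", "matched")], 4)
#>   b_terminal divided_pulse base_pulse a_terminal matched
#> 1          0             0          0          0    TRUE
#> 2          1             1          4          4    TRUE
#> 3          2             2          8          8    TRUE
#> 4          3             3         12         11    TRUE
sum(map$matched)
#> [1] 879      # of 887 saved B frames; the 8 others flagged, not deleted
```

## Command line

```sh
inst/cli/rigflow validate --graph experiment.json
inst/cli/rigflow run      --graph experiment.json --duration 60 --seed 1 --log-dir runs/today
inst/cli/rigflow align    --substate-a sub_a.csv --logs-a log1.csv,log2.csv \
                          --substate-b sub_b.csv --logs-b log3.csv \
                          --pulse-record pulses.csv --division-factor 4 --out-dir out/
inst/cli/rigflow scaffold --type transform --name "My Filter" --dir nodes/
```

Exit codes: 0 success, 1 violations/failures, 2 unusable input. A run
leaves its termination report, per-link counters, com logs and substate
tables under one log directory.

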