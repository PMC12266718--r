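---
title: "rigflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rigflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rigflow runs behavioural-experiment pipelines described as graphs of
*nodes* — sources that only emit data, transforms that receive and emit,
and sinks that only receive — connected by directed port-to-port links.
This vignette explains the execution model, the provenance and
synchronisation machinery, the probabilistic reversal-learning (PRL) task
logic, and the design decisions taken where more than one reasonable
choice existed.

## The actor topology

A running graph of $N$ nodes is exactly $2N + 4$ operating-system
processes:

* one **director**, which owns the run: it spawns everything else, pushes
  parameter values, emits a heartbeat, and orchestrates the graceful stop;
* three **forwarders** — proof-of-life, parameters, and data — which are
  topic-based publish–subscribe brokers; every message between actors
  passes through one of them, so no actor needs to know another's address;
* per node, a **com** process (the relay: it subscribes to the node's
  inbound links, hands packets to the worker one at a time, and publishes
  the worker's output downstream) and a **worker** process (which runs the
  user's three hooks: `initialise`, `work`, `end_of_life`).

Each process is an actor in the strict sense: its state is private and can
only be influenced by messages. A camera node's gain, say, can only be
changed by sending that node a parameter message — never by another
component reaching into its memory.

Start-up is ordered: the director brings up the forwarders, then each
node's com and worker *in authoring order* (the order nodes appear in the
graph file — there is no topological sort, because cycles are legal and
load-bearing: the PRL task wires its trial generator and trial controller
into a 2-cycle). A worker only enters service after its `initialise` hook
has succeeded and it has sent one proof-of-life message; if any worker
fails this, the whole start aborts and every spawned process is reaped.
Data flow opens only after every proof of life has arrived and initial
parameter values have been pushed, which also guarantees that every
subscription is registered before the first packet is published — no
packet can be lost to a subscription race.

### At-most-once delivery and drop accounting

The engine never buffers. While a node's callback is running, its com
marks the worker *busy*; any packet arriving on an inbound link during the
busy window `[callback start, callback return)` is counted as dropped and
discarded. A packet arriving in the same instant the callback returns is
delivered. This is a deliberate design for live experiments: stale sensor
frames are worthless, and an unbounded queue behind a slow consumer is a
silent failure mode. The cost — lost packets — is made fully auditable:

* every emitting worker stamps its packets with a per-node id starting at
  0 and increasing by one per emission;
* every com appends one row per *delivered* packet to its **com log**
  (`upstream_node, upstream_packet_id, local_packet_id, timestamp_ns`),
  with local ids gapless from 0;
* per-link counters `{emitted, delivered, dropped}` satisfy
  `emitted = delivered + dropped` exactly. The stop protocol makes this an
  invariant rather than an approximation: workers publish an end-of-stream
  marker behind their last packet, coms relay it downstream, and a com only
  freezes its counters after it has seen end-of-stream on every inbound
  link — so every in-flight packet is counted one way or the other.

### Parameters, heartbeat, lifecycle

Parameters are pushed through the parameter forwarder and applied by the
worker *between* work passes, so a pass sees either the old or the new
value, never a mixture. Parameters declared non-updatable are refused at
the director with an error acknowledgement. The director heartbeats once
per second; a worker that misses five beats assumes the run is dead and
executes its own end-of-life — the defaults are our choice, as only the
mechanism, not the numbers, is prescribed by the design. On a graceful
stop every worker runs `end_of_life` exactly once, flushes its substate
table, and reports; a worker stuck in a callback past the grace period
(default 10 s) is killed and recorded as forced. After `stop_graph()` the
orphan count is asserted to be zero. A process that has exited but not yet
been reaped by its parent (a zombie) is counted as dead, since it can
never run again and holds no resources.

### Wire format

Packet payloads are lists with one item per declared output, each item a
numeric tensor or a string-keyed record. Payload items travel in a
self-describing little-endian binary framing (type tag, shape, raw
buffer), and integer tensors round-trip bit-exact — a requirement for the
provenance machinery, where ids are data. Engine-internal control frames
(hellos, acks, subscriptions) use R's native serialization; they never
carry scientific data. Transport is framed TCP on the loopback interface
with `TCP_NODELAY` set: with Nagle's algorithm enabled, small frames
incur ~40 ms coalescing stalls that would dominate the busy-window
semantics.

Remote placement fields in graph files are parsed and validated, but
`start_graph()` refuses them ("remote execution not implemented"): graph
files stay forward-compatible with multi-machine execution without this
package pretending to provide it.

## Provenance reconciliation and time alignment

Because drops are logged rather than hidden, an exact correspondence
between what a device generated and what was saved can always be rebuilt.
`compose_chain()` composes the relay relations stage by stage: the origin
substate enumerates the ids the device assigned, and each com log maps the
previous stage's ids to the next. The result is a strictly increasing,
injective map from terminal (saved) indices to origin indices, plus a drop
summary that is additive over stages. The implementation is a sequence of
index joins; the test suite checks it against a brute-force relational
join on every instance up to $10^5$ packets and against the hidden ground
truth of the seeded chain simulator.

Cross-device alignment uses the pulse-divider common-clock scheme: a base
TTL train (120 Hz in the reference rig) triggers camera A directly and,
through a divide-by-$k$ pulse divider ($k = 4$, giving 30 Hz), camera B.
Both trains are recorded on one common device, and each camera's substate
links its frames to pulse indices. `divided_pulse_origin(j, k)` attributes
divided pulse $j$ to base pulse $k \cdot j$ — the **first** pulse of its
group of $k$. The group-onset convention is ours (onset versus offset is
not dictated by the divider arithmetic); it is documented, configurable
(`onset = FALSE` gives $k j + k - 1$), and consistent between the
simulator and the alignment code. `align_two_chains()` then maps each
saved B frame to its saved A partner; B frames whose partner was dropped
are kept with an `NA` partner and a `matched = FALSE` flag rather than
deleted, because an audit trail that silently removes rows is not an audit
trail. All ids everywhere are 0-based.

Relay timestamps are taken on the com's monotonic clock at delivery time;
whether the relay or the worker clock stamps the log is an open choice,
and the com clock was chosen because it is the process that witnesses
every arrival, including drops.

## The PRL task

The task logic lives in pure functions so it can be simulated and tested
without the engine, and in worker factories
(`worker_trial_generator`, `worker_trial_controller`) that run it live.

The **generator** organises trials into two alternating blocks. Each block
assigns every stimulation type a reward probability (the *contingency
matrix*); block lengths are drawn uniformly (inclusive) from a configured
range. Per trial it draws a stimulation type uniformly over the four
types, draws reward availability from the current (block, stimulation)
cell, and updates a per-port tally of correct licks from the previous
trial's history. The reference configuration — our choice, since only the
structure (two blocks, four stimulation types, a length range, a
contingency matrix) is fixed by the design — is

* contingencies `0.8 0.8 0.2 0.2` (block 0) and `0.2 0.2 0.8 0.8`
  (block 1), so a reversal swaps the favourable stimuli;
* block lengths uniform on `[20, 40]` trials, long enough for behaviour to
  track the contingencies but short enough that several reversals occur in
  a 10^3-trial session.

Stimulation types map to lick ports in consecutive pairs
(`port = stim %/% 2`). The correct-lick tallies influence nothing by
default: block transitions are length-based, because the exact
performance rule the tallies feed is not recoverable from the task
description. An optional, clearly-labelled extension
(`performance_rule = list(m, w)`: advance after `m` correct in the last
`w` trials) is provided but off by default.

The **controller** plays one trial through four phases in fixed order —
odour window, pre-response delay, response window, reward window (defaults
0.5 / 0.25 / 1.5 / 1.0 s) — against a rig event stream, and reports
licks, correctness, and reward. `reward_only_after_lick = TRUE` gates
reward delivery on a correct-port lick inside the response window; with
the gate off, an available reward is delivered regardless. Serial-port
parameters (`com_port`, `baud_rate`) are accepted for graph-file
compatibility and ignored with a warning: the rig in this package is a
simulated event stream, not hardware. The live controller worker runs each
trial on a simulated clock (phases advance logically, not in wall time)
and simulates the subject itself (a lick on the correct port with
probability `p_correct_lick`, else the other port); this makes live
sessions fast and exactly reproducible under a fixed run seed.

## Synthetic fixtures

Everything the tests consume is generated by seeded code:

* `simulate_rig()` builds the full two-camera rig — base and divided pulse
  trains, both capture chains with per-stage Bernoulli drops — and emits
  exactly the CSV formats the provenance functions read, alongside a
  ground-truth event table kept separate from the observables. Pulse times
  are integer nanoseconds computed with integer arithmetic only
  (`floor(i * 1e9 / rate)`), and each stage draws from its own seed offset,
  so a fixed seed reproduces byte-identical files and toggling one stage's
  drops does not perturb another's.
* `reference_capture_chain()` constructs the worked drop-accounting
  example: 216,300 origin frames through a two-node chain losing exactly
  56 (split evenly between the stages; only the total is meaningful),
  yielding 216,244 saved frames.
* `scripted_session()` replays a fixed rig event list against the
  controller.

What the simulator does *not* emulate: clock drift between devices (the
scheme is purely pulse-count based, so drift is irrelevant to it by
construction), bursty or correlated drops (drops are independent
Bernoulli), and pixel data (frames are abstract events with ids). Passing
tests therefore demonstrate the bookkeeping is exact under the scheme's
own assumptions — a shared trigger line and per-frame ids — not that any
particular camera meets them.

## Numerical and engineering choices

* Timestamps are nanoseconds held in doubles; exact below $2^{53}$ ns
  (≈ 104 days), far beyond any session.
* Node RNG streams are derived from the run seed as
  `seed + 7919 * node_position` (a prime stride keeps streams distinct);
  all seeds stay below `.Machine$integer.max`.
* Problem sizes in the tests are chosen to keep the default suite around
  two minutes: live engine runs use 1–5-node graphs for a few seconds
  each, reconciliation oracles run at $10^4$–$3 \times 10^4$ packets, and
  statistical checks of the PRL logic use $10^4$ simulated trials (cell
  frequencies are then tested against binomial 99% intervals).
* The engine's latency floor is the broker hop (~1 ms on loopback); the
  drop-semantics tests induce busy windows of 100 ms and more so that
  results do not depend on scheduler jitter.
* Duplicate identical links are forbidden at validation: nothing in the
  many-to-many connection model gives a second identical link meaning.
* The process-count bookkeeping treats zombies as dead (see above); the
  census counts the director, the forwarders, and the com/worker pairs,
  i.e. exactly the $2N+4$ actors of the topology.

## Known limitations

* Single machine only. The placement field exists, but all workers run
  locally.
* The broker is a plain TCP fan-out without high-water marks; throughput
  is adequate for control-rate traffic (hundreds of messages per second)
  but it is not a high-bandwidth video transport.
* A transform whose callback never returns stalls its own node until the
  stop grace period; the engine kills it at stop but does not restart
  nodes mid-run.
* The PRL controller's simulated subject is intentionally simple
  (stationary lick probability); it exercises the task plumbing, not
  learning dynamics.
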