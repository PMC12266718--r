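Package: rigflow
Title: Actor-Based Dataflow Pipelines for Experimental Rigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for running behavioural-experiment pipelines
    described as knowledge graphs of Source, Transform and Sink nodes. Each
    node runs as a pair of communicating processes (a relay and a worker)
    routed through three forwarder brokers, with at-most-once message
    delivery and explicit drop accounting instead of buffering. The package
    also provides the provenance machinery to reconcile per-node relay logs
    and substate tables into exact cross-device frame correspondences
    (including TTL pulse-divider common-clock alignment), a library of
    ready-made nodes (scripted sources, pulse divider, table sink, a
    probabilistic reversal-learning trial generator and controller, an
    external-process wrapper), seeded synthetic fixtures for every input the
    tests need, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
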