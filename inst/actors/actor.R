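#!/usr/bin/env Rscript
# Entry point for engine actor processes (director, forwarders, com and
# worker actors). Spawned by rigflow; not meant to be run by hand.
suppressPackageStartupMessages(library(rigflow))
rigflow:::actor_main(commandArgs(trailingOnly = TRUE))
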