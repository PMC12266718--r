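# Worker for the "@NAME@" transform node.
# Reference this file from a graph node's "worker_ref".

make_worker <- function() {
  rigflow::worker_definition(
    "transform",
    initialise = function(ctx) {
      TRUE
    },
    work = function(ctx, event) {
      # callback: invoked once per delivered packet; return a payload list
      # with one item per declared output (first output first), or NULL to
      # emit nothing this pass.
      list(event$item)
    },
    end_of_life = function(ctx) {
      invisible(NULL)
    }
  )
}
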