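# Worker for the "@NAME@" sink node.
# Reference this file from a graph node's "worker_ref".

make_worker <- function() {
  rigflow::worker_definition(
    "sink",
    initialise = function(ctx) {
      ctx$state$seen <- 0L
      TRUE
    },
    work = function(ctx, event) {
      # callback: consume the delivered item; sinks return NULL.
      ctx$state$seen <- ctx$state$seen + 1L
      NULL
    },
    end_of_life = function(ctx) {
      invisible(NULL)
    }
  )
}
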