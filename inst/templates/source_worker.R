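# Worker for the "@NAME@" source node.
# Reference this file from a graph node's "worker_ref".

make_worker <- function() {
  rigflow::worker_definition(
    "source",
    initialise = function(ctx) {
      # one-off setup (open devices, allocate state in ctx$state, ...)
      ctx$state$i <- 0L
      TRUE
    },
    work = function(ctx) {
      # one pass of the acquisition loop: return a payload list with one
      # item per declared output, or NULL for an idle pass.
      ctx$state$i <- ctx$state$i + 1L
      list(as.numeric(ctx$state$i))
    },
    end_of_life = function(ctx) {
      # release devices / flush files
      invisible(NULL)
    }
  )
}
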