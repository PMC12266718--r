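# Clocks. All timestamps in the package are nanoseconds on a monotonic
# clock, stored as doubles (exact for any realistic run length). Workers
# receive their clock through the node context, so node logic can be driven
# either by the process clock or by a simulated clock for deterministic
# tests; simulated time only moves when advanced, and sleeping on it is
# instantaneous in wall time.

#' A monotonic real-time clock
#'
#' @return a clock object with `now()` (ns, monotonic) and `sleep(ns)`.
#' @export
clock_real <- function() {
  t0 <- proc.time()[["elapsed"]]
  structure(list(
    now = function() (proc.time()[["elapsed"]] - t0) * 1e9,
    sleep = function(ns) Sys.sleep(ns / 1e9),
    simulated = FALSE
  ), class = "rigflow_clock")
}

#' A simulated clock for deterministic runs
#'
#' Time starts at 0 and moves only via `advance(ns)` or `sleep(ns)` (which
#' advances instantly). Node logic written against the clock interface runs
#' identically, but without wall-clock waits.
#'
#' @return a clock object with `now()`, `sleep(ns)` and `advance(ns)`.
#' @export
clock_simulated <- function() {
  t <- 0
  structure(list(
    now = function() t,
    sleep = function(ns) t <<- t + ns,
    advance = function(ns) t <<- t + ns,
    simulated = TRUE
  ), class = "rigflow_clock")
}
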