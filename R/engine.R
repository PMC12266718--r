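# Caller-side engine interface. start_graph() spawns the director process,
# which in turn spawns the three forwarders and one com + worker process per
# node, so a running graph of N nodes is exactly 2N + 4 OS processes. The
# caller talks to the director over a control connection; everything else is
# message passing between the actors.

#' Run configuration
#'
#' @param log_dir directory for all run artifacts (report, com logs,
#'   substates, engine logs); a fresh temporary directory by default.
#' @param seed integer run seed; each node derives its own RNG stream from
#'   it.
#' @param start_timeout seconds allowed for every worker's proof of life
#'   before the start aborts.
#' @param stop_grace seconds a stopping node is given before it is forcibly
#'   killed.
#' @param heartbeat_period seconds between director heartbeats; a worker
#'   that misses `heartbeat_misses` beats runs its end-of-life and exits.
#' @param heartbeat_misses missed beats tolerated.
#' @return a `rigflow_run_config`.
#' @export
run_config <- function(log_dir = NULL, seed = 1L, start_timeout = 60,
                       stop_grace = 10, heartbeat_period = 1, heartbeat_misses = 5) {
  if (is.null(log_dir)) {
    log_dir <- tempfile(sprintf("rigflow_run_%s_", format(Sys.time(), "%Y%m%d_%H%M%S")))
  }
  structure(list(log_dir = log_dir, seed = as.integer(seed),
                 start_timeout = start_timeout, stop_grace = stop_grace,
                 heartbeat_period = heartbeat_period,
                 heartbeat_misses = heartbeat_misses),
            class = "rigflow_run_config")
}

#' Start a graph as a running actor topology
#'
#' Validates the graph, checks every worker reference resolves and every
#' placement is local, then spawns the director, which brings up the three
#' forwarders and each node's com and worker process in authoring order.
#' The call returns once every worker has delivered its proof of life,
#' initial parameter values have been pushed, and data flow is open. If any
#' worker fails to initialise, the whole start aborts and every spawned
#' process is reaped.
#'
#' @param g a valid `rigflow_graph`.
#' @param config a [run_config()].
#' @return a `rigflow_run` handle.
#' @seealso [stop_graph()], [process_census()], [update_parameter()]
#' @export
start_graph <- function(g, config = run_config()) {
  violations <- validate_graph(g)
  if (length(violations) > 0L) {
    stop("invalid graph:\n", paste(" -", violations, collapse = "\n"), call. = FALSE)
  }
  for (n in g$nodes) {
    if (!identical(n$placement, "local")) {
      stop("node ", sQuote(display_name(n)), " requests placement ",
           sQuote(n$placement), ": remote execution not implemented", call. = FALSE)
    }
    resolve_worker_ref(n$worker_ref)   # errors before any spawn
  }
  run_dir <- config$log_dir
  dir.create(file.path(run_dir, "logs"), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(graph = g, config = config), file.path(run_dir, "run.rds"))

  bound <- rf_bind_any()
  rf_spawn_actor(c("role=director", paste0("caller_port=", bound$port),
                   paste0("run_dir=", run_dir)),
                 log_file = file.path(run_dir, "logs", "director.out"))
  if (!socketSelect(list(bound$srv), timeout = config$start_timeout)) {
    close(bound$srv)
    stop("director failed to start within ", config$start_timeout, "s", call. = FALSE)
  }
  con <- socketAccept(bound$srv, blocking = TRUE, open = "a+b", options = "no-delay")
  close(bound$srv)
  ready <- rf_recv_frame(con)
  if (is.null(ready) || !identical(ready$kind, "ready")) {
    try(close(con), silent = TRUE)
    stop("director handshake failed", call. = FALSE)
  }
  deadline <- Sys.time() + config$start_timeout
  started <- NULL
  while (is.null(started)) {
    if (Sys.time() > deadline) {
      tools::pskill(ready$pid)
      try(close(con), silent = TRUE)
      stop("graph start timed out", call. = FALSE)
    }
    if (length(rf_poll(list(con), 0.2)) == 0L) next
    f <- rf_recv_frame(con)
    if (is.null(f)) {
      try(close(con), silent = TRUE)
      stop("director exited during start (see ", file.path(run_dir, "logs"), ")",
           call. = FALSE)
    }
    if (identical(f$kind, "started")) {
      started <- f
    } else if (identical(f$kind, "error")) {
      # the director has already reaped its children; sweep as a belt-and-braces
      for (p in unlist(f$pids)) if (rf_pid_alive(p)) tools::pskill(p)
      try(close(con), silent = TRUE)
      stop("graph start failed: ", f$message, call. = FALSE)
    }
  }
  h <- new.env(parent = emptyenv())
  h$graph <- g
  h$config <- config
  h$run_dir <- run_dir
  h$con <- con
  h$pids <- started$pids
  h$state <- "running"
  class(h) <- c("rigflow_run", "environment")
  h
}

#' @export
print.rigflow_run <- function(x, ...) {
  cat(sprintf("<rigflow run: %d nodes, %s, logs at %s>\n",
              length(x$graph$nodes), x$state, x$run_dir))
  invisible(x)
}

check_running <- function(h) {
  if (!identical(h$state, "running")) {
    stop("the run handle is ", h$state, ", not running", call. = FALSE)
  }
}

#' Live process census of a running graph
#'
#' Counts the engine and node processes currently alive: the director, the
#' three forwarders and each node's com and worker — `2 * N + 4` for a
#' healthy N-node graph.
#'
#' @param h a running `rigflow_run` handle.
#' @return integer process count.
#' @export
process_census <- function(h) {
  check_running(h)
  sum(vapply(unlist(h$pids), rf_pid_alive, logical(1)))
}

#' Update a node parameter while the graph runs
#'
#' The value travels through the parameter forwarder to the node's worker,
#' which applies it between work passes — a pass either sees the old value
#' throughout or the new one, never a mix. Non-updatable parameters and
#' unknown names are refused with an error acknowledgement; the run is
#' unaffected.
#'
#' @param h a running `rigflow_run` handle.
#' @param node node display name.
#' @param param parameter name.
#' @param value new value.
#' @return list `(ok, message)`; `ok = TRUE` once the worker acknowledged.
#' @export
update_parameter <- function(h, node, param, value) {
  check_running(h)
  rf_send_frame(h$con, list(kind = "cmd", cmd = "param", node = node,
                            param = param, value = value))
  deadline <- Sys.time() + 10
  while (Sys.time() < deadline) {
    if (length(rf_poll(list(h$con), 0.1)) == 0L) next
    f <- rf_recv_frame(h$con)
    if (is.null(f)) stop("director connection lost", call. = FALSE)
    if (identical(f$kind, "param_ack")) {
      return(list(ok = isTRUE(f$ok), message = f$message %||% ""))
    }
  }
  list(ok = FALSE, message = "timeout waiting for acknowledgement")
}

#' Stop a running graph gracefully
#'
#' Workers are told to stop in start order; each runs its end-of-life hook
#' exactly once, flushes its substate table and reports back. Coms relay
#' end-of-stream markers so every in-flight packet is counted as delivered
#' or dropped before the per-link counters are frozen. Unresponsive
#' processes are killed after the grace period and recorded as forced. After
#' the call no child process of the run survives.
#'
#' @param h a running `rigflow_run` handle.
#' @return a `rigflow_termination_report`: per-node exit status and
#'   end-of-life flags, per-link `{emitted, delivered, dropped}` counters,
#'   the orphan count (0 after a clean stop) and artifact paths.
#' @export
stop_graph <- function(h) {
  check_running(h)
  rf_send_frame(h$con, list(kind = "cmd", cmd = "stop"))
  deadline <- Sys.time() + h$config$stop_grace + 30
  report <- NULL
  while (is.null(report) && Sys.time() < deadline) {
    if (length(rf_poll(list(h$con), 0.2)) == 0L) next
    f <- rf_recv_frame(h$con)
    if (is.null(f)) break
    if (identical(f$kind, "report")) report <- f$report
  }
  try(close(h$con), silent = TRUE)
  # wait for every registered process to exit, then sweep
  all_pids <- unlist(h$pids)
  deadline <- Sys.time() + 10
  while (any(vapply(all_pids, rf_pid_alive, logical(1))) && Sys.time() < deadline) {
    Sys.sleep(0.1)
  }
  leftover <- all_pids[vapply(all_pids, rf_pid_alive, logical(1))]
  for (p in leftover) tools::pskill(p)
  Sys.sleep(if (length(leftover) > 0L) 0.3 else 0)
  orphans <- sum(vapply(all_pids, rf_pid_alive, logical(1)))
  h$state <- "stopped"
  if (is.null(report)) report <- list(nodes = list(), links = list(), forced = character())
  structure(list(
    nodes = report$nodes,
    links = report$links,
    forced = unlist(report$forced),
    orphan_count = orphans,
    run_dir = h$run_dir
  ), class = "rigflow_termination_report")
}

#' @export
print.rigflow_termination_report <- function(x, ...) {
  cat(sprintf("<termination report: %d nodes, %d links, %d forced, %d orphans>\n",
              length(x$nodes), length(x$links), length(x$forced), x$orphan_count))
  for (l in x$links) {
    cat(sprintf("  %-45s emitted %s delivered %s dropped %s\n", l$link_id,
                l$emitted, l$delivered, l$dropped))
  }
  invisible(x)
}

#' Read a run's saved link counters
#'
#' @param run_dir the run's log directory.
#' @return data.frame `link_id`, `emitted`, `delivered`, `dropped`.
#' @export
read_link_counters <- function(run_dir) {
  read.csv(file.path(run_dir, "link_counters.csv"), stringsAsFactors = FALSE)
}
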